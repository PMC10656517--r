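#' Theoretical b/y fragment ions
#'
#' Singly charged b and y ion m/z values for a peptide:
#' `b_i = sum(residues 1..i) + proton`,
#' `y_j = sum(residues n-j+1..n) + water + proton`.
#' A heavy-isotope label at one residue adds its delta mass to every ion whose
#' span contains the labelled position; such ions carry `contains_label`.
#'
#' @param sequence amino-acid string (length >= 2).
#' @param labels optional data.frame with columns `position` (1-based) and
#'   `delta` (Da > 0) describing isotope labels.
#' @param charge fragment charge (default 1).
#' @return tibble with `series` ("b"/"y"), `ordinal`, `charge`, `mz`,
#'   `contains_label` and `ion` (e.g. "b3", "y5").
#' @export
theoretical_fragments <- function(sequence, labels = NULL, charge = 1L) {
  res <- split_residues(sequence)
  n <- length(res)
  if (n < 2L) stop("need at least 2 residues to fragment", call. = FALSE)
  masses <- unname(AA_MONO_MASS[res])
  label_pos <- integer(0)
  if (!is.null(labels) && nrow(labels) > 0L) {
    if (any(labels$position < 1L | labels$position > n)) {
      stop("label position outside peptide", call. = FALSE)
    }
    if (any(labels$delta <= 0)) stop("label delta mass must be positive", call. = FALSE)
    masses[labels$position] <- masses[labels$position] + labels$delta
    label_pos <- labels$position
  }
  i <- seq_len(n - 1L)
  b_neutral <- cumsum(masses)[i]
  y_neutral <- cumsum(rev(masses))[i] + WATER_MONO
  b_mz <- (b_neutral + charge * PROTON_MASS) / charge
  y_mz <- (y_neutral + charge * PROTON_MASS) / charge
  b_lab <- vapply(i, function(k) any(label_pos <= k), logical(1))
  y_lab <- vapply(i, function(k) any(label_pos > n - k), logical(1))
  tibble::tibble(
    series = rep(c("b", "y"), each = n - 1L),
    ordinal = c(i, i),
    charge = as.integer(charge),
    mz = c(b_mz, y_mz),
    contains_label = c(b_lab, y_lab),
    ion = c(paste0("b", i), paste0("y", i))
  )
}

#' Match theoretical fragments against a peak list
#'
#' Each fragment is matched to the nearest peak within the tolerance window
#' `min(mz * tol_ppm * 1e-6, tol_da)`; one peak may satisfy several fragments.
#' Ties on distance are broken toward the lower-m/z peak.
#'
#' @param spec a [spectrum()] (or a 2-column peaks matrix).
#' @param fragments tibble from [theoretical_fragments()].
#' @param tol_ppm relative tolerance in parts per million (default 20).
#' @param tol_da absolute tolerance cap in Da (default 0.02).
#' @return `fragments` with added `matched`, `observed_mz`, `intensity`,
#'   `delta_mz` columns.
#' @export
match_peaks <- function(spec, fragments, tol_ppm = 20, tol_da = 0.02) {
  peaks <- if (inherits(spec, "spectrum")) spec$peaks else {
    m <- as.matrix(spec)
    colnames(m) <- c("mz", "intensity")
    m
  }
  out <- fragments
  out$matched <- FALSE
  out$observed_mz <- NA_real_
  out$intensity <- NA_real_
  out$delta_mz <- NA_real_
  if (nrow(peaks) == 0L) return(out)
  for (i in seq_len(nrow(out))) {
    mz <- out$mz[i]
    tol <- min(mz * tol_ppm * 1e-6, tol_da)
    d <- abs(peaks[, "mz"] - mz)
    j <- which(d <= tol + 1e-12)
    if (length(j) == 0L) next
    best <- j[order(d[j], peaks[j, "mz"])][1L]  # nearest; tie -> lower mz
    out$matched[i] <- TRUE
    out$observed_mz[i] <- peaks[best, "mz"]
    out$intensity[i] <- peaks[best, "intensity"]
    out$delta_mz[i] <- peaks[best, "mz"] - mz
  }
  out
}

#' Spectral correlation against an isotope-labelled synthetic spectrum
#'
#' Validates an eluted peptide identification by correlating its fragment
#' intensities with those of the co-analysed isotope-labelled synthetic
#' peptide. Theoretical b/y ions are computed without labels for the eluted
#' spectrum and with labels for the synthetic one; intensities are paired by
#' ion identity (series + ordinal) over the ions matched in both spectra, and
#' the Pearson correlation `r` (and `R^2 = r^2`) of the two intensity vectors
#' is reported. Only b and y ions enter the statistic.
#'
#' @param spec_eluted,spec_synthetic [spectrum()] objects.
#' @param sequence the peptide sequence.
#' @param labels isotope labels of the synthetic peptide (see
#'   [theoretical_fragments()]).
#' @param tol_ppm,tol_da matching tolerances (see [match_peaks()]).
#' @param pairing `"intersection"` (default; ions matched in both spectra) or
#'   `"union"` (unmatched intensities enter as zero).
#' @return list of class `spectral_match`: `r`, `r_squared`, `n_matched`,
#'   `defined` (FALSE when fewer than 2 ions are shared), and the per-ion
#'   `table`.
#' @export
spectral_correlation <- function(spec_eluted, spec_synthetic, sequence,
                                 labels = NULL, tol_ppm = 20, tol_da = 0.02,
                                 pairing = c("intersection", "union")) {
  pairing <- match.arg(pairing)
  fr_el <- match_peaks(spec_eluted, theoretical_fragments(sequence),
                       tol_ppm, tol_da)
  fr_sy <- match_peaks(spec_synthetic, theoretical_fragments(sequence, labels),
                       tol_ppm, tol_da)
  tab <- tibble::tibble(
    ion = fr_el$ion, series = fr_el$series, ordinal = fr_el$ordinal,
    mz_eluted = fr_el$mz, mz_synthetic = fr_sy$mz,
    matched_eluted = fr_el$matched, matched_synthetic = fr_sy$matched,
    intensity_eluted = fr_el$intensity, intensity_synthetic = fr_sy$intensity
  )
  if (pairing == "intersection") {
    use <- tab$matched_eluted & tab$matched_synthetic
    x <- tab$intensity_eluted[use]
    y <- tab$intensity_synthetic[use]
  } else {
    use <- tab$matched_eluted | tab$matched_synthetic
    x <- ifelse(is.na(tab$intensity_eluted[use]), 0, tab$intensity_eluted[use])
    y <- ifelse(is.na(tab$intensity_synthetic[use]), 0, tab$intensity_synthetic[use])
  }
  n_matched <- length(x)
  if (n_matched < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, r_squared = NA_real_,
                          n_matched = n_matched, defined = FALSE, table = tab),
                     class = "spectral_match"))
  }
  r <- stats::cor(x, y)
  structure(list(r = r, r_squared = r^2, n_matched = n_matched,
                 defined = TRUE, table = tab),
            class = "spectral_match")
}

#' @export
print.spectral_match <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<spectral_match> R^2 = %.4f over %d shared b/y ions\n",
                x$r_squared, x$n_matched))
  } else {
    cat(sprintf("<spectral_match> undefined (%d shared ions)\n", x$n_matched))
  }
  invisible(x)
}

#' Parse a mutation window identifier
#'
#' Identifiers of the form `PROTEIN_START-END_ REFposALT` (e.g.
#' `"SFPQ_HUMAN_304-313_ I308V"`) describe a peptide window on a protein plus
#' a single amino-acid substitution inside it.
#'
#' @param text identifier string.
#' @return list with `protein_id`, `window_start`, `window_end`,
#'   `ref_residue`, `position`, `alt_residue`.
#' @export
parse_mutation_id <- function(text) {
  m <- regexec("^(.+)_([0-9]+)-([0-9]+)_\\s*([A-Z])([0-9]+)([A-Z])$",
               trimws(text))
  g <- regmatches(trimws(text), m)[[1]]
  if (length(g) != 7L) {
    stop("malformed mutation identifier: '", text, "'", call. = FALSE)
  }
  out <- list(protein_id = g[2], window_start = as.integer(g[3]),
              window_end = as.integer(g[4]), ref_residue = g[5],
              position = as.integer(g[6]), alt_residue = g[7])
  if (!out$ref_residue %in% AA_ALPHABET || !out$alt_residue %in% AA_ALPHABET) {
    stop("mutation identifier '", text, "' has a non-amino-acid residue",
         call. = FALSE)
  }
  if (out$position < out$window_start || out$position > out$window_end) {
    stop("mutation position outside window in '", text, "'", call. = FALSE)
  }
  if (out$window_end < out$window_start) {
    stop("window end before start in '", text, "'", call. = FALSE)
  }
  out
}

#' Extract a neoepitope window from a protein
#'
#' Cuts the `window_start..window_end` substring (1-based inclusive) out of
#' the protein and substitutes the mutant residue, after checking that the
#' protein carries the expected reference residue at the mutated position.
#'
#' @param protein_sequence the (wild-type) protein sequence.
#' @param spec a parsed mutation, from [parse_mutation_id()].
#' @return the mutated peptide sequence (length `end - start + 1`).
#' @export
extract_neoepitope <- function(protein_sequence, spec) {
  n <- nchar(protein_sequence)
  if (spec$window_end > n) {
    stop("window ", spec$window_start, "-", spec$window_end,
         " beyond protein length ", n, call. = FALSE)
  }
  found <- substr(protein_sequence, spec$position, spec$position)
  if (found != spec$ref_residue) {
    stop("reference mismatch at position ", spec$position, ": expected ",
         spec$ref_residue, ", found ", found, call. = FALSE)
  }
  pep <- substr(protein_sequence, spec$window_start, spec$window_end)
  offset <- spec$position - spec$window_start + 1L
  substr(pep, offset, offset) <- spec$alt_residue
  pep
}
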