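#' Fragment spectra as MGF
#'
#' Minimal Mascot Generic Format support for the peak lists the validation
#' step consumes. A spectrum is a list with `title`, `precursor_mz`,
#' `precursor_charge` and a two-column numeric `peaks` matrix (`mz`,
#' `intensity`) kept sorted by m/z.
#'
#' @param title spectrum identifier.
#' @param precursor_mz precursor m/z (Da/charge).
#' @param precursor_charge integer charge >= 1.
#' @param peaks two-column matrix or data.frame of (mz, intensity).
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(title, precursor_mz, precursor_charge, peaks) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)",
                              call. = FALSE)
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (any(peaks[, "intensity"] < 0)) stop("negative peak intensity", call. = FALSE)
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  if (!is.numeric(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be positive", call. = FALSE)
  }
  precursor_charge <- as.integer(precursor_charge)
  if (is.na(precursor_charge) || precursor_charge < 1L) {
    stop("precursor_charge must be an integer >= 1", call. = FALSE)
  }
  structure(list(title = as.character(title), precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge, peaks = peaks),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s'> precursor %.4f m/z (%d+), %d peaks\n",
              x$title, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from an MGF file
#'
#' @param path path to an MGF file (BEGIN IONS / END IONS blocks with PEPMASS
#'   and optional CHARGE and TITLE lines).
#' @return list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("unbalanced BEGIN IONS/END IONS blocks in ", path, call. = FALSE)
  }
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    if (!"PEPMASS" %in% keys) {
      stop("MGF block ", b, " has no PEPMASS", call. = FALSE)
    }
    pepmass <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "[ \t]+")[[1]][1])
    charge <- 1L
    if ("CHARGE" %in% keys) {
      charge <- as.integer(gsub("[+-]", "", vals[match("CHARGE", keys)]))
    }
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else paste0("spectrum_", b)
    peak_lines <- block[!is_kv]
    peaks <- if (length(peak_lines) > 0L) {
      do.call(rbind, lapply(strsplit(peak_lines, "[ \t]+"), function(x) {
        as.numeric(x[1:2])
      }))
    } else {
      matrix(numeric(0), ncol = 2)
    }
    out[[b]] <- spectrum(title, pepmass, charge, peaks)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Peak m/z and intensities are written with enough digits for a lossless
#' round-trip at 1e-6 relative precision.
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output path.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$title),
      sprintf("PEPMASS=%.10g", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      sprintf("%.10g %.10g", s$peaks[, "mz"], s$peaks[, "intensity"]),
      "END IONS"
    ), con)
  }
  invisible(path)
}
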