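#' Monoisotopic peptide mass
#'
#' Sum of the standard monoisotopic residue masses plus one water, plus any
#' modification delta masses.
#'
#' @param sequence uppercase amino-acid string.
#' @param modifications data.frame with columns `position`, `name`, `delta`
#'   (as returned by [parse_modifications()]), or `NULL`.
#' @return monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("SIINFEKL")
monoisotopic_mass <- function(sequence, modifications = NULL) {
  res <- split_residues(sequence)
  m <- sum(AA_MONO_MASS[res]) + WATER_MONO
  if (!is.null(modifications) && nrow(modifications) > 0L) {
    if (any(modifications$position < 1L | modifications$position > length(res))) {
      stop("modification position outside sequence", call. = FALSE)
    }
    m <- m + sum(modifications$delta)
  }
  m
}

#' GRAVY hydropathy score
#'
#' Grand average of hydropathy: the arithmetic mean of Kyte-Doolittle
#' hydropathy values over the peptide's residues. Modifications do not enter.
#'
#' @param sequence uppercase amino-acid string.
#' @return dimensionless GRAVY score.
#' @export
#' @examples
#' gravy("VYPLAFVLI")
gravy <- function(sequence) {
  res <- split_residues(sequence)
  mean(KYTE_DOOLITTLE[res])
}

#' Peptide length distribution
#'
#' @param peptides character vector of sequences (or a peptide table).
#' @return named numeric vector: relative frequency per observed length,
#'   summing to 1, names = lengths.
#' @export
length_distribution <- function(peptides) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  if (length(peptides) == 0L) stop("empty peptide list", call. = FALSE)
  tab <- table(nchar(peptides))
  out <- as.numeric(tab) / length(peptides)
  names(out) <- names(tab)
  out
}

#' Amino-acid composition profile
#'
#' Relative frequency of each of the 20 residues pooled over a peptide set.
#'
#' @param peptides character vector of sequences (or a peptide table).
#' @return list with `freq` (named numeric over the 20 residues, sums to 1)
#'   and `n_peptides`.
#' @export
composition_profile <- function(peptides) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  if (length(peptides) == 0L) stop("empty peptide list", call. = FALSE)
  res <- unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE)
  bad <- setdiff(unique(res), AA_ALPHABET)
  if (length(bad) > 0L) stop("unknown residue(s): ", paste(bad, collapse = ", "),
                             call. = FALSE)
  counts <- table(factor(res, levels = AA_ALPHABET))
  freq <- stats::setNames(as.numeric(counts) / length(res), AA_ALPHABET)
  list(freq = freq, n_peptides = length(peptides))
}

#' Goodness of fit between two composition profiles
#'
#' Squared Pearson correlation of the 20 paired residue frequencies, the usual
#' R-squared reported when comparing amino-acid compositions of peptide sets.
#'
#' @param profile_a,profile_b profiles from [composition_profile()].
#' @return R-squared in \[0, 1\], or `NA` with a warning if either profile has
#'   zero variance (undefined correlation).
#' @export
composition_r2 <- function(profile_a, profile_b) {
  a <- profile_a$freq[AA_ALPHABET]
  b <- profile_b$freq[AA_ALPHABET]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance composition profile: R^2 undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Within-sample percentile ranks of reported areas
#'
#' Normalizes reported peptide abundances in a scale-free, device-agnostic way:
#' each peptide's area is converted to its percentile rank within the sample
#' (ascending rank / n, ties sharing the mean rank), so values lie in (0, 1]
#' and are comparable across instruments. Peptides below `lower_split` are
#' flagged as "lower rank".
#'
#' @param tab peptide table with a non-`NA` `area` column (rows without area
#'   are excluded).
#' @param lower_split percentile defining the lower-rank stratum (default 0.5).
#' @return tibble with `sequence`, `area`, `rank` (percentile in (0,1\]) and
#'   `lower_rank` (logical).
#' @export
normalized_area_ranks <- function(tab, lower_split = 0.5) {
  keep <- !is.na(tab$area)
  if (!any(keep)) stop("no reported areas present", call. = FALSE)
  x <- tab[keep, , drop = FALSE]
  r <- rank(x$area, ties.method = "average") / nrow(x)
  tibble::tibble(sequence = x$sequence, area = x$area, rank = r,
                 lower_rank = r < lower_split)
}

#' Compare hydropathy distributions between peptide sets
#'
#' Reports medians and ranges of GRAVY scores per group and a two-sided
#' rank-based test: Mann-Whitney (Wilcoxon rank-sum) for two groups,
#' Kruskal-Wallis for more.
#'
#' @param ... two or more numeric vectors of GRAVY scores (or character
#'   vectors of sequences, converted via [gravy()]), each of size >= 2.
#' @return list with `medians`, `ranges` (per group) and `p_value`.
#' @export
compare_hydropathy <- function(...) {
  groups <- list(...)
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  groups <- lapply(groups, function(g) {
    if (is.character(g)) vapply(g, gravy, numeric(1), USE.NAMES = FALSE) else g
  })
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  meds <- vapply(groups, stats::median, numeric(1))
  rngs <- t(vapply(groups, range, numeric(2)))
  colnames(rngs) <- c("min", "max")
  p <- if (length(groups) == 2L) {
    suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                        alternative = "two.sided"))$p.value
  } else {
    stats::kruskal.test(groups)$p.value
  }
  list(medians = meds, ranges = rngs, p_value = p)
}
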