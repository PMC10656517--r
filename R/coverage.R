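#' HLA population coverage under Hardy-Weinberg equilibrium
#'
#' Given, per locus, the population allele frequencies and the set of cohort
#' allotypes at that locus, computes the distribution of the number of
#' cohort-covered allotypes an individual carries and the probability of
#' carrying at least one. Per locus the covered-allele mass is
#' `p = sum of population frequencies of the cohort's alleles`; under
#' Hardy-Weinberg an individual carries 0, 1 or 2 covered alleles with
#' probabilities `(1-p)^2`, `2p(1-p)`, `p^2`. Loci are assumed independent and
#' the per-locus distributions are convolved, so with L loci the count runs
#' 0..2L (e.g. the "up to 6 of 6" axis for the three class I loci).
#'
#' @param cohort_alleles named list: locus -> character vector of cohort
#'   allotypes at that locus.
#' @param population_freqs named list: locus -> named numeric vector of
#'   population allele frequencies (per-locus sum <= 1; alleles absent from
#'   the map count zero).
#' @return list with `pmf` (named numeric over 0..2L, sums to 1) and
#'   `coverage_at_least_one`.
#' @export
#' @examples
#' population_coverage(list(A = "A*02"), list(A = c("A*02" = 0.5)))
population_coverage <- function(cohort_alleles, population_freqs) {
  loci <- names(cohort_alleles)
  if (is.null(loci) || !setequal(loci, names(population_freqs))) {
    stop("cohort_alleles and population_freqs must cover the same loci",
         call. = FALSE)
  }
  p_locus <- vapply(loci, function(l) {
    freqs <- population_freqs[[l]]
    if (any(freqs < 0)) stop("negative allele frequency at locus ", l, call. = FALSE)
    if (sum(freqs) > 1 + 1e-9) {
      stop("allele frequencies at locus ", l, " sum above 1", call. = FALSE)
    }
    sum(freqs[intersect(names(freqs), cohort_alleles[[l]])])
  }, numeric(1))
  if (any(p_locus < 0 | p_locus > 1 + 1e-12)) {
    stop("covered-allele mass outside [0, 1]", call. = FALSE)
  }
  p_locus <- pmin(p_locus, 1)
  pmf <- 1
  for (p in p_locus) {
    pmf <- convolve_pmf(pmf, c((1 - p)^2, 2 * p * (1 - p), p^2))
  }
  names(pmf) <- as.character(seq_along(pmf) - 1L)
  list(pmf = pmf, coverage_at_least_one = 1 - pmf[["0"]])
}

# discrete convolution of two pmfs over counts starting at 0
convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}
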