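# fixtures are built in code at test time

# write a small CSV peptide table and return its path
write_tmp_table <- function(lines, ext = ".csv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

# a minimal sample with named replicate sequence sets
make_sample <- function(id, reps, donor = "D1", tissue = "PBMC",
                        cohort = "benign", typing = c("A*02", "B*07")) {
  pep_sample(id, donor, tissue, cohort, "I", typing, reps)
}

# cohort of n samples, each carrying the given peptide sets
make_cohort <- function(name, sets, il = FALSE, ...) {
  samples <- lapply(seq_along(sets), function(i) {
    make_sample(sprintf("%s%02d", name, i), list(R1 = sets[[i]]), ...)
  })
  pep_cohort(name, samples, il_collapsed = il)
}

# independent direct-summation fragment oracle (kept deliberately naive)
oracle_fragment_mz <- function(sequence, series, ordinal) {
  masses <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (series == "b") {
    s <- 0
    for (k in 1:ordinal) s <- s + masses[[res[k]]]
    s + 1.007276
  } else {
    s <- 0
    for (k in (n - ordinal + 1):n) s <- s + masses[[res[k]]]
    s + 18.010565 + 1.007276
  }
}

# exhaustive genotype-enumeration oracle: every combination of two alleles per
# locus, counting copies of cohort-covered alleles
enumerate_coverage <- function(cohort_alleles, population_freqs) {
  per_locus <- lapply(names(cohort_alleles), function(l) {
    freqs <- population_freqs[[l]]
    alleles <- c(names(freqs), ".other")
    p <- c(freqs, 1 - sum(freqs))
    pmf <- numeric(3)
    for (i in seq_along(alleles)) {
      for (j in seq_along(alleles)) {
        k <- (alleles[i] %in% cohort_alleles[[l]]) +
          (alleles[j] %in% cohort_alleles[[l]])
        pmf[k + 1] <- pmf[k + 1] + p[i] * p[j]
      }
    }
    pmf
  })
  pmf <- 1
  for (lp in per_locus) {
    new <- numeric(length(pmf) + 2)
    for (i in seq_along(pmf)) {
      new[i:(i + 2)] <- new[i:(i + 2)] + pmf[i] * lp
    }
    pmf <- new
  }
  pmf
}

random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}
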