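test_that("b/y ion m/z match hand-summed values", {
  fr <- theoretical_fragments("AG")
  expect_equal(fr$mz[fr$ion == "b1"], 72.04439, tolerance = 1e-5)
  expect_equal(fr$mz[fr$ion == "y1"], 76.03930, tolerance = 1e-5)
  expect_error(theoretical_fragments("A"), "at least 2")
  expect_error(theoretical_fragments("AXB"), "unknown residue")
})

test_that("fragment masses agree with a direct-summation oracle", {
  set.seed(17)
  for (i in 1:60) {
    pep <- random_peptide(sample(8:14, 1))
    fr <- theoretical_fragments(pep)
    pick <- sample(nrow(fr), 4)
    for (j in pick) {
      expect_equal(fr$mz[j], oracle_fragment_mz(pep, fr$series[j], fr$ordinal[j]),
                   tolerance = 1e-4)
    }
  }
})

test_that("complementary b/y pairs sum to peptide mass plus two protons", {
  set.seed(19)
  for (i in 1:25) {
    pep <- random_peptide(sample(8:12, 1))
    fr <- theoretical_fragments(pep)
    n <- nchar(pep)
    M <- monoisotopic_mass(pep)
    for (k in seq_len(n - 1)) {
      b <- fr$mz[fr$series == "b" & fr$ordinal == k]
      y <- fr$mz[fr$series == "y" & fr$ordinal == n - k]
      expect_equal(b + y, M + 2 * 1.007276, tolerance = 1e-9)
    }
  }
})

test_that("an isotope label shifts exactly the ions spanning its residue", {
  lab <- data.frame(position = 2L, delta = 6.02013)
  plain <- theoretical_fragments("AG")
  labelled <- theoretical_fragments("AG", lab)
  expect_equal(labelled$mz[labelled$ion == "y1"],
               plain$mz[plain$ion == "y1"] + 6.02013)
  expect_equal(labelled$mz[labelled$ion == "b1"], plain$mz[plain$ion == "b1"])
  expect_equal(labelled$contains_label, c(FALSE, TRUE))
  # each complementary split contains the label on exactly one side
  lab5 <- data.frame(position = 5L, delta = 8.0142)
  fr <- theoretical_fragments("SIINFEKL", lab5)
  for (k in 1:7) {
    b_lab <- fr$contains_label[fr$series == "b" & fr$ordinal == k]
    y_lab <- fr$contains_label[fr$series == "y" & fr$ordinal == 8 - k]
    expect_equal(b_lab + y_lab, 1L)
  }
  expect_error(theoretical_fragments("AG", data.frame(position = 5, delta = 1)),
               "outside")
})

test_that("peak matching respects tolerance caps and prefers the nearest peak", {
  fr <- theoretical_fragments("SIINFEKL")
  b1 <- fr[fr$ion == "b1", ]  # ~88 m/z: ppm cap ~0.0018 Da governs
  exact <- match_peaks(cbind(b1$mz, 100), b1)
  expect_true(exact$matched)
  expect_equal(exact$delta_mz, 0)
  off <- match_peaks(cbind(b1$mz + 0.05, 100), b1)
  expect_false(off$matched)  # beyond both caps
  ppm_off <- match_peaks(cbind(b1$mz + 0.004, 100), b1)
  expect_false(ppm_off$matched)  # inside 0.02 Da but outside 20 ppm
  y7 <- fr[fr$ion == "y7", ]  # ~932 m/z: window ~0.0186 Da
  two <- match_peaks(cbind(c(y7$mz - 0.010, y7$mz + 0.002), c(5, 9)), y7)
  expect_equal(two$intensity, 9)  # nearer peak wins
  tie <- match_peaks(cbind(c(y7$mz - 0.004, y7$mz + 0.004), c(5, 9)), y7)
  expect_equal(tie$intensity, 5)  # tie broken toward lower m/z
})

test_that("spectral correlation is exact for label-shifted copies and scale-invariant", {
  pep <- "SIINFEKL"
  lab <- data.frame(position = 8L, delta = 6.02013)
  fr_plain <- theoretical_fragments(pep)
  fr_lab <- theoretical_fragments(pep, lab)
  ints <- seq(100, 100 + 13 * 25, by = 25)
  prec <- monoisotopic_mass(pep) / 2 + 1.007276
  eluted <- spectrum("e", prec, 2L, cbind(fr_plain$mz, ints))
  synth <- spectrum("s", prec, 2L, cbind(fr_lab$mz, ints))
  m <- spectral_correlation(eluted, synth, pep, lab)
  expect_true(m$defined)
  expect_equal(m$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(m$n_matched, 14L)

  scaled <- spectrum("s10", prec, 2L, cbind(fr_lab$mz, ints * 10))
  m10 <- spectral_correlation(eluted, scaled, pep, lab)
  expect_equal(m10$r_squared, m$r_squared, tolerance = 1e-12)

  # symmetry in the two spectra (labels stay with the synthetic side)
  m_rev <- spectral_correlation(synth, eluted, pep, lab)
  expect_equal(abs(m_rev$r), abs(m$r), tolerance = 1e-12)
})

test_that("too few shared ions yields an undefined flag, not an error", {
  pep <- "SIINFEKL"
  fr <- theoretical_fragments(pep)
  prec <- monoisotopic_mass(pep) / 2 + 1.007276
  eluted <- spectrum("e", prec, 2L, cbind(fr$mz[1], 10))
  synth <- spectrum("s", prec, 2L, cbind(fr$mz[1], 20))
  m <- spectral_correlation(eluted, synth, pep)
  expect_false(m$defined)
  expect_true(is.na(m$r_squared))
})

test_that("mutation identifiers parse to windows and substitutions", {
  a <- parse_mutation_id("SFPQ_HUMAN_304-313_ I308V")
  expect_equal(a$protein_id, "SFPQ_HUMAN")
  expect_equal(c(a$window_start, a$window_end), c(304L, 313L))
  expect_equal(a$window_end - a$window_start + 1L, 10L)
  expect_equal(a$position - a$window_start + 1L, 5L)  # mutated offset
  expect_equal(c(a$ref_residue, a$alt_residue), c("I", "V"))

  b <- parse_mutation_id("MD13L_HUMAN_279-287_ S282L")
  expect_equal(b$window_end - b$window_start + 1L, 9L)
  expect_equal(b$position - b$window_start + 1L, 4L)
  expect_equal(c(b$ref_residue, b$alt_residue), c("S", "L"))

  expect_error(parse_mutation_id("FOO_1-9_ X5Z"), "malformed|non-amino")
  expect_error(parse_mutation_id("garbage"), "malformed")
})

test_that("neoepitope extraction substitutes at the window offset", {
  spec <- list(protein_id = "P", window_start = 1L, window_end = 9L,
               ref_residue = "A", position = 5L, alt_residue = "G")
  expect_equal(extract_neoepitope(strrep("A", 10), spec), "AAAAGAAAA")
  bad <- spec
  bad$ref_residue <- "W"
  expect_error(extract_neoepitope(strrep("A", 10), bad),
               "expected W, found A")
  # structural consistency with reported neoepitopes: the mutated residue
  # lands at the printed offset
  prot <- paste0(strrep("G", 303), "LPADITEDEF", strrep("G", 20))
  m <- parse_mutation_id("SFPQ_HUMAN_304-313_ I308V")
  pep <- extract_neoepitope(prot, m)
  expect_equal(nchar(pep), 10L)
  expect_equal(pep, "LPADVTEDEF")
  expect_equal(substr(pep, 5, 5), "V")
})
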