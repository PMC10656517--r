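test_that("benign reference applies binder and metadata filters with provenance", {
  d1 <- tibble::tibble(sequence = c("AAA", "BBB", "CCC"),
                       binder = c("A*02=strong", "B*07=weak", "A*01=medium"))
  d2 <- tibble::tibble(sequence = c("AAA", "DDD"),
                       binder = c("A*02=strong", "A*02=strong"),
                       disease = c("healthy", "tumor"))
  ref <- build_benign_reference(
    list(ds1 = d1, ds2 = d2),
    list(ds1 = list(binder_strengths = c("strong", "medium")),
         ds2 = list(equals = list(disease = "healthy"))))
  expect_setequal(ref$peptides, c("AAA", "CCC"))
  expect_setequal(ref$provenance[["AAA"]], c("ds1", "ds2"))
  expect_equal(ref$provenance[["CCC"]], "ds1")
  expect_error(
    build_benign_reference(list(d = tibble::tibble(sequence = "AAA")),
                           list(d = list(binder_strengths = "strong"))),
    "missing column 'binder'")
  expect_warning(
    build_benign_reference(
      list(d = d1, e = d1[0, ]),
      list(e = list())),
    "no peptides")
})

test_that("tumor-exclusive split partitions the cohort union", {
  tumor <- make_cohort("T", list(c("P1", "P2"), c("P2", "P3")),
                       cohort = "tumor")
  ref <- build_benign_reference(list(b = tibble::tibble(sequence = "P2")))
  res <- tumor_exclusive(tumor, ref)
  expect_setequal(res$exclusive, c("P1", "P3"))
  expect_equal(res$rejected, "P2")
  expect_length(intersect(res$exclusive, res$rejected), 0L)
  expect_setequal(c(res$exclusive, res$rejected), cohort_union(tumor))

  superset <- build_benign_reference(
    list(b = tibble::tibble(sequence = c("P1", "P2", "P3", "P4"))))
  expect_length(tumor_exclusive(tumor, superset)$exclusive, 0L)

  il_ref <- build_benign_reference(list(b = tibble::tibble(sequence = "P2")),
                                   il_collapse = TRUE)
  expect_error(tumor_exclusive(tumor, il_ref), "canonicalization")
})

test_that("enlarging the benign reference never enlarges the exclusive set", {
  set.seed(23)
  tumor <- make_cohort("T", replicate(4, replicate(30, random_peptide(9)),
                                      simplify = FALSE), cohort = "tumor")
  pool <- cohort_union(tumor)
  small <- build_benign_reference(
    list(b = tibble::tibble(sequence = pool[1:10])))
  large <- build_benign_reference(
    list(b = tibble::tibble(sequence = pool[1:10]),
         c = tibble::tibble(sequence = pool[5:25])))
  ex_small <- tumor_exclusive(tumor, small)$exclusive
  ex_large <- tumor_exclusive(tumor, large)$exclusive
  expect_true(all(ex_large %in% ex_small))
})

test_that("presentation frequencies carry auditable integer counts", {
  sets <- c(replicate(11, c("PEP", "X"), simplify = FALSE),
            replicate(11, "X", simplify = FALSE))
  cll <- make_cohort("C", sets, cohort = "tumor")
  fr <- presentation_frequencies(c("PEP", "X"), cll)
  expect_equal(fr$n_total, c(22L, 22L))
  expect_equal(fr$frequency[fr$peptide == "PEP"], 0.5)
  expect_equal(fr$n_positive[fr$peptide == "PEP"], 11L)
  expect_equal(fr$frequency[fr$peptide == "X"], 1.0)
  # ordering: frequency descending, then identity ascending
  expect_equal(fr$peptide, c("X", "PEP"))
})

test_that("allotype-restricted frequencies use carrier denominators", {
  samples <- c(
    lapply(1:4, function(i) make_sample(paste0("A", i), list(R1 = "PEP"),
                                        typing = c("A*02", "B*07"))),
    lapply(1:6, function(i) make_sample(paste0("B", i), list(R1 = "OTHER"),
                                        typing = c("A*01", "B*08"))))
  cohort <- pep_cohort("mix", samples)
  res <- allotype_frequencies("PEP", cohort, list(PEP = "A*02"))
  expect_equal(res$records$n_matched, 4L)
  expect_equal(res$records$frequency, 1.0)
  none <- allotype_frequencies("PEP", cohort, list(PEP = "C*07"))
  expect_true(is.na(none$records$frequency))  # no carriers: undefined
  skipped <- allotype_frequencies(c("PEP", "UNASSIGNED"), cohort,
                                  list(PEP = "A*02"))
  expect_equal(skipped$n_unassigned, 1L)
})

test_that("display filter retains the boundary and conserves records", {
  rec <- tibble::tibble(peptide = c("A", "B", "C"),
                        frequency = c(0.04, 0.05, 0.50))
  kept <- frequency_display_filter(rec, min_f = 0.05)
  expect_equal(kept$peptide, c("B", "C"))
  expect_equal(nrow(kept) + sum(rec$frequency < 0.05), nrow(rec))
})

test_that("replicate overlap fractions cover exhaustive categories", {
  s <- make_sample("S", list(R1 = c("A", "B"), R2 = "A", R3 = c("A", "C")))
  ov <- replicate_overlap(s)
  expect_equal(ov, c("1" = 2 / 3, "2" = 0, "3" = 1 / 3))
  expect_equal(sum(ov), 1)
  same <- make_sample("S", list(R1 = c("A", "B"), R2 = c("A", "B")))
  expect_equal(replicate_overlap(same)[["2"]], 1.0)
})

test_that("replicate overlap matches the conditional binomial closed form", {
  cfg <- generator_config(seed = 31, n_ligands = 2000L, n_proteins = 600L,
                          artifact_fraction = 0, p_detect = 0.8)
  study <- gen_proteolysis_cohort(cfg, n_samples = 1L)
  ov <- replicate_overlap(study$cohort$samples[[1]])
  p <- 0.8
  expected3 <- p^3 / (1 - (1 - p)^3)
  expect_equal(ov[["3"]], expected3, tolerance = 0.04)
})

test_that("donor-tissue overlap reports one-sample and all-sample fractions", {
  disjoint <- pep_cohort("d", list(
    make_sample("S1", list(R1 = c("A", "B")), donor = "D1", tissue = "liver"),
    make_sample("S2", list(R1 = c("C", "D")), donor = "D1", tissue = "colon")))
  res <- donor_tissue_overlap(disjoint)
  expect_equal(res$D1$fraction_one, 1.0)
  expect_equal(res$D1$fraction_all, 0.0)

  identical_t <- pep_cohort("d", list(
    make_sample("S1", list(R1 = c("A", "B")), donor = "D1"),
    make_sample("S2", list(R1 = c("A", "B")), donor = "D1")))
  res2 <- donor_tissue_overlap(identical_t)
  expect_equal(res2$D1$fraction_one, 0.0)
  expect_equal(res2$D1$fraction_all, 1.0)
  expect_equal(res2$D1$pairwise["S1", "S2"], 2L)

  single <- pep_cohort("d", list(make_sample("S1", list(R1 = "A"))))
  expect_message(res3 <- donor_tissue_overlap(single), "skipped")
  expect_length(res3, 0L)
})

test_that("TAA rejection percentage is order-invariant", {
  ref <- build_benign_reference(
    list(b = tibble::tibble(sequence = c("T1", "T2", "T3", "T4"))))
  taas <- c(sprintf("T%d", 1:4), sprintf("U%d", 1:6))
  rep <- taa_rejection_report(taas, ref)
  expect_equal(rep$pct_rejected, 40)
  expect_equal(sum(rep$table$rejected), 4L)
  shuffled <- taa_rejection_report(rev(taas), ref)
  expect_equal(shuffled$pct_rejected, 40)
  none <- taa_rejection_report(sprintf("U%d", 1:6), ref)
  expect_equal(none$pct_rejected, 0)
})
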