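# a flat predictor makes coverage-score tests independent of motif content
flat_predictor <- function(peptide, allotype) 0.5
`%+%` <- function(a, b) paste0(a, b)

test_that("protein coverage ratio counts union coverage over the protein", {
  proteome <- c(P1 = strrep("A", 45) %+% "KWFQRTYDES" %+% strrep("G", 45))
  lone <- tibble::tibble(sequence = "KWFQRTYDES", proteins = "P1")
  sc <- proteolysis_scores(lone, proteome, "A*02", flat_predictor)
  expect_equal(sc$s_prot, 0.10)
  expect_equal(sc$s_pep, 0.0)  # lone peptide

  proteome2 <- c(P1 = "KWFQRTYDES" %+% strrep("A", 40) %+%
                   "MNHCVILEDQ" %+% strrep("G", 40))
  two <- tibble::tibble(sequence = c("KWFQRTYDES", "MNHCVILEDQ"),
                        proteins = "P1")
  sc2 <- proteolysis_scores(two, proteome2, "A*02", flat_predictor)
  expect_equal(sc2$s_prot, c(0.20, 0.20))  # disjoint union
})

test_that("overlapping placements union their positions", {
  # 10-mers at offsets 1 and 6 of a 100-mer: union covers 15 positions
  core <- "KWFQRMNHCVILEDQ"  # 15 distinct-ish residues
  proteome <- c(P1 = core %+% strrep("G", 85))
  peps <- tibble::tibble(sequence = c(substr(core, 1, 10), substr(core, 6, 15)),
                         proteins = "P1")
  sc <- proteolysis_scores(peps, proteome, "A*02", flat_predictor)
  expect_equal(sc$s_prot, c(0.15, 0.15))
  # each 10-mer shares 5 of its 10 positions with the other
  expect_equal(sc$s_pep, c(0.5, 0.5))
})

test_that("nesting drives the peptide coverage ratio to one", {
  proteome <- c(P1 = strrep("A", 30) %+% "KWFQRMNHCVILEDQ" %+% strrep("G", 30))
  peps <- tibble::tibble(sequence = c("KWFQRMNHCVILEDQ", "RMNHCVILE"),
                         proteins = "P1")
  sc <- proteolysis_scores(peps, proteome, "A*02", flat_predictor)
  expect_equal(sc$s_pep[sc$sequence == "RMNHCVILE"], 1.0)  # fully nested
})

test_that("adding a nested peptide never decreases s_pep (monotonicity)", {
  set.seed(13)
  for (i in 1:5) {
    prot <- random_peptide(80)
    pep <- substr(prot, 20, 31)
    others <- tibble::tibble(sequence = c(pep, substr(prot, 50, 60)),
                             proteins = "P1")
    base <- proteolysis_scores(others, c(P1 = prot), "A*02", flat_predictor)
    nested <- rbind(others, tibble::tibble(sequence = substr(prot, 22, 29),
                                           proteins = "P1"))
    more <- proteolysis_scores(nested, c(P1 = prot), "A*02", flat_predictor)
    expect_gte(more$s_pep[more$sequence == pep],
               base$s_pep[base$sequence == pep])
  }
})

test_that("scores are invariant to accession renaming and row order", {
  prot <- "KWFQRMNHCVILEDQAGSTYPWDKLMRN" %+% strrep("A", 50)
  peps <- tibble::tibble(sequence = c(substr(prot, 1, 10), substr(prot, 5, 16),
                                      substr(prot, 40, 49)),
                         proteins = "P1")
  a <- proteolysis_scores(peps, c(P1 = prot), "A*02", flat_predictor)
  renamed <- peps
  renamed$proteins <- "XYZ_9"
  b <- proteolysis_scores(renamed[c(3, 1, 2), ], c(XYZ_9 = prot), "A*02",
                          flat_predictor)
  b <- b[match(a$sequence, b$sequence), ]
  expect_equal(a$s_prot, b$s_prot)
  expect_equal(a$s_pep, b$s_pep)
})

test_that("unmappable peptides raise an error naming the accession", {
  expect_error(
    proteolysis_scores(tibble::tibble(sequence = "WWWWWWWW", proteins = "P1"),
                       c(P1 = strrep("A", 50)), "A*02", flat_predictor),
    "WWWWWWWW.*P1")
})

test_that("non-ligand propensity inverts the best allotype likeness", {
  expect_equal(nonligand_propensity("AAAAAAAAA", "X",
                                    function(p, a) 1.0), 0.0)
  expect_equal(nonligand_propensity("AAAAAAAAA", c("X", "Y"),
                                    function(p, a) 0.0), 1.0)
  expect_equal(nonligand_propensity("AAAAAAAAA", c("X", "Y"),
                                    function(p, a) if (a == "X") 0.8 else 0.3),
               0.2)
  expect_error(nonligand_propensity("AAA", character(0)), "no allotypes")
  expect_error(nonligand_propensity("AAA", "X", function(p, a) stop("boom")),
               "predictor failed.*AAA")
})

test_that("PWM-drawn motif peptides score below shuffled controls on average", {
  set.seed(71)
  pwm <- default_pwms()[["A*02"]]
  pred <- pwm_predictor()
  motif <- replicate(100, pwm_sample(pwm, 9L))
  shuffled <- vapply(motif, function(p) {
    paste(sample(strsplit(p, "")[[1]]), collapse = "")
  }, character(1))
  s_motif <- nonligand_propensity(motif, "A*02", pred)
  s_shuf <- nonligand_propensity(shuffled, "A*02", pred)
  expect_lt(mean(s_motif), mean(s_shuf))
})

test_that("two-of-three rule calls exactly the majority patterns", {
  thresholds <- c(s_prot = 0.5, s_pep = 0.5, s_hla = 0.5)
  combos <- expand.grid(p = c(0, 1), c = c(0, 1), h = c(0, 1))
  scores <- tibble::tibble(sequence = sprintf("PEP%d", seq_len(nrow(combos))),
                           s_prot = combos$p, s_pep = combos$c,
                           s_hla = combos$h)
  calls <- classify_proteolytic(scores, thresholds)
  expect_equal(calls$is_proteolytic, rowSums(combos) >= 2)
  expect_equal(calls$n_exceeded, as.integer(rowSums(combos)))
})

test_that("threshold exceedance is strict", {
  thresholds <- c(s_prot = 0.5, s_pep = 0.5, s_hla = 0.5)
  at <- classify_proteolytic(tibble::tibble(sequence = "A", s_prot = 0.5,
                                            s_pep = 0.5, s_hla = 0.5),
                             thresholds)
  expect_false(at$is_proteolytic)
})

test_that("proteolysis report summarizes per-sample percentages", {
  calls <- list(
    S1 = tibble::tibble(sequence = sprintf("P%d", 1:100),
                        is_proteolytic = c(rep(TRUE, 2), rep(FALSE, 98))),
    S2 = tibble::tibble(sequence = sprintf("Q%d", 1:50),
                        is_proteolytic = c(rep(TRUE, 5), rep(FALSE, 45))),
    S3 = tibble::tibble(sequence = character(0),
                        is_proteolytic = logical(0))
  )
  expect_warning(rep <- proteolysis_report(calls), "empty sample.*S3")
  expect_equal(rep$per_sample$pct_proteolytic, c(2.0, 10.0))
  expect_equal(rep$median_pct, 6.0)
  expect_equal(rep$range_pct, c(2.0, 10.0))
  ann <- list(S1 = c(rep(FALSE, 2), rep(TRUE, 98)),
              S2 = c(FALSE, TRUE, rep(FALSE, 3), rep(TRUE, 45)))
  expect_warning(rep2 <- proteolysis_report(calls, ann))
  expect_equal(rep2$pct_proteolytic_not_ligand, 100 * 6 / 7)
})
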