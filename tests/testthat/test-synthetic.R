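test_that("proteome generation is byte-deterministic under a seed", {
  cfg <- generator_config(seed = 1, n_proteins = 10L)
  p1 <- gen_proteome(cfg)
  p2 <- gen_proteome(cfg)
  expect_identical(p1, p2)
  expect_length(p1, 10L)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(p1, f1)
  write_fasta(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated residue composition follows the stated background", {
  cfg <- generator_config(seed = 3, n_proteins = 2000L,
                          protein_length = c(500L, 500L))
  prot <- gen_proteome(cfg)  # 1e6 residues
  comp <- composition_profile(unname(prot))
  bg <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
          E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
          M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
          Y = 0.032, V = 0.073)
  bg <- bg / sum(bg)
  expect_true(all(abs(comp$freq[names(bg)] - bg) < 0.005))
})

test_that("class I samples are 9-mer dominated with ~70% weight", {
  cfg <- generator_config(seed = 5, n_ligands = 600L, artifact_fraction = 0)
  study <- gen_proteolysis_cohort(cfg, n_samples = 1L)
  lens <- length_distribution(sample_union(study$cohort$samples[[1]]))
  expect_equal(names(lens)[which.max(lens)], "9")
  expect_equal(lens[["9"]], 0.70, tolerance = 0.07)
})

test_that("artifact fraction zero gives all-ligand truth labels", {
  cfg <- generator_config(seed = 7, n_ligands = 60L, artifact_fraction = 0)
  study <- gen_proteolysis_cohort(cfg, n_samples = 2L)
  for (tr in study$truth) expect_true(all(tr$label == "ligand"))
})

test_that("planted ladders are overlapping fragment series with bounded steps", {
  cfg <- generator_config(seed = 9)
  study <- gen_proteolysis_cohort(cfg, n_samples = 1L)
  tr <- study$truth[[1]]
  arts <- tr$sequence[tr$label == "artifact"]
  expect_gte(length(arts), 4L)
  placements <- locate_peptides(
    tibble::tibble(sequence = arts, proteins = NA_character_), study$proteome)
  # all fragments of a sample's ladders sit on one degraded protein
  expect_length(unique(placements$accession), 1L)
  starts <- sort(unique(placements$start))
  # hotspot groups: consecutive starts within a ladder differ by <= 3
  gaps <- diff(starts)
  expect_gte(sum(gaps <= 3), 4L - 1L)
})

test_that("full detection makes replicates identical", {
  cfg <- generator_config(seed = 13, n_ligands = 50L, p_detect = 1)
  study <- gen_proteolysis_cohort(cfg, n_samples = 1L)
  reps <- replicate_sets(study$cohort$samples[[1]])
  expect_equal(sort(reps[[1]]), sort(reps[[2]]))
  expect_equal(sort(reps[[2]]), sort(reps[[3]]))
})

test_that("ligand peptides map back to the emitted proteome", {
  cfg <- generator_config(seed = 15, n_ligands = 80L)
  study <- gen_proteolysis_cohort(cfg, n_samples = 1L)
  tab <- study$cohort$samples[[1]]$replicates[[1]]
  expect_silent(locate_peptides(tab, study$proteome))
})

test_that("exact-count planting hits requested sample counts", {
  cfg <- generator_config(seed = 17, n_housekeeping = 60L,
                          planted_exclusives = data.frame(
                            frequency = 0.25, allotype = NA_character_))
  ch <- gen_cohorts(cfg)
  pl <- ch$truth$planted
  expect_equal(pl$n_positive, 5L)  # 0.25 x 20 tumor samples
  positives <- vapply(ch$tumor$samples, function(s) {
    pl$peptide %in% sample_union(s)
  }, logical(1))
  expect_equal(sum(positives), 5L)
  # planted peptides never occur in benign samples
  for (s in ch$benign$samples) {
    expect_false(pl$peptide %in% sample_union(s))
  }
})

test_that("non-integer plant counts are rounded with a recorded warning", {
  cfg <- generator_config(seed = 19, n_housekeeping = 40L, n_tumor = 10L,
                          planted_exclusives = data.frame(
                            frequency = 0.33, allotype = NA_character_))
  ch <- gen_cohorts(cfg)
  expect_length(ch$truth$warnings, 1L)
  expect_match(ch$truth$warnings, "rounded")
  expect_equal(ch$truth$planted$n_positive, 3L)
})

test_that("generated ligands out-score shuffled controls under the shared PWMs", {
  cfg <- generator_config(seed = 21, n_ligands = 120L, artifact_fraction = 0)
  study <- gen_proteolysis_cohort(cfg, n_samples = 1L)
  s <- study$cohort$samples[[1]]
  peps <- sample_union(s)[1:100]
  set.seed(22)
  shuf <- vapply(peps, function(p) paste(sample(strsplit(p, "")[[1]]),
                                         collapse = ""), character(1))
  prop_lig <- nonligand_propensity(peps, s$hla_typing, pwm_predictor(cfg$pwms))
  prop_shuf <- nonligand_propensity(shuf, s$hla_typing, pwm_predictor(cfg$pwms))
  expect_lt(mean(prop_lig), mean(prop_shuf))
})

test_that("spectrum pairs carry theoretical fragment m/z and shared intensities", {
  cfg <- generator_config(seed = 25, spectrum_noise_sd = 0, noise_peaks = 0)
  pair <- gen_spectrum_pair("SIINFEKL", config = cfg)
  lab <- data.frame(position = 8L, delta = cfg$label_delta)
  fr <- theoretical_fragments("SIINFEKL")
  fr_lab <- theoretical_fragments("SIINFEKL", lab)
  expect_equal(sort(pair$eluted$peaks[, "mz"]), sort(fr$mz), tolerance = 1e-6)
  expect_equal(sort(pair$synthetic$peaks[, "mz"]), sort(fr_lab$mz),
               tolerance = 1e-6)
  m <- spectral_correlation(pair$eluted, pair$synthetic, "SIINFEKL", lab)
  expect_equal(m$r_squared, 1.0, tolerance = 1e-12)
  noisy <- gen_spectrum_pair("SIINFEKL",
                             config = generator_config(seed = 25,
                                                       spectrum_noise_sd = 0.5))
  mn <- spectral_correlation(noisy$eluted, noisy$synthetic, "SIINFEKL", lab)
  expect_lt(mn$r_squared, 1.0)
})

test_that("bundles round-trip through disk", {
  cfg <- generator_config(seed = 27, n_housekeeping = 30L,
                          planted_exclusives = data.frame(
                            frequency = 0.5, allotype = NA_character_))
  ch <- gen_cohorts(cfg)
  dir <- tempfile()
  write_bundle(ch$proteome, list(benign = ch$benign, tumor = ch$tumor),
               ch$truth, dir)
  back <- load_cohort(dir)
  expect_named(back, c("benign", "tumor"))
  expect_equal(cohort_union(back$tumor), cohort_union(ch$tumor))
  expect_equal(cohort_union(back$benign), cohort_union(ch$benign))
  expect_equal(read_fasta(file.path(dir, "proteome.fasta")), ch$proteome)
  s0 <- ch$tumor$samples[[1]]
  sb <- back$tumor$samples[[1]]
  expect_equal(sb$hla_typing, s0$hla_typing)
  expect_equal(replicate_sets(sb), replicate_sets(s0))
})
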