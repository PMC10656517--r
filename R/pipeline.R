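#' Per-sample peptide tables of a cohort, keyed by sample id
#'
#' Convenience accessor used when a cohort itself serves as a benign
#' reference: one single-column peptide table per sample (the sample union),
#' so reference provenance records which sample contributed each peptide.
#'
#' @param cohort a [pep_cohort()].
#' @return named list of tibbles with a `sequence` column.
#' @export
cohort_datasets <- function(cohort) {
  out <- lapply(cohort$samples, function(s) {
    tibble::tibble(sequence = sample_union(s, il_collapse = cohort$il_collapsed))
  })
  names(out) <- vapply(cohort$samples, `[[`, character(1), "sample_id")
  out
}

#' Run the full synthetic-study pipeline
#'
#' End-to-end composition of the package's stages on generated data:
#' \enumerate{
#'   \item simulate a proteolysis study cohort and benign/tumor profiling
#'     cohorts (seeds derived from `config$seed`);
#'   \item score and classify proteolytic artifacts (per-sample mixtures and
#'     FDR thresholds, two-of-three rule) and compare calls against ground
#'     truth;
#'   \item assemble the benign reference from the benign cohort, compute
#'     tumor-exclusive peptides, cohort-wide and allotype-restricted
#'     presentation frequencies, display and broad-presentation subsets;
#'   \item generate an eluted/labelled-synthetic spectrum pair for a planted
#'     peptide and compute its b/y spectral correlation;
#'   \item write stage TSVs and a single JSON summary.
#' }
#' Reruns with the same config produce byte-identical summaries.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param alpha proteolysis FDR level.
#' @param min_f display-filter threshold (retain frequency >= `min_f`).
#' @param broad_f broad-presentation threshold (frequency > `broad_f`).
#' @param tol_ppm,tol_da fragment matching tolerances.
#' @param n_proteolysis_samples samples in the proteolysis study.
#' @return the summary list (invisibly the same content as `summary.json`).
#' @export
run_pipeline <- function(config = generator_config(), out_dir = NULL,
                         alpha = 0.05, min_f = 0.05, broad_f = 0.20,
                         tol_ppm = 20, tol_da = 0.02,
                         n_proteolysis_samples = 10L) {
  cfg_hash <- config_hash(config)

  # --- stage 1+2: proteolysis study -----------------------------------------
  cfg_prot <- config
  cfg_prot$seed <- config$seed
  study <- gen_proteolysis_cohort(cfg_prot, n_samples = n_proteolysis_samples)
  prot <- run_proteolysis(study$cohort, study$proteome,
                          pwm_predictor(config$pwms), alpha = alpha)
  perf <- classifier_performance(prot$calls, study$truth)
  annotated <- lapply(names(prot$calls), function(sid) {
    tab <- do.call(rbind, study$cohort$samples[[match(
      sid, vapply(study$cohort$samples, `[[`, character(1), "sample_id"))]]$replicates)
    ann <- !is.na(tab$binder[match(prot$calls[[sid]]$sequence, tab$sequence)])
    ann
  })
  names(annotated) <- names(prot$calls)
  report <- proteolysis_report(prot$calls, annotated)

  # --- stage 3: comparative profiling ---------------------------------------
  cfg_prof <- config
  cfg_prof$seed <- config$seed + 1L
  cohorts <- gen_cohorts(cfg_prof)
  reference <- build_benign_reference(cohort_datasets(cohorts$benign))
  profiling <- tumor_exclusive(cohorts$tumor, reference)
  freqs <- presentation_frequencies(profiling$exclusive, cohorts$tumor)
  displayed <- frequency_display_filter(freqs, min_f = min_f)
  broad <- freqs[freqs$frequency > broad_f, , drop = FALSE]
  planted <- cohorts$truth$planted
  restricted <- planted[!is.na(planted$allotype), , drop = FALSE]
  assignment <- stats::setNames(as.list(restricted$allotype), restricted$peptide)
  allo_freqs <- allotype_frequencies(restricted$peptide, cohorts$tumor,
                                     assignment)

  # --- stage 4: spectral validation -----------------------------------------
  cfg_spec <- config
  cfg_spec$seed <- config$seed + 2L
  val_pep <- unname(planted$peptide[which.max(planted$frequency)])
  pair <- gen_spectrum_pair(val_pep, config = cfg_spec)
  match <- spectral_correlation(pair$eluted, pair$synthetic, val_pep,
                                labels = data.frame(position = nchar(val_pep),
                                                    delta = config$label_delta),
                                tol_ppm = tol_ppm, tol_da = tol_da)

  # --- stage 5: summary ------------------------------------------------------
  summary <- list(
    tool = list(package = "immunopepR",
                version = as.character(utils::packageVersion("immunopepR")),
                config_hash = cfg_hash, seed = config$seed),
    parameters = list(alpha = alpha, min_f = min_f, broad_f = broad_f,
                      tol_ppm = tol_ppm, tol_da = tol_da),
    proteolysis = list(
      n_samples = length(prot$calls),
      median_pct_proteolytic = report$median_pct,
      range_pct_proteolytic = report$range_pct,
      recall = perf$recall, empirical_fdr = perf$fdr,
      pct_proteolytic_not_ligand = report$pct_proteolytic_not_ligand),
    profiling = list(
      n_tumor_union = length(profiling$exclusive) + length(profiling$rejected),
      n_exclusive = length(profiling$exclusive),
      n_rejected = length(profiling$rejected),
      n_planted = nrow(planted),
      planted_recovered = sum(planted$peptide %in% profiling$exclusive),
      exclusive_equals_planted =
        setequal(profiling$exclusive, planted$peptide),
      n_displayed = nrow(displayed), n_broad = nrow(broad)),
    spectral_validation = list(
      peptide = val_pep, r_squared = match$r_squared,
      n_matched = match$n_matched)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    header <- sprintf("# immunopepR %s config %s",
                      summary$tool$version, cfg_hash)
    write_tsv_with_header <- function(tab, file) {
      path <- file.path(out_dir, file)
      con <- file(path, "w")
      writeLines(header, con)
      close(con)
      suppressWarnings(utils::write.table(tab, path, sep = "\t",
                                          row.names = FALSE, quote = FALSE,
                                          append = TRUE))
      path
    }
    calls_tab <- do.call(rbind, Map(function(sid, tab) {
      cbind(sample = sid, tab)
    }, names(prot$calls), prot$calls))
    write_tsv_with_header(calls_tab, "proteolysis_calls.tsv")
    write_tsv_with_header(report$per_sample, "proteolysis_summary.tsv")
    write_tsv_with_header(
      tibble::tibble(peptide = profiling$exclusive), "exclusive_peptides.tsv")
    write_tsv_with_header(freqs, "presentation_frequencies.tsv")
    allo_tab <- allo_freqs$records
    allo_tab$frequency <- round(allo_tab$frequency, 10)
    write_tsv_with_header(allo_tab, "allotype_frequencies.tsv")
    write_tsv_with_header(match$table, "spectral_match.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}

#' Classifier performance against generator ground truth
#'
#' Recall of planted artifacts and empirical false discovery rate among
#' proteolytic calls, pooled over samples.
#'
#' @param calls named list of classification tibbles from [run_proteolysis()].
#' @param truth named list of tibbles with `sequence` and `label`
#'   (`"artifact"`/`"ligand"`), as produced by [gen_proteolysis_cohort()].
#' @return list with `recall`, `fdr`, `n_called`, `n_artifacts`.
#' @export
classifier_performance <- function(calls, truth) {
  tp <- fp <- fn <- 0L
  for (sid in names(calls)) {
    called <- calls[[sid]]$sequence[calls[[sid]]$is_proteolytic]
    art <- truth[[sid]]$sequence[truth[[sid]]$label == "artifact"]
    tp <- tp + length(intersect(called, art))
    fp <- fp + length(setdiff(called, art))
    fn <- fn + length(setdiff(art, called))
  }
  list(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       n_called = tp + fp, n_artifacts = tp + fn)
}

#' Deterministic hash of a pipeline/generator configuration
#'
#' MD5 of the canonical JSON serialization of the config (PWM matrices
#' included), used to stamp outputs with provenance.
#'
#' @param config any serializable list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  tf <- tempfile()
  writeLines(js, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}
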