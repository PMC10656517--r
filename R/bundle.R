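#' Write a simulated study bundle to disk
#'
#' Emits the directory tree the pipeline consumes: `proteome.fasta`,
#' per-replicate peptide TSVs under `samples/`, `metadata.yaml` describing the
#' cohorts, and `ground_truth.json` with the generator's bookkeeping. Output
#' is byte-deterministic for a given bundle.
#'
#' @param proteome named character vector of protein sequences.
#' @param cohorts named list of [pep_cohort()] objects.
#' @param truth ground-truth list (serialized as JSON), or `NULL`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(proteome, cohorts, truth = NULL, dir) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(proteome, file.path(dir, "proteome.fasta"))
  meta <- list(cohorts = list())
  for (cname in names(cohorts)) {
    cohort <- cohorts[[cname]]
    csamples <- list()
    for (s in cohort$samples) {
      rel <- list()
      for (rname in names(s$replicates)) {
        fname <- file.path("samples", paste0(s$sample_id, "_", rname, ".tsv"))
        write_peptide_table(s$replicates[[rname]], file.path(dir, fname),
                            sep = "\t")
        rel[[rname]] <- fname
      }
      csamples[[length(csamples) + 1L]] <- list(
        sample_id = s$sample_id, donor_id = s$donor_id, tissue = s$tissue,
        cohort_label = s$cohort_label, hla_class = s$hla_class,
        hla_typing = as.list(s$hla_typing), replicates = rel)
    }
    meta$cohorts[[length(meta$cohorts) + 1L]] <- list(
      name = cohort$name, il_collapsed = cohort$il_collapsed,
      samples = csamples)
  }
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  invisible(dir)
}
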