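#' Replicate-resolved sample immunopeptidome
#'
#' Container for one sample's identified peptides: a named list of replicate
#' peptide tables plus the metadata the comparative steps need (donor, tissue,
#' cohort role, HLA class and typing).
#'
#' @param sample_id,donor_id,tissue character identifiers.
#' @param cohort_label one of `"benign"`, `"tumor"`, `"cell_line"`.
#' @param hla_class `"I"` or `"II"`.
#' @param hla_typing character vector of allotype strings (e.g. `"A*02"`).
#' @param replicates named list (replicate id -> peptide table as returned by
#'   [read_peptide_table()], or a character vector of sequences).
#' @return an object of class `pep_sample`.
#' @export
pep_sample <- function(sample_id, donor_id, tissue, cohort_label, hla_class,
                       hla_typing, replicates) {
  cohort_label <- match.arg(cohort_label, c("benign", "tumor", "cell_line"))
  hla_class <- match.arg(hla_class, c("I", "II"))
  if (length(replicates) < 1L) stop("at least one replicate required", call. = FALSE)
  if (is.null(names(replicates)) || anyDuplicated(names(replicates)) ||
      any(!nzchar(names(replicates)))) {
    stop("replicates must have unique non-empty names", call. = FALSE)
  }
  if (length(hla_typing) > 0L && any(!nzchar(hla_typing))) {
    stop("allotype strings must be non-empty", call. = FALSE)
  }
  replicates <- lapply(replicates, function(r) {
    if (is.character(r)) r <- tibble::tibble(sequence = r)
    stopifnot(is.data.frame(r), "sequence" %in% names(r))
    r
  })
  structure(list(sample_id = sample_id, donor_id = donor_id, tissue = tissue,
                 cohort_label = cohort_label, hla_class = hla_class,
                 hla_typing = as.character(hla_typing), replicates = replicates),
            class = "pep_sample")
}

#' @export
print.pep_sample <- function(x, ...) {
  cat(sprintf("<pep_sample '%s'> donor %s, %s (%s, HLA-%s), %d replicate(s), %d peptides (union)\n",
              x$sample_id, x$donor_id, x$tissue, x$cohort_label, x$hla_class,
              length(x$replicates), length(sample_union(x))))
  invisible(x)
}

#' Per-replicate canonical identity sets
#'
#' @param sample a [pep_sample()].
#' @param il_collapse collapse I/L in identities?
#' @return list of character vectors (one per replicate, unique identities).
#' @export
replicate_sets <- function(sample, il_collapse = FALSE) {
  lapply(sample$replicates, function(r) {
    unique(canonical_sequence(r, il_collapse = il_collapse))
  })
}

#' Sample union peptide set
#'
#' A sample is positive for a peptide if any replicate contains it: the union
#' over replicates of canonical identities.
#'
#' @inheritParams replicate_sets
#' @return character vector of unique identities.
#' @export
sample_union <- function(sample, il_collapse = FALSE) {
  sort(unique(unlist(replicate_sets(sample, il_collapse), use.names = FALSE)))
}

#' Cohort of sample immunopeptidomes
#'
#' @param name cohort name.
#' @param samples list of [pep_sample()] objects with unique sample ids.
#' @param il_collapsed whether identities in this cohort are compared with I/L
#'   collapsed.
#' @return an object of class `pep_cohort`.
#' @export
pep_cohort <- function(name, samples, il_collapsed = FALSE) {
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, samples = samples,
                 il_collapsed = isTRUE(il_collapsed)),
            class = "pep_cohort")
}

#' @export
print.pep_cohort <- function(x, ...) {
  cat(sprintf("<pep_cohort '%s'> %d samples, %d unique peptides (union)%s\n",
              x$name, length(x$samples), length(cohort_union(x)),
              if (x$il_collapsed) ", I/L collapsed" else ""))
  invisible(x)
}

#' Cohort-wide union of canonical peptide identities
#'
#' @param cohort a [pep_cohort()].
#' @return sorted character vector of identities.
#' @export
cohort_union <- function(cohort) {
  sort(unique(unlist(lapply(cohort$samples, sample_union,
                            il_collapse = cohort$il_collapsed),
                     use.names = FALSE)))
}

#' Load a cohort from a simulated (or real) bundle directory
#'
#' Reads `metadata.yaml` plus the per-replicate peptide tables it references.
#' The metadata layout is the one written by [write_bundle()]: a `cohorts`
#' list, each with `name`, `il_collapsed` and `samples`, each sample carrying
#' `sample_id`, `donor_id`, `tissue`, `cohort_label`, `hla_class`,
#' `hla_typing` and a named `replicates` map of relative table paths.
#'
#' @param dir bundle directory.
#' @param name cohort name to load (default: all cohorts).
#' @return a [pep_cohort()] (or named list of them when `name` is `NULL`).
#' @export
load_cohort <- function(dir, name = NULL) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  build <- function(cmeta) {
    samples <- lapply(cmeta$samples, function(sm) {
      reps <- lapply(sm$replicates, function(p) {
        read_peptide_table(file.path(dir, p), peptide_dialect_tsv())
      })
      pep_sample(sm$sample_id, sm$donor_id, sm$tissue, sm$cohort_label,
                 sm$hla_class, unlist(sm$hla_typing), reps)
    })
    pep_cohort(cmeta$name, samples, il_collapsed = isTRUE(cmeta$il_collapsed))
  }
  cohorts <- lapply(meta$cohorts, build)
  names(cohorts) <- vapply(meta$cohorts, `[[`, character(1), "name")
  if (is.null(name)) cohorts else cohorts[[name]]
}

#' Tab-separated peptide-table dialect
#'
#' @return dialect list for [read_peptide_table()] with tab separation.
#' @export
peptide_dialect_tsv <- function() {
  d <- peptide_dialect()
  d$sep <- "\t"
  d
}
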