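#' Assemble a filtered benign reference peptidome
#'
#' Unions peptide identities from several benign datasets after applying
#' per-dataset filter rules (binder-strength whitelists and metadata equality
#' filters, mirroring how public ligand repositories are curated before use
#' as a benign reference). Provenance — which dataset(s) contributed each
#' peptide — is retained.
#'
#' @param datasets named list of peptide tables.
#' @param filter_rules named list (per dataset) of rules: `binder_strengths`
#'   (keep rows whose `binder` annotation contains one of these strengths for
#'   any allotype) and `equals` (named list column -> required value).
#'   Datasets without rules are taken whole.
#' @param il_collapse canonicalization flag for the reference identities.
#' @return list of class `benign_reference`: `peptides` (sorted identity
#'   vector), `provenance` (named list identity -> dataset tags),
#'   `il_collapsed`.
#' @export
build_benign_reference <- function(datasets, filter_rules = list(),
                                   il_collapse = FALSE) {
  stopifnot(!is.null(names(datasets)))
  provenance <- list()
  for (ds in names(datasets)) {
    tab <- datasets[[ds]]
    rules <- filter_rules[[ds]]
    if (!is.null(rules$binder_strengths)) {
      if (!"binder" %in% names(tab)) {
        stop("filter for dataset '", ds, "' references missing column 'binder'",
             call. = FALSE)
      }
      keep <- vapply(tab$binder, function(b) {
        if (is.na(b)) return(FALSE)
        strengths <- sub("^.*=", "", strsplit(b, ";", fixed = TRUE)[[1]])
        any(strengths %in% rules$binder_strengths)
      }, logical(1), USE.NAMES = FALSE)
      tab <- tab[keep, , drop = FALSE]
    }
    for (col in names(rules$equals %||% list())) {
      if (!col %in% names(tab)) {
        stop("filter for dataset '", ds, "' references missing column '", col,
             "'", call. = FALSE)
      }
      tab <- tab[!is.na(tab[[col]]) & tab[[col]] == rules$equals[[col]], ,
                 drop = FALSE]
    }
    if (nrow(tab) == 0L) {
      warning("dataset '", ds, "' contributes no peptides after filtering")
      next
    }
    ids <- unique(canonical_sequence(tab, il_collapse = il_collapse))
    for (id in ids) provenance[[id]] <- c(provenance[[id]], ds)
  }
  structure(list(peptides = sort(names(provenance)), provenance = provenance,
                 il_collapsed = isTRUE(il_collapse)),
            class = "benign_reference")
}

#' @export
print.benign_reference <- function(x, ...) {
  cat(sprintf("<benign_reference> %d peptides from %d dataset(s)%s\n",
              length(x$peptides),
              length(unique(unlist(x$provenance))),
              if (x$il_collapsed) ", I/L collapsed" else ""))
  invisible(x)
}

#' Tumor-exclusive peptides against a benign reference
#'
#' Splits the tumor cohort's union peptide set into peptides never seen in the
#' benign reference (exclusive) and peptides rejected because a benign dataset
#' contains them (with the benign sources that caused the rejection).
#'
#' @param tumor_cohort a [pep_cohort()].
#' @param benign_reference a [build_benign_reference()] result.
#' @return list of class `profiling_result`: `exclusive`, `rejected`
#'   (character vectors, disjoint, union = cohort union), `rejected_sources`
#'   (named list).
#' @export
tumor_exclusive <- function(tumor_cohort, benign_reference) {
  if (!identical(tumor_cohort$il_collapsed, benign_reference$il_collapsed)) {
    stop("cohort and benign reference use different I/L canonicalization",
         call. = FALSE)
  }
  universe <- cohort_union(tumor_cohort)
  rejected <- intersect(universe, benign_reference$peptides)
  exclusive <- setdiff(universe, rejected)
  structure(list(exclusive = sort(exclusive), rejected = sort(rejected),
                 rejected_sources = benign_reference$provenance[rejected]),
            class = "profiling_result")
}

#' @export
print.profiling_result <- function(x, ...) {
  cat(sprintf("<profiling_result> %d exclusive, %d rejected (%.1f%% exclusive)\n",
              length(x$exclusive), length(x$rejected),
              100 * length(x$exclusive) /
                max(length(x$exclusive) + length(x$rejected), 1L)))
  invisible(x)
}

#' Cohort-wide presentation frequencies
#'
#' For each peptide, the fraction of cohort samples whose union peptide set
#' contains it. Output is sorted by frequency (descending), then identity
#' (ascending), and carries auditable integer counts.
#'
#' @param peptides character vector of canonical identities.
#' @param cohort a [pep_cohort()].
#' @return tibble with `peptide`, `n_positive`, `n_total`, `frequency`.
#' @export
presentation_frequencies <- function(peptides, cohort) {
  unions <- lapply(cohort$samples, sample_union,
                   il_collapse = cohort$il_collapsed)
  n_total <- length(unions)
  n_pos <- vapply(peptides, function(p) {
    sum(vapply(unions, function(u) p %in% u, logical(1)))
  }, integer(1), USE.NAMES = FALSE)
  out <- tibble::tibble(peptide = peptides, n_positive = n_pos,
                        n_total = n_total, frequency = n_pos / n_total)
  out[order(-out$frequency, out$peptide), , drop = FALSE]
}

#' Allotype-restricted presentation frequencies
#'
#' Frequencies over the HLA-matched sub-cohort only: for a peptide assigned to
#' allotype `a`, the denominator is the number of samples carrying `a` and the
#' numerator the positives among them.
#'
#' @param peptides character vector of identities.
#' @param cohort a [pep_cohort()].
#' @param allotype_assignment named list peptide -> character vector of
#'   assigned allotype(s); peptides with no assignment are excluded and
#'   counted.
#' @return list with `records` (tibble: `peptide`, `allotype`, `n_positive`,
#'   `n_matched`, `frequency` — `NA` when no sample carries the allotype) and
#'   `n_unassigned`.
#' @export
allotype_frequencies <- function(peptides, cohort, allotype_assignment) {
  unions <- lapply(cohort$samples, sample_union,
                   il_collapse = cohort$il_collapsed)
  typing <- lapply(cohort$samples, `[[`, "hla_typing")
  rows <- list()
  n_unassigned <- 0L
  for (p in peptides) {
    allos <- allotype_assignment[[p]]
    if (is.null(allos) || length(allos) == 0L) {
      n_unassigned <- n_unassigned + 1L
      next
    }
    for (a in allos) {
      carriers <- vapply(typing, function(t) a %in% t, logical(1))
      n_matched <- sum(carriers)
      n_pos <- sum(vapply(which(carriers), function(i) p %in% unions[[i]],
                          logical(1)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        peptide = p, allotype = a, n_positive = n_pos, n_matched = n_matched,
        frequency = if (n_matched > 0L) n_pos / n_matched else NA_real_)
    }
  }
  records <- if (length(rows) > 0L) do.call(rbind, rows) else
    tibble::tibble(peptide = character(), allotype = character(),
                   n_positive = integer(), n_matched = integer(),
                   frequency = numeric())
  list(records = records, n_unassigned = n_unassigned)
}

#' Display filter on presentation frequencies
#'
#' Drops peptides presented on fewer than `min_f` of samples (strictly below;
#' the boundary is retained), the readability filter applied before frequency
#' plots.
#'
#' @param records frequency tibble with a `frequency` column.
#' @param min_f minimum retained frequency (default 0.05).
#' @return the retained records, original sort order preserved.
#' @export
frequency_display_filter <- function(records, min_f = 0.05) {
  records[!is.na(records$frequency) & records$frequency >= min_f, ,
          drop = FALSE]
}

#' Technical-replicate overlap within a sample
#'
#' Over the sample's union peptide set, the fraction of peptides detected in
#' exactly 1, 2, ..., R replicates.
#'
#' @param sample a [pep_sample()].
#' @param il_collapse canonicalization flag.
#' @return named numeric vector over 1..R, summing to 1.
#' @export
replicate_overlap <- function(sample, il_collapse = FALSE) {
  sets <- replicate_sets(sample, il_collapse)
  R <- length(sets)
  counts <- table(factor(unlist(sets, use.names = FALSE), exclude = NULL))
  k <- table(factor(as.integer(counts), levels = seq_len(R)))
  out <- as.numeric(k) / sum(k)
  names(out) <- seq_len(R)
  out
}

#' Peptide overlap across tissues of one donor
#'
#' For each donor with at least two samples: the fraction of the donor's union
#' peptides found in exactly one of their samples, the fraction found in all
#' of them, and a pairwise overlap-count matrix (chord-plot input).
#'
#' @param cohort a [pep_cohort()]; samples are grouped by `donor_id`.
#' @return named list per donor: `n_samples`, `fraction_one`, `fraction_all`,
#'   `pairwise` (matrix of shared-peptide counts). Single-sample donors are
#'   skipped with a message.
#' @export
donor_tissue_overlap <- function(cohort) {
  donors <- split(cohort$samples,
                  vapply(cohort$samples, `[[`, character(1), "donor_id"))
  out <- list()
  for (d in names(donors)) {
    samples <- donors[[d]]
    if (length(samples) < 2L) {
      message("donor ", d, " has a single sample; skipped")
      next
    }
    unions <- lapply(samples, sample_union, il_collapse = cohort$il_collapsed)
    names(unions) <- vapply(samples, `[[`, character(1), "sample_id")
    counts <- table(unlist(unions, use.names = FALSE))
    pw <- outer(seq_along(unions), seq_along(unions),
                Vectorize(function(i, j) length(intersect(unions[[i]], unions[[j]]))))
    dimnames(pw) <- list(names(unions), names(unions))
    out[[d]] <- list(n_samples = length(samples),
                     fraction_one = mean(counts == 1L),
                     fraction_all = mean(counts == length(samples)),
                     pairwise = pw)
  }
  out
}

#' Tumor-associated antigen rejection report
#'
#' Checks a published TAA peptide list against a benign reference: a TAA found
#' in any benign dataset is rejected (it is not tumor-exclusive anymore), and
#' its benign sources are reported.
#'
#' @param taa_peptides character vector (or peptide table) of TAA sequences.
#' @param benign_reference a [build_benign_reference()] result.
#' @return list with `table` (tibble: `peptide`, `rejected`, `benign_sources`)
#'   and `pct_rejected`.
#' @export
taa_rejection_report <- function(taa_peptides, benign_reference) {
  if (is.data.frame(taa_peptides)) taa_peptides <- taa_peptides$sequence
  ids <- unique(canonical_sequence(taa_peptides,
                                   il_collapse = benign_reference$il_collapsed))
  rejected <- ids %in% benign_reference$peptides
  sources <- vapply(ids, function(p) {
    paste(benign_reference$provenance[[p]] %||% character(0), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  list(table = tibble::tibble(peptide = ids, rejected = rejected,
                              benign_sources = sources),
       pct_rejected = 100 * mean(rejected))
}
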