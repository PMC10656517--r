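#' Locate peptides on their source proteins
#'
#' Exact substring search of each peptide against its claimed source
#' protein(s). Every placement is returned (a peptide may occur several times
#' in one protein).
#'
#' @param tab peptide table with `sequence` and `proteins` columns.
#' @param proteome named character vector from [read_fasta()].
#' @return tibble with `sequence`, `accession`, `start`, `end` (1-based,
#'   inclusive).
#' @export
locate_peptides <- function(tab, proteome) {
  seqs <- unique(tab$sequence)
  prot_of <- split(tab$proteins, tab$sequence)
  rows <- list()
  for (pep in seqs) {
    accs <- unique(unlist(strsplit(stats::na.omit(prot_of[[pep]]), ";", fixed = TRUE)))
    accs <- trimws(accs[nzchar(trimws(accs))])
    if (length(accs) == 0L) accs <- names(proteome)  # no claim: search all
    hits <- 0L
    for (acc in accs) {
      target <- proteome[[acc]]
      if (is.null(target) || is.na(target)) next
      starts <- gregexpr(pep, target, fixed = TRUE)[[1]]
      if (starts[1] == -1L) next
      hits <- hits + length(starts)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sequence = pep, accession = acc, start = as.integer(starts),
        end = as.integer(starts) + nchar(pep) - 1L)
    }
    if (hits == 0L) {
      stop("peptide ", pep, " is not a substring of claimed protein(s): ",
           paste(accs, collapse = ", "), call. = FALSE)
    }
  }
  do.call(rbind, rows)
}

# per-protein count, at each residue position, of DISTINCT peptides covering it
protein_cover_counts <- function(placements, proteome) {
  out <- list()
  for (acc in unique(placements$accession)) {
    sub <- placements[placements$accession == acc, , drop = FALSE]
    cnt <- integer(nchar(proteome[[acc]]))
    for (pep in unique(sub$sequence)) {
      own <- sub[sub$sequence == pep, , drop = FALSE]
      mask <- logical(length(cnt))
      for (k in seq_len(nrow(own))) mask[own$start[k]:own$end[k]] <- TRUE
      cnt[mask] <- cnt[mask] + 1L
    }
    out[[acc]] <- cnt
  }
  out
}

#' Proteolysis score triple for every peptide of a sample
#'
#' Computes the three artifact-evidence scores, all oriented so that larger
#' means more artifact-like:
#' \describe{
#'   \item{`s_prot`}{protein coverage ratio: for each source protein, the
#'     fraction of its residues covered by the union of all identified
#'     peptides mapping to it; the peptide takes the maximum over its source
#'     proteins. Degradation hotspots drive this up.}
#'   \item{`s_pep`}{peptide coverage ratio: the fraction of the peptide's own
#'     residues (at its best protein placement) also covered by at least one
#'     other identified peptide — nested/overlapping ladder evidence; 0 for a
#'     lone peptide.}
#'   \item{`s_hla`}{non-ligand propensity: `1 -` the maximum ligand-likeness
#'     over the sample's HLA allotypes under `predictor`.}
#' }
#'
#' @param tab peptide table (`sequence`, `proteins`).
#' @param proteome named character vector from [read_fasta()].
#' @param allotypes the sample's HLA allotypes.
#' @param predictor ligand-likeness function, e.g. [pwm_predictor()].
#' @return tibble with `sequence`, `s_prot`, `s_pep`, `s_hla` (one row per
#'   unique peptide).
#' @export
proteolysis_scores <- function(tab, proteome, allotypes,
                               predictor = pwm_predictor()) {
  placements <- locate_peptides(tab, proteome)
  counts <- protein_cover_counts(placements, proteome)
  seqs <- unique(tab$sequence)

  s_prot <- s_pep <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    pl <- placements[placements$sequence == seqs[i], , drop = FALSE]
    ratios <- vapply(unique(pl$accession), function(acc) {
      sum(counts[[acc]] > 0L) / length(counts[[acc]])
    }, numeric(1))
    s_prot[i] <- max(ratios)
    best_acc <- unique(pl$accession)[which.max(ratios)]
    best <- pl[pl$accession == best_acc, , drop = FALSE][1L, ]
    span <- best$start:best$end
    s_pep[i] <- mean(counts[[best_acc]][span] >= 2L)
  }
  s_hla <- nonligand_propensity(seqs, allotypes, predictor)
  tibble::tibble(sequence = seqs, s_prot = s_prot, s_pep = s_pep, s_hla = s_hla)
}

#' Non-ligand propensity score
#'
#' `1 - max` ligand-likeness over the sample's allotypes: high for peptides
#' that fit none of the sample's HLA binding motifs (artifact-like), low for
#' motif-consistent ligands.
#'
#' @param peptides character vector of sequences.
#' @param allotypes non-empty character vector of allotypes.
#' @param predictor function `(peptide, allotype) -> [0, 1]`.
#' @return numeric vector in \[0, 1\].
#' @export
nonligand_propensity <- function(peptides, allotypes,
                                 predictor = pwm_predictor()) {
  if (length(allotypes) == 0L) stop("no allotypes provided", call. = FALSE)
  vapply(peptides, function(p) {
    likeness <- vapply(allotypes, function(a) {
      s <- tryCatch(predictor(p, a),
                    error = function(e) stop("predictor failed for peptide ", p,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
      s
    }, numeric(1))
    1 - max(likeness)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Fit per-score mixtures and FDR thresholds
#'
#' One two-component Gaussian mixture per score column and the corresponding
#' FDR-controlled cutoff.
#'
#' @param scores tibble from [proteolysis_scores()] (possibly pooled).
#' @param alpha FDR level (default 0.05).
#' @param ... passed to [fit_gaussian_mixture()].
#' @return an object of class `threshold_set`: named `thresholds`, `fits`,
#'   `alpha`.
#' @export
fit_thresholds <- function(scores, alpha = 0.05, ...) {
  score_cols <- c("s_prot", "s_pep", "s_hla")
  fits <- lapply(score_cols, function(k) fit_gaussian_mixture(scores[[k]], ...))
  names(fits) <- score_cols
  thresholds <- vapply(fits, function(f) {
    if (isTRUE(f$converged)) fdr_threshold(f, alpha) else Inf
  }, numeric(1))
  structure(list(thresholds = thresholds, fits = fits, alpha = alpha),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> alpha = %.3g; t = (%s)\n", x$alpha,
              paste(sprintf("%s %.4f", names(x$thresholds), x$thresholds),
                    collapse = ", ")))
  invisible(x)
}

#' Two-of-three proteolytic classification
#'
#' A peptide is called proteolytic when it strictly exceeds at least two of
#' the three score thresholds.
#'
#' @param scores tibble from [proteolysis_scores()].
#' @param threshold_set a [fit_thresholds()] result (or a named numeric vector
#'   of three thresholds).
#' @return tibble with `sequence`, the scores, `exceeds_prot`, `exceeds_pep`,
#'   `exceeds_hla`, `n_exceeded` and `is_proteolytic`.
#' @export
classify_proteolytic <- function(scores, threshold_set) {
  t <- if (inherits(threshold_set, "threshold_set")) threshold_set$thresholds
       else threshold_set
  ep <- scores$s_prot > t[["s_prot"]]
  ec <- scores$s_pep > t[["s_pep"]]
  eh <- scores$s_hla > t[["s_hla"]]
  n <- ep + ec + eh
  tibble::tibble(sequence = scores$sequence,
                 s_prot = scores$s_prot, s_pep = scores$s_pep,
                 s_hla = scores$s_hla,
                 exceeds_prot = ep, exceeds_pep = ec, exceeds_hla = eh,
                 n_exceeded = as.integer(n), is_proteolytic = n >= 2L)
}

#' Run the proteolytic-artifact classifier over a cohort
#'
#' Scores every sample, fits mixtures and FDR thresholds (per sample by
#' default, or on the pooled cohort scores), and applies the two-of-three
#' rule.
#'
#' @param cohort a [pep_cohort()].
#' @param proteome named character vector from [read_fasta()].
#' @param predictor ligand-likeness predictor.
#' @param alpha FDR level.
#' @param pooling `"sample"` (fit thresholds within each sample) or
#'   `"cohort"` (pool scores across samples).
#' @return list with per-sample `calls` (named list of classification
#'   tibbles), `thresholds` (per sample or one pooled set) and `scores`.
#' @export
run_proteolysis <- function(cohort, proteome, predictor = pwm_predictor(),
                            alpha = 0.05, pooling = c("sample", "cohort")) {
  pooling <- match.arg(pooling)
  per_sample <- lapply(cohort$samples, function(s) {
    tab <- do.call(rbind, lapply(s$replicates, function(r) {
      r[, intersect(c("sequence", "proteins"), names(r)), drop = FALSE]
    }))
    tab <- tab[!duplicated(tab$sequence), , drop = FALSE]
    proteolysis_scores(tab, proteome, s$hla_typing, predictor)
  })
  names(per_sample) <- vapply(cohort$samples, `[[`, character(1), "sample_id")

  if (pooling == "cohort") {
    pooled <- do.call(rbind, per_sample)
    ts <- fit_thresholds(pooled, alpha)
    calls <- lapply(per_sample, classify_proteolytic, threshold_set = ts)
    thresholds <- ts
  } else {
    thresholds <- lapply(per_sample, fit_thresholds, alpha = alpha)
    calls <- Map(classify_proteolytic, per_sample, thresholds)
  }
  list(calls = calls, thresholds = thresholds, scores = per_sample)
}

#' Cohort proteolysis summary
#'
#' Per-sample percentage of peptides called proteolytic, the cohort median and
#' range, and (when ligand annotations are available) a cross-tabulation of
#' proteolytic calls against HLA-ligand annotation.
#'
#' @param calls named list of classification tibbles from [run_proteolysis()].
#' @param ligand_annotated optional named list (per sample) of logical vectors
#'   aligned with each call tibble: was the peptide annotated as an HLA
#'   ligand?
#' @return list with `per_sample` (tibble: sample, n, n_proteolytic,
#'   pct_proteolytic), `median_pct`, `range_pct` and optional `cross_tab`.
#' @export
proteolysis_report <- function(calls, ligand_annotated = NULL) {
  keep <- vapply(calls, nrow, integer(1)) > 0L
  if (any(!keep)) {
    warning("excluding empty sample(s): ",
            paste(names(calls)[!keep], collapse = ", "))
    calls <- calls[keep]
  }
  per_sample <- tibble::tibble(
    sample = names(calls),
    n = unname(vapply(calls, nrow, integer(1))),
    n_proteolytic = unname(vapply(calls, function(x) sum(x$is_proteolytic),
                                  integer(1)))
  )
  per_sample$pct_proteolytic <- 100 * per_sample$n_proteolytic / per_sample$n
  out <- list(per_sample = per_sample,
              median_pct = stats::median(per_sample$pct_proteolytic),
              range_pct = range(per_sample$pct_proteolytic))
  if (!is.null(ligand_annotated)) {
    prot <- unlist(lapply(calls, `[[`, "is_proteolytic"), use.names = FALSE)
    lig <- unlist(ligand_annotated[names(calls)], use.names = FALSE)
    out$cross_tab <- table(proteolytic = prot, ligand_annotated = lig)
    out$pct_proteolytic_not_ligand <-
      100 * sum(prot & !lig) / max(sum(prot), 1L)
  }
  out
}
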