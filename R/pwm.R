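#' Position-weight-matrix HLA binding motifs
#'
#' The package's built-in ligand-likeness predictor is a per-allotype position
#' weight matrix over a 9-residue binding core: anchor positions concentrate
#' probability on the allotype's anchor residues, non-anchor positions follow
#' the proteome background. The same PWMs drive the synthetic-data generator,
#' so generated ligands are motif-consistent by construction.
#'
#' @param allotype allotype label (e.g. `"A*02"`).
#' @param anchors named list: core position (1..9, as character) -> character
#'   vector of anchor residues.
#' @param anchor_mass probability mass placed on the anchor residues at an
#'   anchor position (rest follows background).
#' @param secondary strength of the mild position-specific secondary
#'   preferences applied at non-anchor positions (log-scale amplitude; 0
#'   disables them). Real binding motifs are not flat outside their anchors,
#'   and these preferences keep the likeness score continuous rather than a
#'   few discrete anchor-combination values.
#' @return a `hla_pwm` object: 20 x 9 column-stochastic matrix plus metadata.
#' @export
hla_pwm <- function(allotype, anchors, anchor_mass = 0.97, secondary = 0.35) {
  mat <- matrix(rep(AA_BACKGROUND, 9L), nrow = 20L,
                dimnames = list(AA_ALPHABET, NULL))
  if (secondary > 0) {
    # deterministic smooth modulation, distinct per allotype via a phase
    phase <- sum(utf8ToInt(allotype))
    for (j in 1:9) {
      tilt <- exp(secondary * sin(phase + j * seq_len(20L) / 3))
      mat[, j] <- mat[, j] * tilt / sum(mat[, j] * tilt)
    }
  }
  for (pos in names(anchors)) {
    j <- as.integer(pos)
    res <- anchors[[pos]]
    stopifnot(j >= 1L, j <= 9L, all(res %in% AA_ALPHABET))
    col <- AA_BACKGROUND
    col[] <- (1 - anchor_mass) * AA_BACKGROUND / sum(AA_BACKGROUND[setdiff(AA_ALPHABET, res)])
    col[res] <- anchor_mass / length(res)
    other <- setdiff(AA_ALPHABET, res)
    col[other] <- (1 - anchor_mass) * AA_BACKGROUND[other] / sum(AA_BACKGROUND[other])
    mat[, j] <- col
  }
  mat <- sweep(mat, 2L, colSums(mat), "/")
  structure(list(allotype = allotype, matrix = mat,
                 anchor_positions = as.integer(names(anchors))),
            class = "hla_pwm")
}

#' Built-in allotype motif set
#'
#' A small set of canonical class I-style motifs (anchor at core position 2
#' and at the C-terminal core position) used as the default predictor and by
#' the synthetic-data generator.
#'
#' @return named list of [hla_pwm()] objects.
#' @export
default_pwms <- function() {
  list(
    "A*02" = hla_pwm("A*02", list("2" = c("L", "M"), "9" = c("V", "L", "I"))),
    "A*01" = hla_pwm("A*01", list("3" = c("D", "E"), "9" = c("Y"))),
    "B*07" = hla_pwm("B*07", list("2" = c("P"), "9" = c("L", "F"))),
    "B*08" = hla_pwm("B*08", list("3" = c("K", "R"), "9" = c("L", "I")))
  )
}

# map peptide positions onto the 9-position core: first 4 and last 4 residues
# take core columns 1-4 and 6-9; all middle residues share core column 5
core_column_map <- function(len) {
  if (len < 8L) stop("peptides shorter than 8 residues are not scored", call. = FALSE)
  if (len == 8L) return(c(1:4, 6:9))
  c(1:4, rep(5L, len - 8L), 6:9)
}

#' Ligand-likeness of a peptide for one allotype
#'
#' Mean per-position log2-odds of the peptide under the allotype PWM versus
#' the background composition, squashed through a logistic to \[0, 1\].
#' Peptides of length other than 9 are scored by mapping their first and last
#' four residues onto the core flanks and the middle onto the central core
#' column.
#'
#' @param peptide amino-acid string, length >= 8.
#' @param pwm an [hla_pwm()].
#' @return likeness score in \[0, 1\] (0.5 = background-like).
#' @export
pwm_likeness <- function(peptide, pwm) {
  res <- split_residues(peptide)
  cols <- core_column_map(length(res))
  lo <- log2(pwm$matrix[cbind(match(res, AA_ALPHABET), cols)] / AA_BACKGROUND[res])
  stats::plogis(4 * mean(lo))
}

#' Built-in PWM predictor
#'
#' Returns a predictor function `(peptide, allotype) -> likeness in [0, 1]`
#' backed by a PWM set; the interface every ligand-propensity consumer uses,
#' so externally computed predictions can be swapped in via
#' [table_predictor()].
#'
#' @param pwms named list of [hla_pwm()] (default [default_pwms()]).
#' @return function of `(peptide, allotype)`.
#' @export
pwm_predictor <- function(pwms = default_pwms()) {
  force(pwms)
  function(peptide, allotype) {
    pwm <- pwms[[allotype]]
    if (is.null(pwm)) stop("no PWM for allotype ", allotype, call. = FALSE)
    pwm_likeness(peptide, pwm)
  }
}

#' Predictor adapter over a precomputed prediction table
#'
#' @param tab data.frame with columns `peptide`, `allotype`, `score`
#'   (likeness in \[0, 1\]).
#' @param missing value returned for absent (peptide, allotype) pairs;
#'   default `NA` (which propagates as an error in scoring).
#' @return function of `(peptide, allotype)`.
#' @export
table_predictor <- function(tab, missing = NA_real_) {
  stopifnot(all(c("peptide", "allotype", "score") %in% names(tab)))
  key <- paste(tab$peptide, tab$allotype, sep = "\r")
  scores <- stats::setNames(tab$score, key)
  function(peptide, allotype) {
    s <- scores[paste(peptide, allotype, sep = "\r")]
    if (is.na(s)) {
      if (is.na(missing)) {
        stop("no precomputed prediction for ", peptide, " / ", allotype,
             call. = FALSE)
      }
      return(missing)
    }
    unname(s)
  }
}

#' Sample a peptide from an allotype PWM
#'
#' Draws each position independently from the PWM column mapped to it; used by
#' the synthetic-data generator to plant motif-consistent ligands.
#'
#' @param pwm an [hla_pwm()].
#' @param len peptide length (>= 8).
#' @return amino-acid string.
#' @export
pwm_sample <- function(pwm, len) {
  cols <- core_column_map(len)
  paste(vapply(cols, function(j) {
    sample(AA_ALPHABET, 1L, prob = pwm$matrix[, j])
  }, character(1)), collapse = "")
}
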