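#' Amino-acid constant tables
#'
#' Monoisotopic residue masses (Da), Kyte-Doolittle hydropathy values and a
#' background amino-acid composition shared across the package. Residue masses
#' are the standard monoisotopic values for the 20 proteinogenic amino acids;
#' `WATER_MONO` and `PROTON_MASS` are the monoisotopic masses of H2O and of a
#' proton used for peptide and fragment m/z arithmetic.
#'
#' @name aa_tables
#' @keywords internal
NULL

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# standard monoisotopic residue masses, Da
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

WATER_MONO <- 18.010565
PROTON_MASS <- 1.007276

# Kyte & Doolittle (1982) hydropathy scale
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# approximate vertebrate proteome background composition (relative frequency);
# used by the synthetic proteome generator and as PWM background
AA_BACKGROUND <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

#' Split a peptide sequence into validated residues
#'
#' @param sequence uppercase amino-acid string.
#' @return character vector of single residues.
#' @keywords internal
split_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  res
}
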