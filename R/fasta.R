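#' Read a proteome FASTA
#'
#' Loads a protein FASTA into a named character vector (accession -> uppercase
#' amino-acid sequence), the proteome container used throughout the package.
#' The accession is the first whitespace-delimited token of the header line.
#'
#' @param path path to a FASTA file.
#' @return named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  acc <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1L)
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- toupper(as.character(seqs))
  names(out) <- acc
  if (any(!nzchar(out))) stop("empty sequence in FASTA", call. = FALSE)
  if (any(grepl("[-*]", out))) {
    stop("gap or stop characters in FASTA sequences", call. = FALSE)
  }
  out
}

#' Write a proteome FASTA
#'
#' @param proteome named character vector (accession -> sequence).
#' @param path output path.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(is.character(proteome), !is.null(names(proteome)))
  x <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
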