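#' Read a per-sample peptide identification table
#'
#' Reads a delimited identification export (e.g. a search-engine peptide table)
#' into a tibble with one row per identified peptide. Column names are mapped
#' through `dialect`, so exports with arbitrary headers can be consumed without
#' editing code. Unknown extra columns are preserved unchanged.
#'
#' The returned table has the canonical columns `sequence` (uppercase
#' amino-acid string), `proteins` (accessions, `;`-separated), `modifications`
#' (encoded `pos:name:delta` triples, `;`-separated, or `NA`), `area`
#' (non-negative reported area or `NA`), `quality` (search score, e.g. -10lgP,
#' or `NA`) and `binder` (per-allotype binder annotation such as
#' `A*02=strong;B*07=weak`, or `NA`).
#'
#' Rows with an empty sequence are dropped; their count is attached as the
#' `n_rejected` attribute.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect list with `sep` (field separator, default `","`) and
#'   `columns`, a named map from canonical column names to the file's headers.
#' @return a tibble of peptide records (attribute `n_rejected` = dropped rows).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sequence,proteins,area", "ALDFEQEMT,P12345,1.2e6"), tf)
#' read_peptide_table(tf)
read_peptide_table <- function(path, dialect = peptide_dialect()) {
  sep <- dialect$sep %||% ","
  cols <- utils::modifyList(peptide_dialect()$columns, dialect$columns %||% list())
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", colClasses = "character")
  if (!cols$sequence %in% names(raw)) {
    stop("peptide table is missing mandatory column '", cols$sequence, "'",
         call. = FALSE)
  }
  pick <- function(key) {
    nm <- cols[[key]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  }
  blank_na <- function(x) {
    x[x %in% c("", "NA")] <- NA_character_
    x
  }
  out <- tibble::tibble(
    sequence = toupper(trimws(pick("sequence"))),
    proteins = blank_na(pick("proteins")),
    modifications = blank_na(pick("modifications")),
    area = suppressWarnings(as.numeric(pick("area"))),
    quality = suppressWarnings(as.numeric(pick("quality"))),
    binder = blank_na(pick("binder"))
  )
  mapped <- unlist(cols, use.names = FALSE)
  extras <- setdiff(names(raw), mapped)
  for (nm in extras) out[[nm]] <- raw[[nm]]

  keep <- !is.na(out$sequence) & nzchar(out$sequence)
  n_rejected <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (any(!is.na(out$area) & out$area < 0)) {
    stop("reported area must be non-negative", call. = FALSE)
  }
  bad <- !grepl("^[A-Z]+$", out$sequence)
  if (any(bad)) {
    stop("non-residue characters in sequence at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  # validate encoded modifications early so row-level errors carry an index
  for (i in seq_len(nrow(out))) {
    tryCatch(parse_modifications(out$modifications[i], nchar(out$sequence[i])),
             error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Default peptide-table dialect
#'
#' @return list with `sep` and the canonical-to-file column map.
#' @export
peptide_dialect <- function() {
  list(sep = ",", columns = list(
    sequence = "sequence", proteins = "proteins", modifications = "modifications",
    area = "area", quality = "quality", binder = "binder"
  ))
}

#' Write a peptide table
#'
#' @param tab tibble as returned by [read_peptide_table()].
#' @param path output path; written as the dialect's delimited text.
#' @param sep field separator.
#' @export
write_peptide_table <- function(tab, path, sep = ",") {
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Parse an encoded modification string
#'
#' Modifications are encoded as `position:name:delta_mass` triples separated by
#' `;`, with 1-based positions, e.g. `"1:Oxidation:15.9949"`.
#'
#' @param text encoded string or `NA`/empty for no modifications.
#' @param seq_length peptide length used to bound positions (optional).
#' @return data.frame with columns `position`, `name`, `delta` (0 rows if none).
#' @export
parse_modifications <- function(text, seq_length = NULL) {
  empty <- data.frame(position = integer(), name = character(),
                      delta = numeric(), stringsAsFactors = FALSE)
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(trimws(text))) {
    return(empty)
  }
  parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  parsed <- lapply(parts, function(p) {
    f <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(f) != 3L) stop("malformed modification '", p, "'", call. = FALSE)
    pos <- suppressWarnings(as.integer(f[1]))
    delta <- suppressWarnings(as.numeric(f[3]))
    if (is.na(pos) || pos < 1L) stop("malformed modification position in '", p, "'",
                                     call. = FALSE)
    if (is.na(delta)) stop("malformed modification mass in '", p, "'", call. = FALSE)
    data.frame(position = pos, name = f[2], delta = delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parsed)
  if (!is.null(seq_length) && any(out$position > seq_length)) {
    stop("modification position beyond sequence length ", seq_length, call. = FALSE)
  }
  out
}

#' Canonical peptide identity
#'
#' Returns the identity string under which all set comparisons in the package
#' are performed: the modification-stripped uppercase sequence, with every
#' isoleucine replaced by leucine when `il_collapse` is on (mass spectrometry
#' cannot distinguish the two isomers). Idempotent.
#'
#' @param x character vector of sequences, or a peptide table (its `sequence`
#'   column is used).
#' @param il_collapse collapse I to L? Default `FALSE` (sequences as searched).
#' @return character vector of identity strings.
#' @export
#' @examples
#' canonical_sequence("SIINFEKL", il_collapse = TRUE)
canonical_sequence <- function(x, il_collapse = FALSE) {
  if (is.data.frame(x)) x <- x$sequence
  out <- toupper(as.character(x))
  if (isTRUE(il_collapse)) out <- gsub("I", "L", out, fixed = TRUE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
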