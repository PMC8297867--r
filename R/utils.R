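#' @keywords internal
"_PACKAGE"

#' @importFrom utils adist read.delim write.table head tail
#' @importFrom stats setNames rbinom runif median
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet {A,C,G,T,N}
#' (case preserved for upper case input only; input is upper-cased).
#'
#' @param x a single DNA string.
#' @return the reverse complement as a character scalar.
#' @export
rev_comp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "", fixed = TRUE)[[1L]]), collapse = ""))
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

## split a string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (nchar(x) == 0L) stop(what, " has zero length", call. = FALSE)
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L)
    stop(what, " contains non-ACGTN characters: ", substr(bad, 1L, 10L), call. = FALSE)
  x
}

## write a TSV with the package-wide conventions: header, tab, no quoting
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

## 1-based circular coordinate normalization
wrap_coord <- function(pos, n) ((pos - 1L) %% n) + 1L

## union length of a set of [start, end] intervals (1-based inclusive)
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  sum(IRanges::width(ir))
}
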