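## Shared internal helpers: TSV IO and small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated file into a data.frame
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by all
#' package inputs: no factors, no quoting surprises, `#` not treated as a
#' comment character (trait names may contain it).
#'
#' @param file Path to a TSV file with a header row.
#' @return A `data.frame`.
#' @export
readTsv <- function(file) {
  if (!file.exists(file)) {
    stop("input file not found: ", file, call. = FALSE)
  }
  utils::read.delim(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "", check.names = FALSE)
}

#' Write a data.frame as a tab-separated file
#'
#' @param x A `data.frame`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeTsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

## lexically smallest element, used for deterministic tie-breaking
.lexMin <- function(x) sort(as.character(x), method = "radix")[1L]

## derive a stream-specific 32-bit seed from a master seed
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}
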