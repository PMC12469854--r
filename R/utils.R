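#' Canonicalize gene symbols
#'
#' Strips surrounding whitespace and upper-cases labels so that
#' case-inconsistent symbols from different sources merge during
#' deduplication.
#'
#' @param x character vector of gene labels.
#' @return character vector of canonical labels.
#' @export
canonicalize_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Canonicalize drug names
#'
#' Strips, case-folds and collapses internal whitespace; optionally applies a
#' user-supplied synonym map afterwards.
#'
#' @param x character vector of drug names.
#' @param synonyms optional named character vector mapping canonical alias ->
#'   canonical preferred name (applied after case-folding).
#' @return character vector of canonical names.
#' @export
canonicalize_drug <- function(x, synonyms = NULL) {
  out <- tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
  if (!is.null(synonyms)) {
    names(synonyms) <- tolower(gsub("[[:space:]]+", " ", trimws(names(synonyms))))
    synonyms <- tolower(gsub("[[:space:]]+", " ", trimws(synonyms)))
    hit <- out %in% names(synonyms)
    out[hit] <- unname(synonyms[out[hit]])
  }
  out
}

#' Read a TSV file into a data.frame
#'
#' Thin wrapper over [utils::read.delim()] with the conventions used
#' throughout the package: tab separation, header row, no factor coercion,
#' UTF-8, and `#`-comment support disabled (gene symbols may contain odd
#' characters but never tabs).
#'
#' @param path file path.
#' @param ... passed to [utils::read.delim()].
#' @return data.frame.
#' @export
read_tsv_table <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "",
                    fileEncoding = "UTF-8", ...)
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Path to a packaged fixture file
#'
#' @param file file name under `inst/extdata`.
#' @return absolute path.
#' @export
seno_extdata <- function(file) {
  p <- system.file("extdata", file, package = "senosynergy", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

# Normalize Unicode minus signs (U+2212, U+2013 misuse) to ASCII "-" before
# numeric parsing; docking tables copied from PDFs routinely contain them.
normalize_minus <- function(x) {
  x <- gsub("−", "-", x)
  x
}

# Parse numerics strictly: NA on failure is converted to an error by callers
# that require validated fields.
parse_num <- function(x) {
  suppressWarnings(as.numeric(normalize_minus(x)))
}
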