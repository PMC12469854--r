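#' Differential-expression set operations
#'
#' Threshold DE result tables into up/down gene sets and perform the
#' intersection/union bookkeeping used when combining two aging contrasts.
#'
#' @name deg_sets
NULL

#' Construct a gene set
#'
#' @param name set label.
#' @param members character vector of gene symbols (deduplicated, whitespace
#'   stripped; case preserved).
#' @param direction one of `"up"`, `"down"`, `"any"`.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, members, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  members <- unique(trimws(as.character(members)))
  members <- members[nzchar(members)]
  structure(list(name = name, members = members, direction = direction),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s' (%s): %d members>\n",
              x$name, x$direction, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read a DE result table
#'
#' @param path TSV with header columns for gene id, log2 fold change and
#'   adjusted p-value.
#' @param gene_col,lfc_col,padj_col column names (configurable to match the
#'   upstream DE tool's output).
#' @return data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @export
read_deg_table <- function(path, gene_col = "gene_id", lfc_col = "log2fc",
                           padj_col = "padj") {
  df <- read_tsv_table(path)
  for (col in c(gene_col, lfc_col, padj_col)) {
    if (!col %in% names(df)) stop("missing column in DE table: ", col)
  }
  data.frame(gene_id = trimws(as.character(df[[gene_col]])),
             log2fc = parse_num(df[[lfc_col]]),
             padj = parse_num(df[[padj_col]]),
             stringsAsFactors = FALSE)
}

#' Threshold a DE table into up- and down-regulated gene sets
#'
#' A gene is upregulated when `log2fc > lfc_thresh` and `padj < padj_thresh`,
#' downregulated when `log2fc < -lfc_thresh` and `padj < padj_thresh`.  Both
#' inequalities are strict, so boundary values are excluded.  Records with
#' missing statistics are dropped (not imputed) and the drop count is reported
#' via a warning and in the returned summary.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `padj` (one row
#'   per gene).
#' @param lfc_thresh positive log2 fold-change threshold (default 1.0).
#' @param padj_thresh positive adjusted-p threshold (default 0.05).
#' @param name_prefix prefix for the returned set names.
#' @return list with elements `up` and `down` ([gene_set]s) and `summary`
#'   (list with `n_input`, `n_up`, `n_down`, `n_dropped`).
#' @export
filter_deg <- function(table, lfc_thresh = 1.0, padj_thresh = 0.05,
                       name_prefix = "deg") {
  stopifnot(nrow(table) > 0, lfc_thresh > 0, padj_thresh > 0)
  gid <- trimws(as.character(table$gene_id))
  if (any(!nzchar(gid))) stop("empty gene_id in DE table")
  if (anyDuplicated(gid)) stop("duplicate gene_id in DE table: ",
                               gid[duplicated(gid)][1L])
  bad_p <- !is.na(table$padj) & (table$padj < 0 | table$padj > 1)
  if (any(bad_p)) stop("padj outside [0,1] for gene ", gid[bad_p][1L])

  ok <- is.finite(table$log2fc) & is.finite(table$padj)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(sprintf("filter_deg: dropped %d record(s) with missing statistics",
                    n_dropped))
  }
  lfc <- table$log2fc[ok]
  padj <- table$padj[ok]
  gid <- gid[ok]
  up <- gid[lfc > lfc_thresh & padj < padj_thresh]
  down <- gid[lfc < -lfc_thresh & padj < padj_thresh]
  list(up = gene_set(paste0(name_prefix, "_up"), up, "up"),
       down = gene_set(paste0(name_prefix, "_down"), down, "down"),
       summary = list(n_input = nrow(table), n_up = length(up),
                      n_down = length(down), n_dropped = n_dropped))
}

#' Intersect two gene sets of the same direction
#'
#' @param a,b [gene_set] objects with matching `direction`.
#' @param name name for the result.
#' @return [gene_set] with the common members.
#' @export
intersect_sets <- function(a, b, name = paste0(a$name, "&", b$name)) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  if (!identical(a$direction, b$direction)) {
    stop(sprintf("cannot intersect sets with directions '%s' and '%s'",
                 a$direction, b$direction))
  }
  gene_set(name, intersect(a$members, b$members), a$direction)
}

#' Union size by inclusion-exclusion
#'
#' `|A| + |B| - |A intersect B|`, the count "after excluding duplicate
#' entries" when pooling two gene lists.
#'
#' @param size_a,size_b,size_intersection non-negative integer counts.
#' @return integer union size.
#' @export
union_count <- function(size_a, size_b, size_intersection) {
  stopifnot(size_a >= 0, size_b >= 0, size_intersection >= 0)
  if (size_intersection > min(size_a, size_b)) {
    stop("intersection size exceeds a set size")
  }
  as.integer(size_a + size_b - size_intersection)
}

#' Write a gene set as a one-symbol-per-line text file
#'
#' @param set [gene_set].
#' @param path output path.
#' @export
write_gene_list <- function(set, path) {
  writeLines(set$members, path)
}

#' Write a [filter_deg] summary as JSON
#'
#' @param summary the `summary` element returned by [filter_deg].
#' @param path output path.
#' @export
write_deg_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE)
}
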