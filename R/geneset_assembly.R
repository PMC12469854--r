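#' Aging target-gene universe assembly
#'
#' Build the target-gene universe from six sources (two DE contrasts plus
#' four curated aging/senescence databases), apply per-source filters,
#' deduplicate at the label level, convert labels to stable IDs and
#' deduplicate again.  The resulting ordered universe defines feature indices
#' for the synergy model and the background for enrichment.
#'
#' @name geneset_assembly
NULL

SOURCE_TAGS <- c("deg_gse72815", "deg_gse141595", "genage", "longevitymap",
                 "cellage", "agingatlas")

#' Per-source loading rules
#'
#' @param gene_col name of the column holding gene labels.
#' @param filter_col name of the column the per-source filter inspects
#'   (Association for LongevityMap, Senescence Effect for CellAge, the logFC
#'   column for DE sources); ignored for pass-through sources.
#' @param direction for `deg_*` sources: `"up"` keeps `logFC > 1`, `"down"`
#'   keeps `logFC < -1`, `"both"` keeps either.
#' @return list of class `source_rules`.
#' @export
source_rules <- function(gene_col = "gene", filter_col = NULL,
                         direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  structure(list(gene_col = gene_col, filter_col = filter_col,
                 direction = direction), class = "source_rules")
}

#' Load one gene source table with its filter applied
#'
#' Filters follow the curation rules of the assembled dataset:
#' \itemize{
#'   \item `longevitymap`: keep only rows whose Association column equals
#'     `"significant"` (case-insensitive) -- the database records negative
#'     results too.
#'   \item `cellage`: drop rows whose Senescence Effect column equals
#'     `"Unclear"` (case-insensitive).
#'   \item `deg_gse72815`, `deg_gse141595`: keep `logFC > 1` and/or
#'     `logFC < -1` depending on `rules$direction` (strict cutoffs).
#'   \item `genage`, `agingatlas`: pass through unfiltered.
#' }
#'
#' @param path TSV path, or a data.frame already in memory.
#' @param source_tag one of `r paste(SOURCE_TAGS, collapse = ", ")`.
#' @param rules a [source_rules] object.
#' @return data.frame with columns `gene_label`, `source_tag`.
#' @export
load_source <- function(path, source_tag, rules = source_rules()) {
  if (!source_tag %in% SOURCE_TAGS) {
    stop("unknown source_tag: ", source_tag)
  }
  df <- if (is.data.frame(path)) path else read_tsv_table(path)
  if (!rules$gene_col %in% names(df)) {
    stop("missing gene column '", rules$gene_col, "' in source ", source_tag)
  }
  need_filter_col <- function() {
    if (is.null(rules$filter_col) || !rules$filter_col %in% names(df)) {
      stop("missing filter column '",
           if (is.null(rules$filter_col)) "<unset>" else rules$filter_col,
           "' required for source ", source_tag)
    }
    df[[rules$filter_col]]
  }
  keep <- switch(source_tag,
    longevitymap = tolower(trimws(need_filter_col())) == "significant",
    cellage = tolower(trimws(need_filter_col())) != "unclear",
    deg_gse72815 = ,
    deg_gse141595 = {
      lfc <- parse_num(need_filter_col())
      switch(rules$direction,
             up = lfc > 1, down = lfc < -1,
             both = lfc > 1 | lfc < -1)
    },
    rep(TRUE, nrow(df))
  )
  keep[is.na(keep)] <- FALSE
  labels <- trimws(as.character(df[[rules$gene_col]]))[keep]
  if (any(!nzchar(labels))) stop("empty gene label in source ", source_tag)
  data.frame(gene_label = labels,
             source_tag = rep(source_tag, length(labels)),
             stringsAsFactors = FALSE)
}

#' Pool source entries and deduplicate labels
#'
#' Labels are canonicalized (whitespace stripped, upper-cased) before
#' deduplication; first occurrence order is preserved.  The final
#' lexicographic ordering happens later, in [convert_ids()].
#'
#' @param entries data.frame with a `gene_label` column (e.g. rbind of
#'   [load_source()] outputs), or a list of such data.frames.
#' @return list with `total` (raw entry count), `deduplicated` (character
#'   vector of canonical labels in first-occurrence order) and
#'   `per_source_counts` (named integer vector, when `source_tag` present).
#' @export
assemble <- function(entries) {
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- do.call(rbind, entries)
  }
  stopifnot(is.data.frame(entries), nrow(entries) > 0)
  canon <- canonicalize_gene(entries$gene_label)
  per_source <- if ("source_tag" %in% names(entries)) {
    tab <- table(entries$source_tag)
    stats::setNames(as.integer(tab), names(tab))
  } else NULL
  list(total = nrow(entries),
       deduplicated = canon[!duplicated(canon)],
       per_source_counts = per_source)
}

#' Convert labels to IDs and build the gene universe
#'
#' Unmapped labels are dropped (with a warning carrying the count); mapped
#' IDs are deduplicated again, because two labels may map to one ID, and
#' finally sorted lexicographically so feature indices are stable across
#' runs.
#'
#' @param labels character vector of canonical gene labels.
#' @param mapping data.frame with columns `label` and `id` (unique labels),
#'   or NULL for the identity mapping.
#' @return object of class `gene_universe`: list with `genes` (sorted unique
#'   IDs), `index` (named integer vector id -> 1-based position) and
#'   `n_dropped`.
#' @export
convert_ids <- function(labels, mapping = NULL) {
  labels <- canonicalize_gene(labels)
  if (is.null(mapping)) {
    ids <- labels
    n_dropped <- 0L
  } else {
    stopifnot(all(c("label", "id") %in% names(mapping)))
    key <- canonicalize_gene(mapping$label)
    if (anyDuplicated(key)) {
      stop("mapping has duplicate keys: ", key[duplicated(key)][1L])
    }
    lut <- stats::setNames(as.character(mapping$id), key)
    ids <- unname(lut[labels])
    n_dropped <- sum(is.na(ids))
    if (n_dropped > 0) {
      warning(sprintf("convert_ids: %d label(s) could not be converted",
                      n_dropped))
    }
    ids <- ids[!is.na(ids)]
  }
  genes <- sort(unique(ids), method = "radix")
  structure(list(genes = genes,
                 index = stats::setNames(seq_along(genes), genes),
                 n_dropped = as.integer(n_dropped)),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe: %d genes>\n", length(x$genes)))
  invisible(x)
}

#' @export
length.gene_universe <- function(x) length(x$genes)

#' Assemble the full universe from source tables in one call
#'
#' @param sources named list: each element a list with `path` (TSV path or
#'   data.frame), `tag`, and optionally `rules` (a [source_rules]).
#' @param mapping optional label -> id mapping data.frame (see
#'   [convert_ids()]); NULL for identity.
#' @return list with `universe` ([convert_ids] result) and `summary`
#'   (`total`, `after_dedup`, `after_id_conversion`, `per_source_counts`).
#' @export
build_universe <- function(sources, mapping = NULL) {
  loaded <- lapply(sources, function(s) {
    load_source(s$path, s$tag, if (is.null(s$rules)) source_rules() else s$rules)
  })
  asm <- assemble(loaded)
  uni <- convert_ids(asm$deduplicated, mapping)
  list(universe = uni,
       summary = list(total = asm$total,
                      after_dedup = length(asm$deduplicated),
                      after_id_conversion = length(uni$genes),
                      per_source_counts = asm$per_source_counts))
}

#' Write a gene universe and its summary
#'
#' @param result a [build_universe()] result.
#' @param genes_path one-ID-per-line output path.
#' @param summary_path JSON summary output path.
#' @export
write_universe <- function(result, genes_path, summary_path = NULL) {
  writeLines(result$universe$genes, genes_path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(result$summary, summary_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
}

#' Read a gene universe from a one-ID-per-line file
#'
#' @param path text file with one gene ID per line.
#' @return `gene_universe`.
#' @export
read_universe <- function(path) {
  convert_ids(readLines(path))
}
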