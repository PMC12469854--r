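#' Over-representation analysis
#'
#' One-sided hypergeometric tests of a study gene set against annotation
#' terms (GO/KEGG-style), Benjamini-Hochberg correction across all tested
#' terms, and a minimum-hit-count reporting rule.
#'
#' @name enrichment
NULL

#' Hypergeometric upper-tail probability
#'
#' P(X >= x) for X ~ Hypergeometric(population N, successes K, draws n):
#' the probability of observing at least `x` annotated genes in a random
#' study set of size `n` drawn from a universe of `N` genes of which `K`
#' carry the annotation.
#'
#' @param x observed hit count.
#' @param n study-set size (draws).
#' @param K annotated genes in the universe (successes).
#' @param N universe size (population).
#' @return probability in [0, 1].
#' @export
hypergeom_upper_tail <- function(x, n, K, N) {
  stopifnot(length(x) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (x < 0 || n < 0 || K < 0 || N < 0) stop("counts must be non-negative")
  if (x > min(n, K)) stop("x exceeds min(n, K)")
  if (n > N || K > N) stop("n and K must not exceed N")
  if (x == 0) return(1.0)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sort p-values ascending, multiply the i-th by m/i, enforce monotone
#' non-decreasing adjusted values from the largest rank downwards, cap at 1,
#' and return in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Read annotation terms from a GMT file
#'
#' Standard GMT dialect: one term per line, tab-separated
#' `term_id <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file path.
#' @param namespace collection tag applied to every term (`"BP"`, `"CC"`,
#'   `"MF"` or `"pathway"`).
#' @return list of terms, each a list with `term_id`, `description`,
#'   `namespace`, `members` (character vector).
#' @export
read_gmt <- function(path, namespace = c("pathway", "BP", "CC", "MF")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  terms <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 60))
    list(term_id = parts[1], description = parts[2], namespace = namespace,
         members = unique(trimws(parts[-(1:2)])))
  })
  ids <- vapply(terms, `[[`, "", "term_id")
  if (anyDuplicated(ids)) stop("duplicate term_id in GMT: ",
                               ids[duplicated(ids)][1L])
  terms
}

#' Over-representation analysis of a study set
#'
#' Each term is tested with the hypergeometric upper tail using
#' `N = |universe|`, `K = |term members in universe|`, `n = |study|`,
#' `x = |term members in study|`.  BH adjustment runs across ALL tested
#' terms; the `min_count` filter is applied afterwards, so reported adjusted
#' p-values are unaffected by the count-based view.  Output is sorted by
#' descending hit count, then ascending p, then term_id.
#'
#' @param study a [gene_set] or character vector of study genes; genes
#'   outside the universe are dropped with a warning.
#' @param terms list of terms as returned by [read_gmt()].
#' @param universe a `gene_universe` (see [convert_ids()]) or character
#'   vector defining the background.
#' @param min_count minimum hit count for a term to be reported (default 2).
#' @return data.frame with columns `term_id`, `description`, `namespace`,
#'   `hit_genes` (slash-joined), `count`, `p_value`, `p_adjusted`.
#' @export
enrich <- function(study, terms, universe, min_count = 2) {
  uni_genes <- if (inherits(universe, "gene_universe")) universe$genes
               else unique(as.character(universe))
  if (length(uni_genes) == 0) stop("empty universe")
  study_genes <- if (inherits(study, "gene_set")) study$members
                 else unique(as.character(study))
  outside <- setdiff(study_genes, uni_genes)
  if (length(outside) > 0) {
    warning(sprintf("enrich: %d study gene(s) outside the universe dropped",
                    length(outside)))
    study_genes <- setdiff(study_genes, outside)
  }
  N <- length(uni_genes)
  n <- length(study_genes)
  rows <- lapply(terms, function(tm) {
    members_in_uni <- intersect(tm$members, uni_genes)
    hits <- intersect(tm$members, study_genes)
    K <- length(members_in_uni)
    x <- length(hits)
    data.frame(term_id = tm$term_id, description = tm$description,
               namespace = tm$namespace,
               hit_genes = paste(sort(hits), collapse = "/"),
               count = x,
               p_value = hypergeom_upper_tail(x, n, K, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_value)
  res <- res[res$count >= min_count, , drop = FALSE]
  res <- res[order(-res$count, res$p_value, res$term_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results as a TSV report
#'
#' Columns: ID, Description, Gene ID (slash-joined), Count, p, p.adjust.
#'
#' @param res [enrich()] result.
#' @param path output path.
#' @export
write_enrichment <- function(res, path) {
  out <- data.frame(ID = res$term_id, Description = res$description,
                    `Gene ID` = res$hit_genes, Count = res$count,
                    p = res$p_value, p.adjust = res$p_adjusted,
                    check.names = FALSE)
  write_tsv_table(out, path)
}
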