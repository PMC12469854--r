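#' Senolytic combination enumeration, filtering and ranking
#'
#' Enumerate all unordered pairs of a senolytic drug list, keep the pairs
#' whose constituent drugs both appear in the training set, predict synergy
#' scores, and report the combinations exceeding a score threshold, ranked.
#'
#' @name combo_pipeline
NULL

#' Enumerate unordered drug pairs
#'
#' All `n * (n - 1) / 2` pairs of distinct drugs, ordered lexicographically
#' by pair (self-pairs excluded).
#'
#' @param drugs character vector of canonical drug names.
#' @return data.frame with columns `drugA`, `drugB` (within each row
#'   `drugA < drugB` lexicographically).
#' @export
enumerate_pairs <- function(drugs) {
  drugs <- as.character(drugs)
  dup <- unique(drugs[duplicated(drugs)])
  if (length(dup) > 0) {
    stop("duplicate drug names after canonicalization: ",
         paste(dup, collapse = ", "))
  }
  n <- length(drugs)
  if (n < 2) {
    return(data.frame(drugA = character(0), drugB = character(0),
                      stringsAsFactors = FALSE))
  }
  s <- sort(drugs, method = "radix")
  idx <- utils::combn(n, 2)
  out <- data.frame(drugA = s[idx[1, ]], drugB = s[idx[2, ]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$drugA, out$drugB, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep pairs whose drugs both appear in the training set
#'
#' @param pairs data.frame with `drugA`, `drugB` columns.
#' @param training_drugs character vector of canonical training-set drug
#'   names.
#' @return filtered data.frame (same columns, rownames reset).
#' @export
filter_known <- function(pairs, training_drugs) {
  keep <- pairs$drugA %in% training_drugs & pairs$drugB %in% training_drugs
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold and rank predicted combinations
#'
#' Keeps rows with `predicted_score > threshold` (strict), sorts by
#' descending score with lexicographic pair tie-break, and assigns ranks
#' `1..k`.
#'
#' @param rows data.frame with columns `drugA`, `drugB`, `predicted_score`.
#' @param threshold score cutoff (default 8).
#' @return data.frame with columns `drugA`, `drugB`, `predicted_score`,
#'   `rank`.
#' @export
rank_and_threshold <- function(rows, threshold = 8.0) {
  stopifnot(all(c("drugA", "drugB", "predicted_score") %in% names(rows)))
  if (any(!is.finite(rows$predicted_score))) stop("scores must be finite")
  out <- rows[rows$predicted_score > threshold, , drop = FALSE]
  out <- out[order(-out$predicted_score, out$drugA, out$drugB,
                   method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Resolve the cell-line context for senolytic prediction
#'
#' The application stage needs one expression profile; the choice is either
#' a named column of the expression matrix or `"MEAN"`, the mean profile
#' over training cell lines (the default when no specific line is known).
#'
#' @param expression genes x cell-lines numeric matrix (rownames = gene
#'   IDs).
#' @param cell_line column name or `"MEAN"`.
#' @param universe `gene_universe` to align against.
#' @return numeric profile of length `length(universe)`.
#' @export
resolve_cell_context <- function(expression, cell_line, universe) {
  prof <- if (identical(cell_line, "MEAN")) {
    rowMeans(expression)
  } else {
    if (!cell_line %in% colnames(expression)) {
      stop("cell line not found in expression matrix: ", cell_line)
    }
    expression[, cell_line]
  }
  align_profile(prof, universe)
}

#' Run the full prediction stage
#'
#' Enumerates pairs of `drugs`, filters to pairs fully covered by the
#' training drug set, predicts each pair's synergy score with the trained
#' model in the chosen cell context, and returns the thresholded ranking.
#'
#' @param model trained `synergy_model`.
#' @param drugs character vector of candidate (senolytic) drug names; they
#'   are canonicalized internally.
#' @param drug_targets named list drug -> target gene IDs covering at least
#'   the filtered drugs.
#' @param training_drugs canonical names of drugs present in the training
#'   set.
#' @param expression genes x cell-lines expression matrix.
#' @param universe `gene_universe`.
#' @param cell_line `"MEAN"` or a column of `expression`.
#' @param threshold score cutoff (strict `>`; default 8).
#' @param synonyms optional drug synonym map for canonicalization.
#' @return list with `ranked` (the thresholded [rank_and_threshold()] table),
#'   `all_predictions` (every filtered pair with its score) and `n_filtered`
#'   (pairs surviving the training-set filter).
#' @export
predict_combinations <- function(model, drugs, drug_targets, training_drugs,
                                 expression, universe, cell_line = "MEAN",
                                 threshold = 8.0, synonyms = NULL) {
  drugs <- unique(canonicalize_drug(drugs, synonyms))
  pairs <- enumerate_pairs(drugs)
  pairs <- filter_known(pairs, canonicalize_drug(training_drugs, synonyms))
  profile <- resolve_cell_context(expression, cell_line, universe)
  if (nrow(pairs) == 0) {
    empty <- data.frame(drugA = character(0), drugB = character(0),
                        predicted_score = numeric(0), rank = integer(0))
    return(list(ranked = empty, all_predictions = empty[, 1:3],
                n_filtered = 0L))
  }
  Xraw <- t(vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$drugA[i]; b <- pairs$drugB[i]
    for (d in c(a, b)) {
      if (!d %in% names(drug_targets)) {
        stop("drug absent from the drug-target table: ", d)
      }
    }
    fuse(drug_targets[[a]], drug_targets[[b]], profile, universe)
  }, numeric(3 * length(universe$genes))))
  scores <- predict_fused(model, Xraw)
  preds <- data.frame(drugA = pairs$drugA, drugB = pairs$drugB,
                      predicted_score = scores, stringsAsFactors = FALSE)
  list(ranked = rank_and_threshold(preds, threshold),
       all_predictions = preds, n_filtered = nrow(pairs))
}

#' Write a ranked combination table
#'
#' Columns mirror the reporting convention: drugA_Name, drug_B_Name,
#' Predicted_Synergy_Score, rank.
#'
#' @param ranked [rank_and_threshold()] output.
#' @param path output TSV path.
#' @export
write_ranked <- function(ranked, path) {
  out <- data.frame(drugA_Name = ranked$drugA, drug_B_Name = ranked$drugB,
                    Predicted_Synergy_Score = ranked$predicted_score,
                    rank = ranked$rank, check.names = FALSE)
  write_tsv_table(out, path)
}
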