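#' Drug-pair / cell-line feature fusion
#'
#' Binary drug-target vectors over the gene universe, concatenation of the
#' two drug blocks with the cell-line expression block, and Z-score
#' standardization fitted on training rows only.
#'
#' @name feature_fusion
NULL

#' Read a drug -> target-gene mapping table
#'
#' @param path TSV with columns `drug` and `target_gene` (one pair per row),
#'   or a data.frame of the same shape.
#' @param drug_col,target_col column names.
#' @param synonyms optional named character vector for
#'   [canonicalize_drug()].
#' @return named list: canonical drug name -> character vector of target gene
#'   IDs.  Drugs with zero targets after parsing are kept (empty vector) with
#'   a warning.
#' @export
read_drug_targets <- function(path, drug_col = "drug",
                              target_col = "target_gene", synonyms = NULL) {
  df <- if (is.data.frame(path)) path else read_tsv_table(path)
  for (col in c(drug_col, target_col)) {
    if (!col %in% names(df)) stop("missing column in drug-target table: ", col)
  }
  drug <- canonicalize_drug(df[[drug_col]], synonyms)
  target <- canonicalize_gene(df[[target_col]])
  keep <- nzchar(drug)
  tgts <- split(target[keep], drug[keep])
  tgts <- lapply(tgts, function(v) unique(v[nzchar(v)]))
  empty <- names(tgts)[lengths(tgts) == 0]
  if (length(empty) > 0) {
    warning("drugs with no parsed targets: ", paste(empty, collapse = ", "))
  }
  tgts
}

#' Read a genes x cell-lines expression matrix
#'
#' @param path TSV whose first column holds gene IDs and remaining columns
#'   one cell line each.
#' @return numeric matrix, rownames = gene IDs, colnames = cell lines.
#' @export
read_expression <- function(path) {
  df <- read_tsv_table(path)
  genes <- canonicalize_gene(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Binary drug-target vector over the universe
#'
#' @param targets character vector of target gene IDs (a `drug_record`'s
#'   target set).
#' @param universe `gene_universe`.
#' @return numeric 0/1 vector of length `length(universe)`, ordered by
#'   universe index; targets outside the universe are ignored with a warning.
#' @export
drug_vector <- function(targets, universe) {
  stopifnot(inherits(universe, "gene_universe"), length(universe$genes) > 0)
  targets <- unique(canonicalize_gene(targets))
  outside <- setdiff(targets, universe$genes)
  if (length(outside) > 0) {
    warning(sprintf("drug_vector: %d target(s) outside the universe ignored",
                    length(outside)))
  }
  as.numeric(universe$genes %in% targets)
}

#' Align a cell-line expression profile to the universe
#'
#' @param expression numeric vector named by gene ID, or a matrix column.
#' @param universe `gene_universe`.
#' @param missing_value value used for universe genes absent from the
#'   profile (default 0).
#' @return numeric vector of length `length(universe)` in universe order.
#' @export
align_profile <- function(expression, universe, missing_value = 0) {
  stopifnot(!is.null(names(expression)))
  out <- unname(expression[universe$genes])
  out[is.na(out)] <- missing_value
  if (any(!is.finite(out))) stop("non-finite expression values after alignment")
  as.numeric(out)
}

#' Fuse a drug pair and a cell-line profile into one feature vector
#'
#' Layout is `[x_A | x_B | x_cell]`, each block of length `|universe|`; total
#' length `3 * |universe|`.
#'
#' @param targets_a,targets_b target-gene sets of the two drugs.
#' @param cell_profile numeric vector of length `|universe|` aligned to the
#'   universe (see [align_profile()]).
#' @param universe `gene_universe`.
#' @return numeric vector of length `3 * length(universe)`.
#' @export
fuse <- function(targets_a, targets_b, cell_profile, universe) {
  G <- length(universe$genes)
  if (length(cell_profile) != G) {
    stop(sprintf("cell profile length %d does not match universe size %d",
                 length(cell_profile), G))
  }
  c(drug_vector(targets_a, universe), drug_vector(targets_b, universe),
    as.numeric(cell_profile))
}

#' Fit a Z-score standardizer on training rows
#'
#' Per-feature mean and population standard deviation (ddof = 0).  Features
#' with zero variance get std = 1 so the standardized output is exactly 0.
#'
#' @param train numeric matrix (rows = training fused features).
#' @return object of class `standardizer` with `means` and `stds`.
#' @export
fit_standardizer <- function(train) {
  stopifnot(is.matrix(train), nrow(train) >= 1)
  means <- colMeans(train)
  vars <- colMeans(train^2) - means^2
  vars[vars < 0] <- 0          # guard tiny negative fp error
  stds <- sqrt(vars)
  stds[stds == 0] <- 1
  structure(list(means = means, stds = stds), class = "standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param s `standardizer` from [fit_standardizer()].
#' @param rows numeric matrix or single vector of raw features.
#' @param invert if TRUE, map standardized rows back to the raw scale.
#' @return matrix (or vector, matching the input shape).
#' @export
apply_standardizer <- function(s, rows, invert = FALSE) {
  if (!inherits(s, "standardizer")) stop("standardizer not fitted")
  vec_in <- is.null(dim(rows))
  m <- if (vec_in) matrix(rows, nrow = 1) else rows
  if (ncol(m) != length(s$means)) stop("feature dimension mismatch")
  out <- if (invert) {
    sweep(sweep(m, 2, s$stds, "*"), 2, s$means, "+")
  } else {
    sweep(sweep(m, 2, s$means, "-"), 2, s$stds, "/")
  }
  if (vec_in) out[1, ] else out
}

#' Serialize / restore a standardizer as JSON
#'
#' @param s `standardizer`.
#' @param path file path.
#' @export
write_standardizer <- function(s, path) {
  jsonlite::write_json(list(means = s$means, stds = s$stds), path,
                       digits = NA)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(means = as.numeric(obj$means), stds = as.numeric(obj$stds)),
            class = "standardizer")
}
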