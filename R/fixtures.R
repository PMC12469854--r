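#' Packaged reference fixtures
#'
#' Small plain-text fixtures shipped with the package: the common
#' upregulated/downregulated gene lists of the two aging contrasts, the
#' enriched-pathway annotation collection, the published top-ranked
#' combination predictions, the nitazoxanide--mTOR docking mode table, and
#' the 63-compound senolytic list.
#'
#' @name fixtures
NULL

#' Load the common upregulated (or downregulated) gene-list fixture
#'
#' @param direction `"up"` (78 genes) or `"down"` (2 genes).
#' @return [gene_set].
#' @export
fixture_common_degs <- function(direction = c("up", "down")) {
  direction <- match.arg(direction)
  f <- if (direction == "up") "table1_common_upregulated.txt"
       else "table1_common_downregulated.txt"
  gene_set(paste0("common_", direction), readLines(seno_extdata(f)), direction)
}

#' Load the pathway annotation fixture (GMT)
#'
#' @return term list as from [read_gmt()].
#' @export
fixture_pathways <- function() {
  read_gmt(seno_extdata("table2_pathways.gmt"), namespace = "pathway")
}

#' Load the top-ranked prediction fixture
#'
#' @return data.frame with columns `drugA`, `drugB`, `predicted_score`.
#' @export
fixture_predictions <- function() {
  df <- read_tsv_table(seno_extdata("table3_predictions.tsv"))
  data.frame(drugA = df$drugA_Name, drugB = df$drug_B_Name,
             predicted_score = df$Predicted_Synergy_Score,
             stringsAsFactors = FALSE)
}

#' Load the docking mode-table fixture
#'
#' @return data.frame as from [parse_mode_table()].
#' @export
fixture_docking_modes <- function() {
  parse_mode_table(seno_extdata("table5_docking_modes.txt"))
}

#' Load the senolytic compound list fixture
#'
#' @return data.frame with columns `Drug_Name`, `Targets`
#'   (semicolon-separated annotations).
#' @export
fixture_senolytics <- function() {
  read_tsv_table(seno_extdata("table6_senolytics.tsv"))
}
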