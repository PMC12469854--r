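#' Docking-report post-processing
#'
#' Parse AutoDock-Vina-style mode tables (whitespace-aligned stdout or TSV),
#' select the reference binding mode by lowest affinity, and classify the
#' remaining modes as structurally similar or deviating by their RMSD lower
#' bound relative to the reference.  No docking is run here; only reports
#' are consumed.
#'
#' @name dock_report
NULL

#' Parse a docking mode table
#'
#' Accepts either a TSV with a header (`Mode`, `Affinity`, `RMSD l.b.`,
#' `RMSD u.b.` -- matched loosely) or a whitespace-aligned four-column table
#' as printed by Vina.  Unicode minus signs are normalized before numeric
#' parsing.  Rows violating `rmsd_lb <= rmsd_ub` or with non-numeric fields
#' raise an error naming the line.
#'
#' @param text path to a file, or a character vector of lines.
#' @return data.frame with columns `mode`, `affinity`, `rmsd_lb`, `rmsd_ub`.
#' @export
parse_mode_table <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text, encoding = "UTF-8")
           else as.character(text)
  lines <- normalize_minus(lines)
  lines <- lines[nzchar(trimws(lines))]
  # drop header / separator lines: keep lines whose first token is an integer
  is_data <- vapply(lines, function(ln) {
    grepl("^[0-9]+([\t ]|$)", trimws(ln))
  }, logical(1))
  header_lines <- which(!is_data)
  data_idx <- which(is_data)
  if (length(data_idx) == 0) stop("no data rows found in mode table")
  rows <- lapply(data_idx, function(i) {
    toks <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (length(toks) < 4) {
      stop(sprintf("malformed mode-table row at line %d: expected 4 fields", i))
    }
    vals <- suppressWarnings(as.numeric(toks[1:4]))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric field in mode-table row at line %d", i))
    }
    vals
  })
  m <- do.call(rbind, rows)
  df <- data.frame(mode = as.integer(m[, 1]), affinity = m[, 2],
                   rmsd_lb = m[, 3], rmsd_ub = m[, 4])
  rownames(df) <- NULL
  bad <- df$rmsd_lb > df$rmsd_ub | df$rmsd_lb < 0
  if (any(bad)) {
    stop(sprintf("invalid RMSD bounds in mode-table row at line %d",
                 data_idx[which(bad)[1]]))
  }
  if (anyDuplicated(df$mode)) stop("duplicate mode numbers in table")
  df
}

#' Select the reference docking mode
#'
#' The mode with the minimum (most negative) binding affinity; ties broken
#' by the lowest mode number.  By reporting convention the reference mode's
#' RMSD bounds are zero.
#'
#' @param modes data.frame from [parse_mode_table()].
#' @return single-row data.frame (the reference mode).
#' @export
reference_mode <- function(modes) {
  stopifnot(nrow(modes) >= 1)
  o <- order(modes$affinity, modes$mode)
  modes[o[1], , drop = FALSE]
}

#' Classify non-reference modes by RMSD similarity
#'
#' A mode is structurally similar to the reference when its RMSD lower
#' bound is below `rmsd_threshold`; all other non-reference modes are
#' deviating.  Also reports the affinity span (min, max) over the reference
#' plus the similar modes -- the binding-free-energy range of the stable
#' conformations.
#'
#' @param modes data.frame from [parse_mode_table()].
#' @param ref reference mode row (default: [reference_mode()] of `modes`).
#' @param rmsd_threshold similarity cutoff in Angstrom (default 10).
#' @return list with `reference`, `similar`, `deviating` (data.frames) and
#'   `affinity_span` (length-2 numeric, min then max).
#' @export
classify_modes <- function(modes, ref = reference_mode(modes),
                           rmsd_threshold = 10.0) {
  if (!ref$mode %in% modes$mode) stop("reference mode not present in table")
  rest <- modes[modes$mode != ref$mode, , drop = FALSE]
  similar <- rest[rest$rmsd_lb < rmsd_threshold, , drop = FALSE]
  deviating <- rest[rest$rmsd_lb >= rmsd_threshold, , drop = FALSE]
  span_aff <- c(ref$affinity, similar$affinity)
  list(reference = ref, similar = similar, deviating = deviating,
       affinity_span = c(min(span_aff), max(span_aff)))
}

#' Write a docking classification report as JSON
#'
#' @param cls [classify_modes()] result.
#' @param path output path.
#' @export
write_dock_report <- function(cls, path) {
  obj <- list(reference = as.list(cls$reference),
              similar = cls$similar$mode,
              deviating = cls$deviating$mode,
              affinity_span = cls$affinity_span)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
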