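#' Seeded synthetic-data generators
#'
#' Generators for every input class the pipeline consumes -- DE result
#' tables, curated gene-source tables with duplicates and unmappable labels,
#' a drug-target bipartite graph, cell-line expression profiles, and
#' drug-combination labels from a known ground-truth synergy function --
#' so the full pipeline is testable without any external download.  All
#' sampling in one call flows from a single seeded stream.
#'
#' @name synthetic_data
NULL

#' Synthetic-world configuration
#'
#' The ground-truth synergy of a combination (A, B, cell c) is
#' `S = beta0 + beta1 * |T_A intersect T_B| + beta2 * h_A * h_B + eps`,
#' where `T_X` is drug X's target set, `h_X = |T_X intersect M_c|` counts
#' targets hitting cell line c's vulnerability module `M_c`, and
#' `eps ~ Normal(0, sigma^2)`.  Target overlap rewards redundant hitting of
#' shared genes; the bilinear module term rewards both drugs engaging the
#' cell line's vulnerable program -- a senolytic-like mechanism the model
#' must read from the expression block.
#'
#' @param n_genes genes in the synthetic universe.
#' @param n_drugs drugs in the target graph.
#' @param targets_per_drug_mean Poisson mean for targets per drug (minimum
#'   1 enforced).
#' @param n_cell_lines cell lines.
#' @param module_size genes per cell-line vulnerability module.
#' @param beta0,beta1,beta2 synergy-function coefficients.
#' @param sigma label noise standard deviation.
#' @param n_combos combination labels to draw.
#' @param duplication_rate duplicate-entry rate for source tables.
#' @param unmappable_fraction fraction of distinct source labels withheld
#'   from the ID mapping.
#' @param n_up,n_down planted up/down DEG counts per DE table.
#' @param entries_per_source base entries per curated source table.
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 100L, n_drugs = 50L,
                             targets_per_drug_mean = 10,
                             n_cell_lines = 8L, module_size = 15L,
                             beta0 = 0, beta1 = 1.0, beta2 = 0.5,
                             sigma = 1.0, n_combos = 2000L,
                             duplication_rate = 0.3,
                             unmappable_fraction = 0.1,
                             n_up = 20L, n_down = 10L,
                             entries_per_source = 40L, seed = 1L) {
  stopifnot(n_genes > 0, n_drugs > 0, n_cell_lines > 0, module_size > 0,
            sigma >= 0, n_combos > 0, duplication_rate >= 0,
            unmappable_fraction >= 0, unmappable_fraction <= 1,
            targets_per_drug_mean >= 0)
  structure(list(n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
                 targets_per_drug_mean = targets_per_drug_mean,
                 n_cell_lines = as.integer(n_cell_lines),
                 module_size = as.integer(module_size),
                 beta0 = beta0, beta1 = beta1, beta2 = beta2, sigma = sigma,
                 n_combos = as.integer(n_combos),
                 duplication_rate = duplication_rate,
                 unmappable_fraction = unmappable_fraction,
                 n_up = as.integer(n_up), n_down = as.integer(n_down),
                 entries_per_source = as.integer(entries_per_source),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the synthetic world
#'
#' Universe of `n_genes` IDs; each drug receives
#' `max(1, Poisson(targets_per_drug_mean))` targets sampled without
#' replacement; each cell line gets expression `Normal(0, 1)` per gene with
#' a uniformly sampled vulnerability module of `module_size` genes shifted
#' by +2.
#'
#' @param config [synthetic_config()].
#' @return list with `universe` (`gene_universe`), `drugs` (named list drug
#'   -> target gene IDs), `expression` (genes x cell lines matrix),
#'   `modules` (named list cell line -> module gene IDs) and `config`.
#' @export
gen_world <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$module_size > config$n_genes) {
    stop("module_size exceeds n_genes")
  }
  with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    universe <- convert_ids(genes)
    drugs <- stats::setNames(vector("list", config$n_drugs),
                             sprintf("drug%03d", seq_len(config$n_drugs)))
    for (d in seq_len(config$n_drugs)) {
      k <- max(1L, stats::rpois(1, config$targets_per_drug_mean))
      k <- min(k, config$n_genes)
      drugs[[d]] <- sort(sample(genes, k))
    }
    cells <- sprintf("cell%02d", seq_len(config$n_cell_lines))
    expr <- matrix(stats::rnorm(config$n_genes * config$n_cell_lines),
                   config$n_genes, config$n_cell_lines,
                   dimnames = list(genes, cells))
    modules <- stats::setNames(vector("list", config$n_cell_lines), cells)
    for (c in seq_len(config$n_cell_lines)) {
      mod <- sort(sample(genes, config$module_size))
      modules[[c]] <- mod
      expr[mod, c] <- expr[mod, c] + 2
    }
    list(universe = universe, drugs = drugs, expression = expr,
         modules = modules, config = config)
  })
}

# Noiseless ground-truth synergy of one (A, B, cell) triple.
true_synergy <- function(world, a, b, cell) {
  cfg <- world$config
  ov <- length(intersect(world$drugs[[a]], world$drugs[[b]]))
  hA <- length(intersect(world$drugs[[a]], world$modules[[cell]]))
  hB <- length(intersect(world$drugs[[b]], world$modules[[cell]]))
  cfg$beta0 + cfg$beta1 * ov + cfg$beta2 * hA * hB
}

#' Generate combination labels from the ground-truth synergy function
#'
#' Draws `n_combos` (drugA, drugB, cell) triples uniformly without
#' replacement over distinct pair x cell-line slots, labels each with the
#' ground-truth synergy plus Gaussian noise, and stores the noiseless score
#' alongside.
#'
#' @param world [gen_world()] output.
#' @param config [synthetic_config()] (defaults to the world's own config).
#' @return data.frame with columns `drugA`, `drugB`, `cell_line`, `score`
#'   (noisy label) and `truth` (noiseless).
#' @export
gen_combos <- function(world, config = world$config) {
  drugs <- names(world$drugs)
  if (length(drugs) < 2) stop("need at least 2 drugs to form combinations")
  cells <- colnames(world$expression)
  pairs <- utils::combn(length(drugs), 2)
  n_slots <- ncol(pairs) * length(cells)
  if (config$n_combos > n_slots) {
    stop(sprintf("n_combos (%d) exceeds available pair x cell slots (%d)",
                 config$n_combos, n_slots))
  }
  with_seed(config$seed + 1L, {
    slot <- sample.int(n_slots, config$n_combos)
    pair_i <- ((slot - 1L) %/% length(cells)) + 1L
    cell_i <- ((slot - 1L) %% length(cells)) + 1L
    a <- drugs[pairs[1, pair_i]]
    b <- drugs[pairs[2, pair_i]]
    cl <- cells[cell_i]
    truth <- vapply(seq_along(a), function(i) true_synergy(world, a[i], b[i],
                                                           cl[i]), 0)
    score <- truth + stats::rnorm(length(truth), 0, config$sigma)
    data.frame(drugA = a, drugB = b, cell_line = cl, score = score,
               truth = truth, stringsAsFactors = FALSE)
  })
}

#' Build the raw fused feature matrix for a combination table
#'
#' @param world [gen_world()] output.
#' @param combos [gen_combos()] output (or any data.frame with `drugA`,
#'   `drugB`, `cell_line`).
#' @return numeric matrix, one fused `[x_A | x_B | x_cell]` row per
#'   combination.
#' @export
combos_to_features <- function(world, combos) {
  G <- length(world$universe$genes)
  profiles <- lapply(colnames(world$expression), function(cl)
    align_profile(world$expression[, cl], world$universe))
  names(profiles) <- colnames(world$expression)
  t(vapply(seq_len(nrow(combos)), function(i) {
    fuse(world$drugs[[combos$drugA[i]]], world$drugs[[combos$drugB[i]]],
         profiles[[combos$cell_line[i]]], world$universe)
  }, numeric(3 * G)))
}

#' Generate a pair of DE result tables with planted truth
#'
#' Each table plants `n_up` upregulated genes (`log2fc ~ U(1.2, 3)`,
#' `padj ~ U(0, 0.04)`), `n_down` mirrored downregulated genes, and fills
#' the rest with null genes that fail the default filter (either
#' `|log2fc| < 0.8` with any padj, or any log2fc with `padj > 0.1`).
#'
#' @param config [synthetic_config()].
#' @return list with `tables` (two data.frames with `gene_id`, `log2fc`,
#'   `padj`) and `truth` (planted `up` / `down` gene vectors per table).
#' @export
gen_deg_tables <- function(config) {
  if (config$n_up + config$n_down > config$n_genes) {
    stop("planted counts exceed n_genes")
  }
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  with_seed(config$seed + 2L, {
    one <- function() {
      planted <- sample(genes, config$n_up + config$n_down)
      up <- planted[seq_len(config$n_up)]
      down <- planted[config$n_up + seq_len(config$n_down)]
      null <- setdiff(genes, planted)
      lfc <- stats::setNames(numeric(length(genes)), genes)
      padj <- stats::setNames(numeric(length(genes)), genes)
      lfc[up] <- stats::runif(config$n_up, 1.2, 3)
      padj[up] <- stats::runif(config$n_up, 0, 0.04)
      lfc[down] <- -stats::runif(config$n_down, 1.2, 3)
      padj[down] <- stats::runif(config$n_down, 0, 0.04)
      weak <- stats::runif(length(null)) < 0.5
      lfc[null[weak]] <- stats::runif(sum(weak), -0.7, 0.7)
      padj[null[weak]] <- stats::runif(sum(weak))
      lfc[null[!weak]] <- stats::runif(sum(!weak), -3, 3)
      padj[null[!weak]] <- stats::runif(sum(!weak), 0.11, 1)
      list(table = data.frame(gene_id = genes, log2fc = unname(lfc),
                              padj = unname(padj), stringsAsFactors = FALSE),
           up = sort(up), down = sort(down))
    }
    t1 <- one(); t2 <- one()
    list(tables = list(t1$table, t2$table),
         truth = list(list(up = t1$up, down = t1$down),
                      list(up = t2$up, down = t2$down)))
  })
}

#' Generate six gene-source tables with duplicates and an ID mapping
#'
#' Emulates the curated-source assembly inputs: two DE-derived sources with
#' a `logFC` column, a LongevityMap-style table with an `Association`
#' column (including non-significant rows), a CellAge-style table with a
#' `Senescence Effect` column (including Unclear rows), and two
#' pass-through sources.  Duplicate rows are injected at
#' `duplication_rate`; a fraction of distinct labels is withheld from the
#' ID mapping.
#'
#' @param config [synthetic_config()].
#' @return list with `tables` (named list of data.frames), `rules` (named
#'   list of [source_rules()] matching each table), `mapping` (label -> id
#'   data.frame) and `truth` (`distinct_labels`, `n_distinct`,
#'   `n_mappable`).
#' @export
gen_source_tables <- function(config) {
  pool <- sprintf("AG%04d", seq_len(max(200L, config$n_genes)))
  n <- config$entries_per_source
  with_seed(config$seed + 3L, {
    dup <- function(labels) {
      k <- floor(length(labels) * config$duplication_rate)
      if (k > 0) c(labels, sample(labels, k, replace = TRUE)) else labels
    }
    kept <- list()

    deg_tab <- function() {
      lab <- sample(pool, n)
      keep_n <- ceiling(n * 0.6)
      lfc <- c(stats::runif(keep_n, 1.1, 3) *
                 sample(c(1, -1), keep_n, replace = TRUE),
               stats::runif(n - keep_n, -0.9, 0.9))
      lab_kept <- lab[seq_len(keep_n)]
      lab_all <- dup(lab_kept)
      # excluded rows appended undisturbed; duplicates only among kept rows
      tab <- data.frame(gene = c(lab_all, lab[(keep_n + 1):n]),
                        logFC = c(lfc[seq_len(keep_n)],
                                  sample(lfc[seq_len(keep_n)],
                                         length(lab_all) - keep_n,
                                         replace = TRUE),
                                  lfc[(keep_n + 1):n]),
                        stringsAsFactors = FALSE)
      list(tab = tab[sample.int(nrow(tab)), , drop = FALSE], kept = lab_kept)
    }
    g1 <- deg_tab(); g2 <- deg_tab()
    kept$deg_gse72815 <- g1$kept
    kept$deg_gse141595 <- g2$kept

    lab <- sample(pool, n)
    sig <- stats::runif(n) < 0.6
    lmap <- data.frame(gene = dup(lab[sig]),
                       Association = "significant", stringsAsFactors = FALSE)
    lmap <- rbind(lmap, data.frame(gene = lab[!sig],
                                   Association = "non-significant"))
    kept$longevitymap <- lab[sig]

    lab <- sample(pool, n)
    eff <- sample(c("Induces", "Inhibits", "Unclear"), n, replace = TRUE,
                  prob = c(0.45, 0.35, 0.2))
    clr <- eff != "Unclear"
    ca_lab <- dup(lab[clr])
    cellage <- data.frame(gene = c(ca_lab, lab[!clr]),
                          `Senescence Effect` = c(
                            sample(c("Induces", "Inhibits"),
                                   length(ca_lab), replace = TRUE),
                            rep("Unclear", sum(!clr))),
                          check.names = FALSE, stringsAsFactors = FALSE)
    kept$cellage <- lab[clr]

    lab <- sample(pool, n)
    genage <- data.frame(gene = dup(lab), stringsAsFactors = FALSE)
    kept$genage <- lab

    lab <- sample(pool, n)
    agingatlas <- data.frame(gene = dup(lab), stringsAsFactors = FALSE)
    kept$agingatlas <- lab

    distinct <- unique(canonicalize_gene(unlist(kept)))
    n_unmap <- floor(length(distinct) * config$unmappable_fraction)
    unmappable <- if (n_unmap > 0) sample(distinct, n_unmap) else character(0)
    mappable <- setdiff(distinct, unmappable)
    mapping <- data.frame(label = mappable,
                          id = sprintf("ENSG%06d", seq_along(mappable)),
                          stringsAsFactors = FALSE)

    tables <- list(deg_gse72815 = g1$tab, deg_gse141595 = g2$tab,
                   genage = genage, longevitymap = lmap, cellage = cellage,
                   agingatlas = agingatlas)
    rules <- list(
      deg_gse72815 = source_rules("gene", "logFC", "both"),
      deg_gse141595 = source_rules("gene", "logFC", "both"),
      genage = source_rules("gene"),
      longevitymap = source_rules("gene", "Association"),
      cellage = source_rules("gene", "Senescence Effect"),
      agingatlas = source_rules("gene"))
    list(tables = tables, rules = rules, mapping = mapping,
         truth = list(distinct_labels = sort(distinct),
                      n_distinct = length(distinct),
                      n_mappable = length(mappable)))
  })
}

#' Write all synthetic fixtures to a directory
#'
#' Emits the world (universe, drug targets, expression), a combination
#' table, DE tables, source tables, the ID mapping and a `truth.json`.
#'
#' @param config [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the list of written paths.
#' @export
simulate_to_dir <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- gen_world(config)
  combos <- gen_combos(world)
  degs <- gen_deg_tables(config)
  srcs <- gen_source_tables(config)
  p <- function(f) file.path(dir, f)

  writeLines(world$universe$genes, p("universe.txt"))
  dt <- do.call(rbind, lapply(names(world$drugs), function(d)
    data.frame(drug = d, target_gene = world$drugs[[d]])))
  write_tsv_table(dt, p("drug_targets.tsv"))
  expr_df <- data.frame(gene_id = rownames(world$expression),
                        world$expression, check.names = FALSE)
  write_tsv_table(expr_df, p("expression.tsv"))
  write_tsv_table(combos, p("combos.tsv"))
  write_tsv_table(degs$tables[[1]], p("deg_table_1.tsv"))
  write_tsv_table(degs$tables[[2]], p("deg_table_2.tsv"))
  for (nm in names(srcs$tables)) {
    write_tsv_table(srcs$tables[[nm]], p(paste0("source_", nm, ".tsv")))
  }
  write_tsv_table(srcs$mapping, p("id_mapping.tsv"))
  jsonlite::write_json(
    list(deg = list(table1 = degs$truth[[1]], table2 = degs$truth[[2]]),
         sources = srcs$truth,
         modules = world$modules,
         config = unclass(config)),
    p("truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}
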