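ns <- asNamespace("senosynergy")

test_that("generators are fully deterministic under a fixed seed", {
  cfg <- tiny_synth_config(seed = 31L)
  w1 <- gen_world(cfg); w2 <- gen_world(cfg)
  expect_identical(w1$drugs, w2$drugs)
  expect_identical(w1$expression, w2$expression)
  expect_identical(gen_combos(w1), gen_combos(w2))
  expect_identical(gen_deg_tables(cfg), gen_deg_tables(cfg))
  expect_identical(gen_source_tables(cfg), gen_source_tables(cfg))
  # and the generators do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_world(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("gen_world enforces the min-1 target rule and the module shift", {
  cfg <- tiny_synth_config(seed = 1L, targets_per_drug_mean = 0)
  w <- gen_world(cfg)
  expect_true(all(lengths(w$drugs) == 1L))
  expect_error(gen_world(tiny_synth_config(module_size = 500L)),
               "module_size")
  # module genes are upshifted: average the contrast over several seeds
  diffs <- vapply(1:10, function(s) {
    w <- gen_world(tiny_synth_config(seed = s))
    mean(vapply(colnames(w$expression), function(cl) {
      mod <- w$modules[[cl]]
      mean(w$expression[mod, cl]) -
        mean(w$expression[setdiff(rownames(w$expression), mod), cl])
    }, 0))
  }, 0)
  expect_gt(mean(diffs), 1.5)
})

test_that("combination labels follow the stated synergy formula", {
  # hand-crafted world: overlap 2, module hits 1 and 3, defaults
  genes <- sprintf("g%02d", 1:10)
  world <- list(
    universe = convert_ids(genes),
    drugs = list(A = c("G01", "G02", "G03"),
                 B = c("G02", "G03", "G04", "G05", "G06")),
    modules = list(c1 = c("G01", "G04", "G05", "G06")),
    config = synthetic_config(seed = 1L))
  expect_equal(ns$true_synergy(world, "A", "B", "c1"), 0 + 1 * 2 + 0.5 * 1 * 3)
  # symmetry in the drug pair
  expect_equal(ns$true_synergy(world, "B", "A", "c1"),
               ns$true_synergy(world, "A", "B", "c1"))

  # sigma = 0: labels equal the noiseless truth; disjoint targets and no
  # module hits give exactly beta0
  cfg0 <- tiny_synth_config(seed = 17L, sigma = 0)
  w <- gen_world(cfg0)
  combos <- gen_combos(w)
  expect_equal(combos$score, combos$truth)
  none <- combos[mapply(function(a, b, cl) {
    length(intersect(w$drugs[[a]], w$drugs[[b]])) == 0 &&
      (length(intersect(w$drugs[[a]], w$modules[[cl]])) == 0 ||
       length(intersect(w$drugs[[b]], w$modules[[cl]])) == 0)
  }, combos$drugA, combos$drugB, combos$cell_line), ]
  if (nrow(none) > 0) expect_true(all(none$score == cfg0$beta0))

  # noise calibration: sd(label - truth) ~ sigma
  cfgN <- synthetic_config(seed = 23L, n_combos = 4000L, sigma = 1.5)
  wN <- gen_world(cfgN)
  cN <- gen_combos(wN)
  expect_equal(sd(cN$score - cN$truth), 1.5, tolerance = 0.05)
})

test_that("gen_combos draws distinct pair-by-cell slots and validates", {
  cfg <- tiny_synth_config(seed = 3L)
  w <- gen_world(cfg)
  combos <- gen_combos(w)
  expect_identical(nrow(combos), cfg$n_combos)
  expect_true(all(combos$drugA != combos$drugB))
  key <- paste(pmin(combos$drugA, combos$drugB),
               pmax(combos$drugA, combos$drugB), combos$cell_line)
  expect_false(any(duplicated(key)))
  one <- gen_world(tiny_synth_config(n_drugs = 1L))
  expect_error(gen_combos(one), "at least 2")
  expect_error(gen_combos(w, tiny_synth_config(n_combos = 10000L)),
               "exceeds")
})

test_that("planted DEG counts guard against impossible configs", {
  expect_error(gen_deg_tables(synthetic_config(n_genes = 10L, n_up = 8L,
                                               n_down = 8L)),
               "exceed")
})

test_that("simulate_to_dir writes a loadable fixture set", {
  dir <- withr::local_tempdir()
  cfg <- tiny_synth_config(seed = 41L)
  simulate_to_dir(cfg, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  uni <- read_universe(file.path(dir, "universe.txt"))
  expect_identical(length(uni$genes), cfg$n_genes)
  tg <- read_drug_targets(file.path(dir, "drug_targets.tsv"))
  expect_identical(length(tg), as.integer(cfg$n_drugs))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_identical(dim(expr), c(cfg$n_genes, cfg$n_cell_lines))
  deg <- read_deg_table(file.path(dir, "deg_table_1.tsv"))
  res <- filter_deg(deg)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(res$up$members, truth$deg$table1$up)
})
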