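ns <- asNamespace("senosynergy")

test_that("early-stopping rule: patience epochs without improvement", {
  # validation losses 3.0, 2.0, 2.5, 2.6 with patience 2: best epoch 2,
  # stop fires at epoch 4
  st <- ns$stopper_init(2L)
  st <- ns$stopper_update(st, 1, 3.0)
  st <- ns$stopper_update(st, 2, 2.0)
  expect_false(st$stop)
  st <- ns$stopper_update(st, 3, 2.5)
  expect_false(st$stop)
  st <- ns$stopper_update(st, 4, 2.6)
  expect_true(st$stop)
  expect_identical(st$best_epoch, 2L)
  expect_equal(st$best_val, 2.0)
})

test_that("training is deterministic and records a coherent history", {
  cfgS <- tiny_synth_config()
  world <- gen_world(cfgS)
  combos <- gen_combos(world)
  X <- combos_to_features(world, combos)
  cfg <- tiny_model_config(max_epochs = 8L, patience = 3L)
  m1 <- train_model(build_model(cfg, length(world$universe$genes)),
                    X, combos$score)
  m2 <- train_model(build_model(cfg, length(world$universe$genes)),
                    X, combos$score)
  expect_identical(m1$history$epochs, m2$history$epochs)
  expect_identical(predict_fused(m1, X[1:5, ]), predict_fused(m2, X[1:5, ]))
  h <- m1$history
  expect_lte(h$best_epoch, h$stopped_epoch)
  expect_lte(h$stopped_epoch, cfg$max_epochs)
  # reported best val MSE is the minimum of the history
  expect_equal(h$best_val_mse, min(h$epochs$val_mse))
})

test_that("training on constant labels converges to the label value", {
  cfgS <- tiny_synth_config(seed = 21L)
  world <- gen_world(cfgS)
  combos <- gen_combos(world)
  X <- combos_to_features(world, combos)
  y <- rep(5, nrow(X))
  cfg <- tiny_model_config(seed = 21L, max_epochs = 30L, patience = 30L,
                           dropout = 0)
  m <- train_model(build_model(cfg, length(world$universe$genes)), X, y)
  pred <- predict_fused(m, X[1:20, ])
  expect_true(all(abs(pred - 5) < 0.5))
})

test_that("prediction is exactly order-symmetric", {
  cfgS <- tiny_synth_config(seed = 2L)
  world <- gen_world(cfgS)
  combos <- gen_combos(world)
  X <- combos_to_features(world, combos)
  cfg <- tiny_model_config(seed = 2L, max_epochs = 5L)
  m <- train_model(build_model(cfg, length(world$universe$genes)),
                   X, combos$score)
  prof <- align_profile(world$expression[, 1], world$universe)
  d <- names(world$drugs)
  ab <- predict_synergy(m, d[1], d[2], world$drugs, prof, world$universe)
  ba <- predict_synergy(m, d[2], d[1], world$drugs, prof, world$universe)
  expect_identical(ab, ba)
  # identical drugs: symmetrized mean equals the single pass
  aa <- predict_synergy(m, d[1], d[1], world$drugs, prof, world$universe)
  x <- fuse(world$drugs[[d[1]]], world$drugs[[d[1]]], prof, world$universe)
  expect_equal(aa, predict_fused(m, x, symmetrize = FALSE)[1])
  expect_error(
    predict_synergy(m, "no-such-drug", d[1], world$drugs, prof,
                    world$universe),
    "no-such-drug")
})

test_that("noiseless synthetic data is learnable above the mean-only baseline", {
  cfgS <- tiny_synth_config(seed = 5L, sigma = 0, n_combos = 180L,
                            n_cell_lines = 4L)
  world <- gen_world(cfgS)
  combos <- gen_combos(world)
  X <- combos_to_features(world, combos)
  tr <- 1:150; te <- 151:180
  cfg <- tiny_model_config(seed = 5L, max_epochs = 40L, patience = 40L,
                           dropout = 0)
  m <- train_model(build_model(cfg, length(world$universe$genes)),
                   X[tr, ], combos$score[tr])
  pred <- predict_fused(m, X[te, ])
  rho <- suppressWarnings(cor(pred, combos$truth[te], method = "spearman"))
  expect_gt(rho, 0)   # mean-only baseline has zero correlation
})

test_that("training rejects degenerate inputs", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, 10L)
  X <- matrix(rnorm(5 * 30), 5, 30)
  expect_error(train_model(m, X[1, , drop = FALSE], 1), "at least 2")
  expect_error(train_model(m, X, c(1, 2, NA, 4, 5)), "finite")
  # 5 rows at val_fraction 0.1 -> empty validation split
  expect_error(train_model(m, X, rep(1, 5)), "larger dataset")
})
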