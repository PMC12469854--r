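#' Attention-based synergy regressor
#'
#' A small transformer regressor over fused drug-pair / cell-line features.
#' The fused vector is split into its three semantic blocks (drug A, drug B,
#' cell line); each block passes through its own linear embedding plus a
#' learned token-type offset, giving a 3-token sequence.  The sequence runs
#' through post-norm multi-head self-attention blocks, tokens are
#' mean-pooled, and a two-hidden-layer feed-forward head produces the scalar
#' synergy score.  Training uses Adam on MSE loss with early stopping on a
#' seeded validation split, and drug-order symmetry is handled by swap
#' augmentation at train time plus order-averaging at prediction time.
#'
#' @name synergy_model
NULL

#' Model configuration
#'
#' @param d_model embedding width (must be divisible by `n_heads`).
#' @param n_heads attention heads per block.
#' @param n_blocks number of self-attention blocks.
#' @param head_hidden sizes of the two hidden layers of the prediction head.
#' @param dropout dropout rate in [0, 1), applied after attention, after the
#'   per-block feed-forward, and after each head hidden layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation-MSE
#'   improvement).
#' @param val_fraction fraction of combinations held out for validation.
#' @param seed integer seed driving initialization, the validation split,
#'   shuffling and dropout.
#' @return list of class `model_config`.
#' @export
model_config <- function(d_model = 128L, n_heads = 8L, n_blocks = 2L,
                         head_hidden = c(256L, 128L), dropout = 0.3,
                         learning_rate = 0.003, batch_size = 128L,
                         max_epochs = 100L, patience = 10L,
                         val_fraction = 0.1, seed = 1L) {
  stopifnot(d_model %% n_heads == 0, dropout >= 0, dropout < 1,
            patience <= max_epochs, length(head_hidden) == 2,
            val_fraction > 0, val_fraction < 1)
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_blocks = as.integer(n_blocks),
                 head_hidden = as.integer(head_hidden), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "model_config")
}

init_params <- function(config, G) {
  d <- config$d_model
  dff <- 4L * d
  emb <- lapply(1:3, function(k) list(W = glorot(G, d), b = numeric(d)))
  tok <- lapply(1:3, function(k) stats::rnorm(d, 0, 0.02))
  # residual-feeding projections (Wo, W2) are down-scaled by
  # 1/sqrt(2 * n_blocks): the standard stabilization for post-norm residual
  # stacks trained without a warmup schedule
  rs <- 1 / sqrt(2 * config$n_blocks)
  blocks <- lapply(seq_len(config$n_blocks), function(l) list(
    Wq = glorot(d, d), bq = numeric(d),
    Wk = glorot(d, d), bk = numeric(d),
    Wv = glorot(d, d), bv = numeric(d),
    Wo = glorot(d, d) * rs, bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    W1 = glorot(d, dff), b1 = numeric(dff),
    W2 = glorot(dff, d) * rs, b2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d)
  ))
  h1 <- config$head_hidden[1]; h2 <- config$head_hidden[2]
  head <- list(W1 = glorot(d, h1), b1 = numeric(h1),
               W2 = glorot(h1, h2), b2 = numeric(h2),
               W3 = glorot(h2, 1L), b3 = numeric(1))
  list(emb = emb, tok = tok, blocks = blocks, head = head)
}

#' Build an untrained synergy model
#'
#' Parameter initialization is seeded from `config$seed`: two models built
#' from the same config and universe size produce identical initial
#' predictions.
#'
#' @param config a [model_config()].
#' @param universe_size number of genes in the feature universe (each fused
#'   input row has length `3 * universe_size`).
#' @return object of class `synergy_model`.
#' @export
build_model <- function(config, universe_size) {
  stopifnot(inherits(config, "model_config"))
  if (universe_size < 1) stop("universe_size must be positive")
  params <- with_seed(config$seed, init_params(config, as.integer(universe_size)))
  structure(list(config = config, G = as.integer(universe_size),
                 params = params, standardizer = NULL, history = NULL,
                 trained = FALSE, universe_hash = NA_character_),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf(
    "<synergy_model: G=%d, d_model=%d, %d block(s) x %d heads, %s>\n",
    x$G, x$config$d_model, x$config$n_blocks, x$config$n_heads,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Full forward pass.  X is a standardized (batch x 3G) matrix.
model_forward <- function(params, X, config, train = FALSE) {
  G <- ncol(X) %/% 3L
  p <- config$dropout
  H <- vector("list", 3)
  Xb <- vector("list", 3)
  for (k in 1:3) {
    Xb[[k]] <- X[, ((k - 1) * G + 1):(k * G), drop = FALSE]
    H[[k]] <- addbias(Xb[[k]] %*% params$emb[[k]]$W,
                      params$emb[[k]]$b + params$tok[[k]])
  }
  caches <- vector("list", config$n_blocks)
  for (l in seq_len(config$n_blocks)) {
    blk <- params$blocks[[l]]
    at <- attn_forward(H, blk, config$n_heads)
    dr1 <- lapply(at$out, drop_forward, p = p, train = train)
    ln1 <- vector("list", 3); H1 <- vector("list", 3)
    for (i in 1:3) {
      ln1[[i]] <- ln_forward(H[[i]] + dr1[[i]]$y, blk$ln1_g, blk$ln1_b)
      H1[[i]] <- ln1[[i]]$y
    }
    Zpre <- lapply(H1, function(h) addbias(h %*% blk$W1, blk$b1))
    Z <- lapply(Zpre, relu)
    Fo <- lapply(Z, function(z) addbias(z %*% blk$W2, blk$b2))
    dr2 <- lapply(Fo, drop_forward, p = p, train = train)
    ln2 <- vector("list", 3); Hn <- vector("list", 3)
    for (i in 1:3) {
      ln2[[i]] <- ln_forward(H1[[i]] + dr2[[i]]$y, blk$ln2_g, blk$ln2_b)
      Hn[[i]] <- ln2[[i]]$y
    }
    caches[[l]] <- list(at = at$cache, dr1 = dr1, ln1 = ln1, H1 = H1,
                        Zpre = Zpre, Z = Z, dr2 = dr2, ln2 = ln2)
    H <- Hn
  }
  P <- (H[[1]] + H[[2]] + H[[3]]) / 3
  hd <- params$head
  A1pre <- addbias(P %*% hd$W1, hd$b1); A1 <- relu(A1pre)
  d1 <- drop_forward(A1, p, train)
  A2pre <- addbias(d1$y %*% hd$W2, hd$b2); A2 <- relu(A2pre)
  d2 <- drop_forward(A2, p, train)
  yhat <- as.numeric(addbias(d2$y %*% hd$W3, hd$b3))
  list(yhat = yhat,
       cache = list(Xb = Xb, blocks = caches, P = P, A1pre = A1pre, A1 = A1,
                    d1 = d1, A2pre = A2pre, A2 = A2, d2 = d2, G = G))
}

# Backward pass; dyhat is the gradient of the loss w.r.t. yhat (length B).
model_backward <- function(params, cache, dyhat, config) {
  B <- length(dyhat)
  hd <- params$head
  gr <- list()
  dy <- matrix(dyhat, B, 1)
  gr$head <- list()
  gr$head$W3 <- crossprod(cache$d2$y, dy)
  gr$head$b3 <- colSums(dy)
  dd2 <- dy %*% t(hd$W3)
  dA2 <- drop_backward(dd2, cache$d2)
  dA2pre <- dA2 * (cache$A2pre > 0)
  gr$head$W2 <- crossprod(cache$d1$y, dA2pre)
  gr$head$b2 <- colSums(dA2pre)
  dd1 <- dA2pre %*% t(hd$W2)
  dA1 <- drop_backward(dd1, cache$d1)
  dA1pre <- dA1 * (cache$A1pre > 0)
  gr$head$W1 <- crossprod(cache$P, dA1pre)
  gr$head$b1 <- colSums(dA1pre)
  dP <- dA1pre %*% t(hd$W1)

  dH <- lapply(1:3, function(i) dP / 3)
  gr$blocks <- vector("list", config$n_blocks)
  for (l in rev(seq_len(config$n_blocks))) {
    blk <- params$blocks[[l]]
    cc <- cache$blocks[[l]]
    g <- list()
    dH1 <- vector("list", 3)
    g$ln2_g <- 0; g$ln2_b <- 0
    g$W2 <- 0; g$b2 <- 0; g$W1 <- 0; g$b1 <- 0
    for (i in 1:3) {
      lb <- ln_backward(dH[[i]], cc$ln2[[i]], blk$ln2_g)
      g$ln2_g <- g$ln2_g + lb$dg; g$ln2_b <- g$ln2_b + lb$db
      dR2 <- lb$dx                       # grad at H1 + dropout(FFN)
      dF <- drop_backward(dR2, cc$dr2[[i]])
      g$W2 <- g$W2 + crossprod(cc$Z[[i]], dF)
      g$b2 <- g$b2 + colSums(dF)
      dZ <- (dF %*% t(blk$W2)) * (cc$Zpre[[i]] > 0)
      g$W1 <- g$W1 + crossprod(cc$H1[[i]], dZ)
      g$b1 <- g$b1 + colSums(dZ)
      dH1[[i]] <- dR2 + dZ %*% t(blk$W1)
    }
    g$ln1_g <- 0; g$ln1_b <- 0
    dA_out <- vector("list", 3)
    dHres <- vector("list", 3)
    for (i in 1:3) {
      lb <- ln_backward(dH1[[i]], cc$ln1[[i]], blk$ln1_g)
      g$ln1_g <- g$ln1_g + lb$dg; g$ln1_b <- g$ln1_b + lb$db
      dHres[[i]] <- lb$dx                # grad at H + dropout(attn)
      dA_out[[i]] <- drop_backward(lb$dx, cc$dr1[[i]])
    }
    ab <- attn_backward(dA_out, cc$at, blk, config$n_heads)
    for (i in 1:3) dH[[i]] <- dHres[[i]] + ab$dH[[i]]
    gr$blocks[[l]] <- c(ab$grads,
                        list(ln1_g = g$ln1_g, ln1_b = g$ln1_b,
                             W1 = g$W1, b1 = g$b1, W2 = g$W2, b2 = g$b2,
                             ln2_g = g$ln2_g, ln2_b = g$ln2_b))
  }
  gr$emb <- vector("list", 3)
  gr$tok <- vector("list", 3)
  for (k in 1:3) {
    gr$emb[[k]] <- list(W = crossprod(cache$Xb[[k]], dH[[k]]),
                        b = colSums(dH[[k]]))
    gr$tok[[k]] <- colSums(dH[[k]])
  }
  # reorder to match the params tree exactly
  ord <- function(tmpl, got) {
    if (is.list(tmpl)) {
      out <- vector("list", length(tmpl)); names(out) <- names(tmpl)
      nm <- names(tmpl)
      for (i in seq_along(tmpl)) {
        gi <- if (is.null(nm) || !nzchar(nm[i])) got[[i]] else got[[nm[i]]]
        out[[i]] <- ord(tmpl[[i]], gi)
      }
      out
    } else got
  }
  ord(params, gr)
}

# Swap the two drug blocks of raw fused rows [x_A | x_B | x_cell].
swap_blocks <- function(X, G) {
  X[, c((G + 1):(2 * G), 1:G, (2 * G + 1):(3 * G)), drop = FALSE]
}

mse <- function(a, b) mean((a - b)^2)

# Early-stopping bookkeeping, factored out so the stated stopping rule is
# testable in isolation: stop once `patience` epochs have elapsed since the
# best validation loss; the best epoch's weights are what training returns.
stopper_init <- function(patience) {
  list(best_val = Inf, best_epoch = 0L, patience = as.integer(patience),
       improved = FALSE, stop = FALSE)
}

stopper_update <- function(st, epoch, val_mse) {
  if (val_mse < st$best_val) {
    st$best_val <- val_mse
    st$best_epoch <- as.integer(epoch)
    st$improved <- TRUE
  } else {
    st$improved <- FALSE
    if (epoch - st$best_epoch >= st$patience) st$stop <- TRUE
  }
  st
}

eval_mse <- function(params, X, y, config, batch = 512L) {
  n <- nrow(X)
  tot <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    fw <- model_forward(params, X[s:e, , drop = FALSE], config, train = FALSE)
    tot <- tot + sum((fw$yhat - y[s:e])^2)
  }
  tot / n
}

#' Train a synergy model
#'
#' Rows are split into train/validation at the combination level with a
#' seeded draw; the training set is augmented with the drug-swapped copy of
#' every row; the standardizer is fitted on the (augmented) training rows
#' only and stored in the model.  Training minimizes MSE with Adam, stops
#' when validation MSE has not improved for `patience` epochs (or at
#' `max_epochs`), and restores the weights of the best epoch.
#'
#' @param model an untrained (or re-trainable) [build_model()] result.
#' @param X raw (unstandardized) fused feature matrix, one combination per
#'   row, layout `[x_A | x_B | x_cell]`.
#' @param y numeric synergy labels.
#' @param verbose print per-epoch losses.
#' @return the trained model, with `$history` (per-epoch train/val MSE,
#'   `best_epoch`, `stopped_epoch`) and `$standardizer` attached.
#' @export
train_model <- function(model, X, y, verbose = FALSE) {
  stopifnot(inherits(model, "synergy_model"), is.matrix(X),
            nrow(X) == length(y))
  if (nrow(X) < 2) stop("need at least 2 combinations to train")
  if (any(!is.finite(y))) stop("labels must be finite")
  config <- model$config
  G <- model$G
  if (ncol(X) != 3 * G) stop("feature width does not match 3 * universe size")
  n <- nrow(X)
  n_val <- floor(n * config$val_fraction)
  if (n_val < 1) {
    stop("validation split is empty at this dataset size; ",
         "provide a larger dataset or raise val_fraction")
  }

  with_seed(config$seed + 1L, {
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- rbind(X[tr_idx, , drop = FALSE],
                 swap_blocks(X[tr_idx, , drop = FALSE], G))
    ytr <- c(y[tr_idx], y[tr_idx])
    std <- fit_standardizer(Xtr)
    Xtr <- apply_standardizer(std, Xtr)
    Xval <- apply_standardizer(std, X[val_idx, , drop = FALSE])
    yval <- y[val_idx]

    params <- model$params
    state <- adam_init(params)
    stp <- stopper_init(config$patience)
    best_params <- params
    hist_tr <- numeric(0); hist_val <- numeric(0)
    ntr <- nrow(Xtr)
    stopped <- config$max_epochs
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(ntr)
      tr_loss_num <- 0
      for (s in seq(1, ntr, by = config$batch_size)) {
        e <- min(s + config$batch_size - 1, ntr)
        rows <- perm[s:e]
        xb <- Xtr[rows, , drop = FALSE]
        yb <- ytr[rows]
        fw <- model_forward(params, xb, config, train = TRUE)
        resid <- fw$yhat - yb
        tr_loss_num <- tr_loss_num + sum(resid^2)
        dyhat <- 2 * resid / length(yb)
        grads <- model_backward(params, fw$cache, dyhat, config)
        st <- adam_step(params, grads, state, config$learning_rate)
        params <- st$params; state <- st$state
      }
      train_mse <- tr_loss_num / ntr
      val_mse <- eval_mse(params, Xval, yval, config)
      hist_tr <- c(hist_tr, train_mse); hist_val <- c(hist_val, val_mse)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        train_mse, val_mse))
      }
      stp <- stopper_update(stp, epoch, val_mse)
      if (stp$improved) best_params <- params
      stopped <- epoch
      if (stp$stop) break
    }
    model$params <- best_params
    model$standardizer <- std
    model$trained <- TRUE
    model$history <- list(
      epochs = data.frame(epoch = seq_along(hist_tr), train_mse = hist_tr,
                          val_mse = hist_val),
      best_epoch = stp$best_epoch, stopped_epoch = stopped,
      best_val_mse = stp$best_val)
    model
  })
}

#' Predict synergy scores for standardized or raw fused rows
#'
#' Low-level batch interface: `Xraw` rows are standardized with the
#' training-time standardizer and passed through the network with dropout
#' disabled.  Order symmetry is handled by averaging with the drug-swapped
#' rows.
#'
#' @param model trained `synergy_model`.
#' @param Xraw raw fused feature matrix (rows `[x_A | x_B | x_cell]`).
#' @param symmetrize average the forward passes of `(A, B)` and `(B, A)`
#'   orders (default TRUE).
#' @return numeric vector of predicted scores.
#' @export
predict_fused <- function(model, Xraw, symmetrize = TRUE) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (is.null(model$standardizer)) stop("standardizer not fitted")
  if (is.null(dim(Xraw))) Xraw <- matrix(Xraw, nrow = 1)
  X1 <- apply_standardizer(model$standardizer, Xraw)
  p1 <- model_forward(model$params, X1, model$config, train = FALSE)$yhat
  if (!symmetrize) return(p1)
  X2 <- apply_standardizer(model$standardizer, swap_blocks(Xraw, model$G))
  p2 <- model_forward(model$params, X2, model$config, train = FALSE)$yhat
  (p1 + p2) / 2
}

#' Predict the synergy score of one drug pair in a cell-line context
#'
#' @param model trained `synergy_model`.
#' @param drug_a,drug_b canonical drug names present in `drug_targets`.
#' @param drug_targets named list drug -> target gene IDs (see
#'   [read_drug_targets()]).
#' @param cell_profile expression vector aligned to `universe` (see
#'   [align_profile()]).
#' @param universe `gene_universe` the model was trained over.
#' @return scalar predicted synergy score (order-symmetric by construction).
#' @export
predict_synergy <- function(model, drug_a, drug_b, drug_targets,
                            cell_profile, universe) {
  for (d in c(drug_a, drug_b)) {
    if (!d %in% names(drug_targets)) {
      stop("drug absent from the drug-target table: ", d)
    }
  }
  x <- fuse(drug_targets[[drug_a]], drug_targets[[drug_b]], cell_profile,
            universe)
  predict_fused(model, x)[1]
}

# --- checkpoint serialization (JSON; text-only, dimension-preserving) -------

ser_tree <- function(x) {
  if (is.list(x)) lapply(x, ser_tree)
  else if (is.matrix(x)) list(.dim = dim(x), .data = as.numeric(x))
  else as.numeric(x)
}

deser_tree <- function(x) {
  if (is.list(x) && !is.null(x$.dim)) {
    d <- as.integer(unlist(x$.dim))
    matrix(as.numeric(unlist(x$.data)), d[1], d[2])
  } else if (is.list(x) && length(x) > 0 &&
             !any(vapply(x, is.list, logical(1)))) {
    as.numeric(unlist(x))         # leaf vector read back as a list of scalars
  } else if (is.list(x)) {
    lapply(x, deser_tree)
  } else {
    as.numeric(x)
  }
}

#' Hash a gene universe for checkpoint consistency checks
#'
#' Order-sensitive polynomial checksum of the universe gene list; not
#' cryptographic, only a guard against pairing a checkpoint with the wrong
#' universe.
#'
#' @param universe `gene_universe`.
#' @return character checksum.
#' @export
universe_hash <- function(universe) {
  h <- 0
  mod <- 2^31 - 1
  for (ch in utf8ToInt(paste(universe$genes, collapse = "\n"))) {
    h <- (h * 131 + ch) %% mod
  }
  sprintf("u%d-%.0f", length(universe$genes), h)
}

#' Save / load a model checkpoint
#'
#' Single JSON file holding the config, all weights, the fitted
#' standardizer and the universe hash.
#'
#' @param model `synergy_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config), G = model$G,
              params = ser_tree(model$params),
              standardizer = if (is.null(model$standardizer)) NULL else
                list(means = model$standardizer$means,
                     stds = model$standardizer$stds),
              trained = model$trained,
              universe_hash = model$universe_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(model_config, lapply(obj$config, function(v)
    if (length(v) > 1) unlist(v) else v[[1]]))
  m <- build_model(cfg, obj$G[[1]])
  m$params <- deser_tree(obj$params)
  if (!is.null(obj$standardizer)) {
    m$standardizer <- structure(
      list(means = as.numeric(unlist(obj$standardizer$means)),
           stds = as.numeric(unlist(obj$standardizer$stds))),
      class = "standardizer")
  }
  m$trained <- isTRUE(obj$trained[[1]])
  m$universe_hash <- if (is.null(obj$universe_hash)) NA_character_
                     else as.character(obj$universe_hash[[1]])
  m
}
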