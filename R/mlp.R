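# Multi-output feedforward network trained with a masked mean-squared-error
# loss, so phenotypes missing for a participant contribute nothing to the
# gradient. Written in base-R matrix algebra (BLAS does the heavy lifting);
# sizes here are a few thousand participants by a few hundred edges.

#' Configuration for the multi-output feedforward network
#'
#' @param hidden Integer vector of hidden-layer widths (>= 1 layer).
#' @param dropout Dropout rate on hidden activations during training, in
#'   `[0, 1)`.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience: stop after this many epochs
#'   without validation-loss improvement; the best-epoch weights are kept.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(256, 128, 64), dropout = 0.3, lr = 1e-3,
                       batch_size = 128, max_epochs = 100, patience = 10,
                       seed = 1) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1), all(hidden == round(hidden)))
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "mlp_config")
}

# He-normal initial weights for layer sizes c(d_in, hidden..., d_out).
mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    list(w = matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

# Forward pass. With keep_hidden, stores per layer its input and, for hidden
# layers, the combined ReLU/dropout derivative multiplier (dmask), so the
# backward pass is exact including the inverted-dropout 1/(1-p) scale.
mlp_forward <- function(layers, x, dropout = 0, keep_hidden = FALSE) {
  nl <- length(layers)
  hs <- if (keep_hidden) vector("list", nl) else NULL
  h <- x
  for (l in seq_len(nl)) {
    a <- sweep(h %*% layers[[l]]$w, 2, layers[[l]]$b, "+")
    if (l < nl) {
      dmask <- (a > 0) * 1
      if (dropout > 0) {
        keep <- matrix((stats::runif(length(a)) >= dropout) / (1 - dropout),
                       nrow(a), ncol(a))
        dmask <- dmask * keep
      }
      h2 <- a * dmask
    } else {
      dmask <- NULL
      h2 <- a
    }
    if (keep_hidden) hs[[l]] <- list(input = h, dmask = dmask)
    h <- h2
  }
  if (keep_hidden) list(out = h, hs = hs) else h
}

# One Adam step on the masked-MSE gradient for a minibatch.
# trainable: logical per layer (frozen layers get no update and, once no
# trainable layer remains below, propagation stops).
mlp_backward_step <- function(layers, state, x, y, mask, cfg, trainable, t_step) {
  nl <- length(layers)
  fw <- mlp_forward(layers, x, dropout = cfg$dropout, keep_hidden = TRUE)
  diff <- fw$out - y
  diff[!mask] <- 0
  grad_out <- 2 * diff / max(sum(mask), 1)
  for (l in rev(seq_len(nl))) {
    w_pre <- layers[[l]]$w
    if (trainable[l]) {
      gw <- crossprod(fw$hs[[l]]$input, grad_out)
      gb <- colSums(grad_out)
      for (nm in c("w", "b")) {
        g <- if (nm == "w") gw else gb
        st <- state[[l]][[nm]]
        st$m <- 0.9 * st$m + 0.1 * g
        st$v <- 0.999 * st$v + 0.001 * g^2
        mhat <- st$m / (1 - 0.9^t_step)
        vhat <- st$v / (1 - 0.999^t_step)
        layers[[l]][[nm]] <- layers[[l]][[nm]] - cfg$lr * mhat / (sqrt(vhat) + 1e-8)
        state[[l]][[nm]] <- st
      }
    }
    if (l == 1 || !any(trainable[seq_len(l - 1)])) break
    grad_out <- tcrossprod(grad_out, w_pre) * fw$hs[[l - 1]]$dmask
  }
  list(layers = layers, state = state)
}

masked_mse <- function(pred, y, mask) {
  d <- (pred - y)
  d[!mask] <- 0
  sum(d^2) / max(sum(mask), 1)
}

#' Train the multi-output feedforward network on a source dataset
#'
#' Minimizes masked mean-squared error over all phenotypes jointly (missing
#' entries excluded from loss and gradient), with ReLU hidden layers,
#' inverted dropout, Adam updates, and early stopping on a validation
#' split. Targets are z-scored per phenotype with training-split statistics
#' before fitting and predictions are de-standardized on output, so the
#' multi-output loss is on one scale across phenotypes.
#'
#' @param x Numeric matrix, participants x features (normalized FC vectors).
#' @param y Numeric matrix, participants x phenotypes; `NA` = missing.
#' @param config An [mlp_config()].
#' @param val_idx Row indices used for early stopping (the 20% split); if
#'   `NULL`, a seeded 80/20 split is drawn.
#' @return Object of class `mlp_model`.
#' @export
train_mlp <- function(x, y, config = mlp_config(), val_idx = NULL) {
  stopifnot(is.matrix(x))
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  stopifnot(nrow(x) == nrow(y))
  n <- nrow(x)
  if (is.null(val_idx)) {
    val_idx <- with_local_seed(config$seed + 1L,
                               sample(n, max(1, round(0.2 * n))))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0) stop("empty train split", call. = FALSE)
  mask <- is.finite(y)
  if (any(colSums(mask[tr_idx, , drop = FALSE]) == 0)) {
    # all-masked phenotype columns carry no gradient; keep them but warn
    warning("phenotype column(s) with no observed training entries")
  }
  yc <- colMeans2_masked(y, mask, tr_idx)
  ys <- colSds_masked(y, mask, tr_idx, yc)
  ys[!is.finite(ys) | ys < 1e-12] <- 1
  yz <- sweep(sweep(y, 2, yc), 2, ys, "/")
  yz[!mask] <- 0

  sizes <- c(ncol(x), config$hidden, ncol(y))
  # separate streams for initialization and for the shuffle/dropout draws,
  # so the training trajectory of shared parameters does not depend on how
  # many draws the output layer's initialization consumed
  seeds <- derive_seeds(config$seed, 2L)
  layers0 <- with_local_seed(seeds[1], mlp_init(sizes))
  with_local_seed(seeds[2], {
    layers <- layers0
    state <- lapply(layers, function(l) list(
      w = list(m = l$w * 0, v = l$w * 0),
      b = list(m = l$b * 0, v = l$b * 0)))
    trainable <- rep(TRUE, length(layers))
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    wait <- 0L; t_step <- 0L
    history <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / config$batch_size)
      for (b in seq_len(nb)) {
        rows <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, length(ord))]
        t_step <- t_step + 1L
        upd <- mlp_backward_step(layers, state, x[rows, , drop = FALSE],
                                 yz[rows, , drop = FALSE],
                                 mask[rows, , drop = FALSE],
                                 config, trainable, t_step)
        layers <- upd$layers; state <- upd$state
      }
      vp <- mlp_forward(layers, x[val_idx, , drop = FALSE])
      vl <- masked_mse(vp, yz[val_idx, , drop = FALSE], mask[val_idx, , drop = FALSE])
      history <- c(history, vl)
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, layers = layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(
      layers = best$layers, sizes = sizes, config = config,
      y_center = yc, y_scale = ys, phenotype_names = colnames(y),
      best_epoch = best$epoch, val_history = history
    ), class = "mlp_model")
  })
}

colMeans2_masked <- function(y, mask, rows) {
  vapply(seq_len(ncol(y)), function(j) {
    v <- y[rows, j][mask[rows, j]]
    if (length(v) == 0) 0 else mean(v)
  }, numeric(1))
}

colSds_masked <- function(y, mask, rows, ctr) {
  vapply(seq_len(ncol(y)), function(j) {
    v <- y[rows, j][mask[rows, j]]
    if (length(v) < 2) 1 else stats::sd(v)
  }, numeric(1))
}

#' @export
predict.mlp_model <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != object$sizes[1]) {
    stop("feature length mismatch: network input is ", object$sizes[1],
         ", got ", ncol(newx), call. = FALSE)
  }
  out <- mlp_forward(object$layers, newx)  # dropout disabled: deterministic
  out <- sweep(sweep(out, 2, object$y_scale, "*"), 2, object$y_center, "+")
  colnames(out) <- object$phenotype_names
  out
}
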