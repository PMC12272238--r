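# Classical transfer learning: re-initialize the pre-trained network's output
# layer for the single target phenotype and fine-tune only the last two
# layers on the K adaptation participants.

#' Configuration for fine-tuning the pre-trained network
#'
#' @param lr_grid Candidate fixed learning rates for the 5-fold grid search.
#' @param max_epochs Fine-tuning epoch cap (default 10).
#' @param patience Stop when validation loss fails to improve for this many
#'   consecutive epochs within the cap (default 3).
#' @param n_folds Folds for the learning-rate search (default 5).
#' @param seed Integer seed (output-layer initialization, folds, shuffling).
#' @return A list of class `finetune_config`.
#' @export
finetune_config <- function(lr_grid = c(1e-4, 1e-3, 1e-2), max_epochs = 10,
                            patience = 3, n_folds = 5, seed = 1) {
  stopifnot(length(lr_grid) >= 1, all(lr_grid > 0), max_epochs >= 1)
  structure(list(lr_grid = lr_grid, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "finetune_config")
}

# Core loop: fine-tune the last two layers at a fixed lr on rows `tr`, early
# stopping on rows `va` (if non-empty). Returns the layer list.
finetune_run <- function(layers, x, yz, tr, va, lr, cfg_mlp, config, seed) {
  nl <- length(layers)
  trainable <- rep(FALSE, nl)
  trainable[c(nl - 1, nl)] <- TRUE
  cfg <- cfg_mlp
  cfg$lr <- lr
  mask1 <- matrix(TRUE, length(tr), 1)
  with_local_seed(seed, {
    state <- lapply(layers, function(l) list(
      w = list(m = l$w * 0, v = l$w * 0),
      b = list(m = l$b * 0, v = l$b * 0)))
    best <- list(loss = Inf, layers = layers)
    wait <- 0L; t_step <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr)
      nb <- ceiling(length(ord) / cfg$batch_size)
      for (b in seq_len(nb)) {
        rows <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, length(ord))]
        t_step <- t_step + 1L
        upd <- mlp_backward_step(layers, state, x[rows, , drop = FALSE],
                                 yz[rows, , drop = FALSE],
                                 matrix(TRUE, length(rows), 1),
                                 cfg, trainable, t_step)
        layers <- upd$layers; state <- upd$state
      }
      if (length(va) > 0) {
        vl <- masked_mse(mlp_forward(layers, x[va, , drop = FALSE]),
                         yz[va, , drop = FALSE], matrix(TRUE, length(va), 1))
        if (vl < best$loss - 1e-12) {
          best <- list(loss = vl, layers = layers); wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      } else {
        best <- list(loss = NA_real_, layers = layers)
      }
    }
    best$layers
  })
}

#' Fine-tune the pre-trained network on K target participants
#'
#' The pre-trained multi-output network's last layer is replaced by a freshly
#' initialized single-output layer; only the last two layers (final hidden +
#' output) are updated. A fixed learning rate is chosen by `n_folds`-fold
#' cross-validation and grid search over `config$lr_grid`; the final model is
#' fine-tuned on all K participants with an 80/20 early-stopping split, a
#' 10-epoch cap by default. All parameters outside the last two layers are
#' bit-identical to the pre-trained network.
#'
#' @param pretrained An [train_mlp()] model.
#' @param x Numeric matrix, K x features (normalized FC vectors).
#' @param y Numeric target vector, length K, fully observed.
#' @param config A [finetune_config()].
#' @return Object of class `finetuned_mlp` (single output).
#' @export
finetune_mlp <- function(pretrained, x, y, config = finetune_config()) {
  stopifnot(inherits(pretrained, "mlp_model"), is.matrix(x),
            length(y) == nrow(x))
  if (anyNA(y)) stop("fine-tuning target must be observed for all K participants", call. = FALSE)
  k <- nrow(x)
  if (k < config$n_folds) {
    stop("K = ", k, " participants is below the ", config$n_folds,
         "-fold protocol minimum", call. = FALSE)
  }
  if (ncol(x) != pretrained$sizes[1]) {
    stop("feature length mismatch: network input is ", pretrained$sizes[1],
         call. = FALSE)
  }
  ym <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd < 1e-12) ysd <- 1
  yz <- matrix((y - ym) / ysd, ncol = 1)

  nl <- length(pretrained$layers)
  d_hidden <- pretrained$sizes[nl]   # width of the last hidden layer
  seeds <- derive_seeds(config$seed, length(config$lr_grid) + 3L)
  base_layers <- pretrained$layers
  # fresh single-output layer, same He-normal initializer family as pretraining
  base_layers[[nl]] <- with_local_seed(seeds[1], list(
    w = matrix(stats::rnorm(d_hidden, sd = sqrt(2 / d_hidden)), d_hidden, 1),
    b = 0))
  cfg_mlp <- pretrained$config
  cfg_mlp$dropout <- 0  # K is small; dropout off during adaptation

  split8020 <- function(idx, seed) {
    nva <- max(1, round(0.2 * length(idx)))
    va <- with_local_seed(seed, sample(idx, nva))
    list(tr = setdiff(idx, va), va = va)
  }

  lr <- config$lr_grid[1]
  cv <- NULL
  if (length(config$lr_grid) > 1) {
    folds <- make_folds(k, config$n_folds, seeds[2])
    err <- matrix(NA_real_, config$n_folds, length(config$lr_grid))
    for (f in seq_len(config$n_folds)) {
      tr_all <- which(folds != f); va_f <- which(folds == f)
      sp <- split8020(tr_all, seeds[3] + f)
      for (g in seq_along(config$lr_grid)) {
        ly <- finetune_run(base_layers, x, yz, sp$tr, sp$va,
                           config$lr_grid[g], cfg_mlp, config, seeds[3 + g])
        pr <- mlp_forward(ly, x[va_f, , drop = FALSE])
        err[f, g] <- mean((pr - yz[va_f, 1])^2)
      }
    }
    scores <- colMeans(err)
    lr <- config$lr_grid[which.min(scores)]
    cv <- tibble::tibble(lr = config$lr_grid, cv_mse = scores)
  }
  sp <- split8020(seq_len(k), seeds[2])
  layers <- finetune_run(base_layers, x, yz, sp$tr, sp$va, lr, cfg_mlp,
                         config, seeds[3])
  structure(list(
    layers = layers, sizes = c(pretrained$sizes[-length(pretrained$sizes)], 1L),
    lr = lr, cv = cv, y_center = ym, y_scale = ysd,
    frozen_layers = seq_len(nl - 2)
  ), class = "finetuned_mlp")
}

#' @export
predict.finetuned_mlp <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != object$sizes[1]) {
    stop("feature length mismatch: network input is ", object$sizes[1],
         ", got ", ncol(newx), call. = FALSE)
  }
  drop(mlp_forward(object$layers, newx)) * object$y_scale + object$y_center
}
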