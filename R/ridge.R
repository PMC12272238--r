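# Ridge-family solvers. One eigendecomposition of the smaller Gram matrix is
# shared across the whole lambda grid, which keeps 5-fold CV over 21 lambdas
# cheap even at a few thousand participants.

# Weights for every lambda of a centered ridge problem.
# X: n x d (already centered), y: length n (already centered).
# Returns d x length(lambdas) matrix of weights.
ridge_weights_path <- function(xc, yc, lambdas) {
  n <- nrow(xc); d <- ncol(xc)
  if (d <= n) {
    eg <- eigen(crossprod(xc), symmetric = TRUE)
    xty <- crossprod(xc, yc)            # d x 1
    vty <- crossprod(eg$vectors, xty)   # d x 1
    w <- vapply(lambdas, function(l) {
      dd <- eg$values + l
      if (min(dd) <= 1e-12 * max(dd, 1e-300)) dd <- pmax(dd, 1e-12 * max(dd, .Machine$double.xmin))
      drop(eg$vectors %*% (vty / dd))
    }, numeric(d))
  } else {
    eg <- eigen(tcrossprod(xc), symmetric = TRUE)
    vty <- crossprod(eg$vectors, yc)    # n x 1
    w <- vapply(lambdas, function(l) {
      dd <- eg$values + l
      if (min(dd) <= 1e-12 * max(dd, 1e-300)) dd <- pmax(dd, 1e-12 * max(dd, .Machine$double.xmin))
      alpha <- eg$vectors %*% (vty / dd)
      drop(crossprod(xc, alpha))
    }, numeric(d))
  }
  matrix(w, nrow = d)
}

#' Fit a linear ridge regression model for one phenotype
#'
#' Ridge regression with an unpenalized intercept (fitted by centering), the
#' regularization weight chosen by grid search with `n_folds`-fold
#' cross-validation on the observed rows, and the final weights refit on all
#' observed rows with the chosen lambda. Missing target entries (`NA`) are
#' dropped row-wise.
#'
#' @param x Numeric matrix, participants x features.
#' @param y Numeric target vector (length `nrow(x)`), `NA` = missing.
#' @param lambda Fixed regularization weight; if `NULL` (default), tuned on
#'   `lambda_grid`.
#' @param lambda_grid Candidate grid, see [default_lambda_grid()].
#' @param n_folds Folds for cross-validation (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `lrr_model`: weights, intercept, chosen
#'   `lambda`, and the CV score table (`cv`, mean squared validation error
#'   per candidate).
#' @export
lrr <- function(x, y, lambda = NULL, lambda_grid = default_lambda_grid(),
                n_folds = 5, seed = 1) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  obs <- which(is.finite(y))
  if (length(obs) == 0) stop("all target values are missing", call. = FALSE)
  xo <- x[obs, , drop = FALSE]
  yo <- y[obs]
  cv <- NULL
  if (is.null(lambda)) {
    if (length(obs) < n_folds) {
      stop("need >= ", n_folds, " observed participants for ", n_folds,
           "-fold tuning, got ", length(obs), call. = FALSE)
    }
    folds <- make_folds(length(obs), n_folds, seed)
    err <- matrix(NA_real_, n_folds, length(lambda_grid))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      xm <- colMeans(xo[tr, , drop = FALSE]); ym <- mean(yo[tr])
      w <- ridge_weights_path(sweep(xo[tr, , drop = FALSE], 2, xm), yo[tr] - ym,
                              lambda_grid)
      pred <- sweep(xo[!tr, , drop = FALSE], 2, xm) %*% w + ym
      err[f, ] <- colMeans((pred - yo[!tr])^2)
    }
    scores <- colMeans(err)
    lambda <- pick_lambda(lambda_grid, scores)
    cv <- tibble::tibble(lambda = lambda_grid, cv_mse = scores)
  }
  xm <- colMeans(xo); ym <- mean(yo)
  w <- drop(ridge_weights_path(sweep(xo, 2, xm), yo - ym, lambda))
  structure(list(
    weights = w, intercept = ym - sum(xm * w), lambda = lambda,
    n_train = length(obs), cv = cv,
    feature_names = colnames(x)
  ), class = "lrr_model")
}

#' @export
predict.lrr_model <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != length(object$weights)) {
    stop("feature length mismatch: model has ", length(object$weights),
         ", input has ", ncol(newx), call. = FALSE)
  }
  drop(newx %*% object$weights) + object$intercept
}

# Dual solve of (K + lambda I) alpha = yc on observed rows, eigen shared
# across lambdas. Returns matrix n x length(lambdas) of dual coefficients.
krr_alpha_path <- function(k, yc, lambdas, on_singular = c("error", "guard")) {
  on_singular <- match.arg(on_singular)
  eg <- eigen(k, symmetric = TRUE)
  vty <- crossprod(eg$vectors, yc)
  vapply(lambdas, function(l) {
    dd <- eg$values + l
    if (min(dd) <= 1e-10 * max(abs(dd), 1e-300)) {
      if (on_singular == "error") {
        stop("kernel system is singular at lambda = ", l,
             " (duplicate or collinear participants); use lambda > 0",
             call. = FALSE)
      }
      dd <- pmax(dd, 1e-10 * max(abs(dd), .Machine$double.xmin))
    }
    drop(eg$vectors %*% (vty / dd))
  }, numeric(nrow(k)))
}

#' Fit kernel ridge regression on a precomputed kernel
#'
#' Solves the dual system `(K + lambda I) alpha = y - mean(y)` on the rows
#' whose target is observed. Targets are mean-centered before the solve and
#' the mean is added back at prediction time (a correlation kernel has no
#' intercept pathway of its own).
#'
#' @param k Symmetric kernel matrix over training participants.
#' @param y Target vector, `NA` = missing.
#' @param lambda Nonnegative regularization weight.
#' @return Object of class `krr_fit` with `alpha` (dual coefficients on
#'   observed rows), `y_mean`, `obs` (observed row indices), `lambda`.
#' @export
fit_krr <- function(k, y, lambda) {
  stopifnot(is.matrix(k), nrow(k) == ncol(k), length(y) == nrow(k), lambda >= 0)
  obs <- which(is.finite(y))
  if (length(obs) < 2) stop("need >= 2 observed targets", call. = FALSE)
  ko <- k[obs, obs, drop = FALSE]
  ym <- mean(y[obs])
  alpha <- drop(krr_alpha_path(ko, y[obs] - ym, lambda, on_singular = "error"))
  structure(list(alpha = alpha, y_mean = ym, obs = obs, lambda = lambda),
            class = "krr_fit")
}

#' Tune and fit correlation-kernel KRR on feature rows
#'
#' The participant-by-participant kernel is the Pearson correlation of
#' feature vectors ([correlation_kernel()]). Lambda is tuned by
#' `n_folds`-fold cross-validation on the observed participants (mean
#' squared validation error; ties broken toward the larger lambda) and the
#' final model is refit on all observed participants with the chosen value.
#'
#' @param x Numeric matrix, participants x features. Stored in the model:
#'   evaluating the kernel on new participants needs the training features.
#' @param y Target vector, `NA` = missing.
#' @param lambda Fixed lambda; if `NULL`, tuned on `lambda_grid`.
#' @inheritParams lrr
#' @return Object of class `krr_model`: training features, dual
#'   coefficients, target mean, chosen `lambda`, CV table.
#' @export
krr <- function(x, y, lambda = NULL, lambda_grid = default_lambda_grid(),
                n_folds = 5, seed = 1) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  obs <- which(is.finite(y))
  if (length(obs) < 2) stop("need >= 2 observed targets", call. = FALSE)
  xo <- x[obs, , drop = FALSE]
  yo <- y[obs]
  k <- correlation_kernel(xo)
  cv <- NULL
  if (is.null(lambda)) {
    if (length(obs) < n_folds) {
      stop("need >= ", n_folds, " observed participants for ", n_folds,
           "-fold tuning, got ", length(obs), call. = FALSE)
    }
    folds <- make_folds(length(obs), n_folds, seed)
    err <- matrix(NA_real_, n_folds, length(lambda_grid))
    for (f in seq_len(n_folds)) {
      tr <- which(folds != f); va <- which(folds == f)
      ym <- mean(yo[tr])
      a <- krr_alpha_path(k[tr, tr, drop = FALSE], yo[tr] - ym, lambda_grid,
                          on_singular = "guard")
      pred <- k[va, tr, drop = FALSE] %*% a + ym
      err[f, ] <- colMeans((pred - yo[va])^2)
    }
    scores <- colMeans(err)
    lambda <- pick_lambda(lambda_grid, scores)
    cv <- tibble::tibble(lambda = lambda_grid, cv_mse = scores)
  }
  ym <- mean(yo)
  alpha <- drop(krr_alpha_path(k, yo - ym, lambda, on_singular = "guard"))
  res <- k %*% alpha + lambda * alpha - (yo - ym)
  structure(list(
    x_train = xo, alpha = alpha, y_mean = ym, lambda = lambda,
    n_train = length(obs), cv = cv,
    dual_residual = sqrt(sum(res^2)) / max(sqrt(sum((yo - ym)^2)), 1e-300)
  ), class = "krr_model")
}

#' @export
predict.krr_model <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != ncol(object$x_train)) {
    stop("feature length mismatch: model trained on ", ncol(object$x_train),
         " features, input has ", ncol(newx), call. = FALSE)
  }
  kx <- correlation_kernel(newx, object$x_train)
  drop(kx %*% object$alpha) + object$y_mean
}
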