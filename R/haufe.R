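# Haufe-transform feature importance: the covariance of each FC edge with
# the model's predicted phenotype. For a linear predictor this is the
# activation pattern Sigma w, the interpretable counterpart of the weight
# vector.

#' Haufe-transform importance map
#'
#' Per-edge sample covariance (unbiased, n - 1 denominator) between the edge
#' value and the predicted phenotype across participants. A positive value
#' means higher connectivity at that edge goes with the model predicting a
#' greater phenotype value.
#'
#' @param x Numeric matrix, participants x edges (n >= 3), canonical edge
#'   order.
#' @param predictions Numeric vector of model predictions, length `nrow(x)`,
#'   non-constant.
#' @param source Label recorded on the map (e.g. `"multilayer@K100"`).
#' @return Numeric vector of length `ncol(x)` of class `importance_map` with
#'   attribute `source`.
#' @export
haufe_importance <- function(x, predictions, source = "model") {
  stopifnot(is.matrix(x), length(predictions) == nrow(x))
  if (nrow(x) < 3) stop("need >= 3 participants for a covariance", call. = FALSE)
  if (stats::sd(predictions) < 1e-300) {
    stop("degenerate input: constant predictions have no covariance pattern",
         call. = FALSE)
  }
  v <- drop(crossprod(sweep(x, 2, colMeans(x)),
                      predictions - mean(predictions))) / (nrow(x) - 1)
  structure(v, class = "importance_map", source = source)
}

#' Pseudo-ground-truth importance map from the full target sample
#'
#' Trains correlation-kernel KRR (lambda by 5-fold CV) on all participants
#' with the target observed, then Haufe-transforms its in-sample predictions
#' over those same participants. Used as the reference against which the
#' small-sample approaches' maps are scored.
#'
#' @param x Feature matrix, participants x edges.
#' @param y Target vector, `NA` = missing.
#' @param lambda_grid Grid for lambda.
#' @param seed Integer seed (CV folds).
#' @return An `importance_map` with source `"pseudo_ground_truth"`.
#' @export
pseudo_ground_truth <- function(x, y, lambda_grid = default_lambda_grid(),
                                seed = 1) {
  obs <- which(is.finite(y))
  xo <- x[obs, , drop = FALSE]
  m <- krr(xo, y[obs], lambda_grid = lambda_grid, seed = seed)
  haufe_importance(xo, predict(m, xo), source = "pseudo_ground_truth")
}

#' Agreement between two importance maps
#'
#' Pearson correlation of the two maps (identical edge order required).
#'
#' @param a,b `importance_map`s or numeric vectors of equal length.
#' @return Pearson correlation.
#' @export
importance_agreement <- function(a, b) {
  if (length(a) != length(b)) {
    stop("importance maps differ in length: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Importance map as a tidy edge table
#'
#' @param map An `importance_map` of length `P(P-1)/2`.
#' @return Tibble with `edge_i`, `edge_j` (parcel indices, i > j), `value`.
#' @export
importance_table <- function(map) {
  e <- length(map)
  p <- as.integer(round((1 + sqrt(1 + 8 * e)) / 2))
  idx <- edge_index(p)
  tibble::tibble(edge_i = idx$i, edge_j = idx$j, value = as.numeric(map))
}
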