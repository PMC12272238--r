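#' Derive a stream of child seeds from one top-level seed
#'
#' Every random stage of a pipeline draws its seed from this stream so a
#' single top-level seed makes the whole run (fold assignments, K-shot
#' repetitions, network initialization, bootstraps) exactly replayable.
#'
#' @param seed Integer top-level seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in \[1, 2^31 - 2\].
#' @export
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Fold labels 1..n_folds for n observations, deterministic given seed.
make_folds <- function(n, n_folds, seed) {
  if (n < n_folds) {
    stop("cannot make ", n_folds, "-fold splits from ", n,
         " observations; use fewer folds or more participants", call. = FALSE)
  }
  with_local_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

#' Default regularization grid for ridge-family models
#'
#' Logarithmic grid of 21 values: 0 plus 20 points spanning 1e-4 to 1e4,
#' covering under- to over-regularized regimes.
#'
#' @return Numeric vector of length 21, increasing.
#' @export
default_lambda_grid <- function() {
  c(0, 10^seq(-4, 4, length.out = 20))
}

# Largest value among those attaining the minimum score (ties -> stronger
# regularization).
pick_lambda <- function(lambdas, scores) {
  ok <- is.finite(scores)
  if (!any(ok)) stop("no lambda in the grid produced a finite CV score", call. = FALSE)
  best <- min(scores[ok])
  tol <- 1e-12 * max(1, abs(best))
  max(lambdas[ok & scores <= best + tol])
}
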