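# Approach builders for the K-shot protocol. Each returns a function
# f(x_all, y_shot, shot, eval_idx, seed) -> predictions for eval_idx, the
# contract run_kshot_experiment() expects. Builders that reuse frozen base
# learners cache the base-feature matrix for the dataset they are applied
# to, since those features do not depend on the K-shot draw.

#' Classical KRR baseline for the K-shot protocol
#'
#' Trains correlation-kernel KRR on the raw FC vectors of the K shot
#' participants (lambda by 5-fold CV, refit on all K) and predicts the
#' evaluation participants. No meta-training is used.
#'
#' @param lambda_grid Grid for lambda.
#' @return An approach function for [run_kshot_experiment()].
#' @export
approach_classical_krr <- function(lambda_grid = default_lambda_grid()) {
  function(x_all, y_shot, shot, eval_idx, seed) {
    m <- krr(x_all[shot, , drop = FALSE], y_shot, lambda_grid = lambda_grid,
             seed = seed)
    predict(m, x_all[eval_idx, , drop = FALSE])
  }
}

#' Transfer-learning baseline for the K-shot protocol
#'
#' Fine-tunes the pre-trained multi-output network ([finetune_mlp()]) on the
#' K shot participants' normalized FC vectors.
#'
#' @param pretrained The extra-large dataset's [train_mlp()] network.
#' @param config A [finetune_config()]; its seed is replaced per repetition.
#' @return An approach function.
#' @export
approach_transfer <- function(pretrained, config = finetune_config()) {
  force(pretrained)
  cache <- new.env(parent = emptyenv())
  function(x_all, y_shot, shot, eval_idx, seed) {
    if (is.null(cache$x) || !identical(cache$x, x_all)) {
      cache$x <- x_all
      cache$xn <- normalize_features(x_all)
    }
    cfg <- config
    cfg$seed <- as.integer(seed %% 2147483647)
    m <- finetune_mlp(pretrained, cache$xn[shot, , drop = FALSE], y_shot, cfg)
    predict(m, cache$xn[eval_idx, , drop = FALSE])
  }
}

#' Meta-matching approaches for the K-shot protocol
#'
#' Builds the stacking-variant approach over a trained multilayer hierarchy.
#' The base-learner feature matrix for the target dataset is computed once
#' and cached; only the final stacking KRR is refit per repetition.
#'
#' @param model A [train_multilayer()] hierarchy.
#' @param variant `"stacking"`, `"dataset_stacking"` or `"multilayer"`.
#' @param families Extra-large families for the single-source variant.
#' @param lambda_grid Grid for the stacking KRR lambda.
#' @return An approach function.
#' @export
approach_meta_matching <- function(model,
                                   variant = c("multilayer", "dataset_stacking", "stacking"),
                                   families = "mlp",
                                   lambda_grid = default_lambda_grid()) {
  variant <- match.arg(variant)
  force(model)
  cache <- new.env(parent = emptyenv())
  function(x_all, y_shot, shot, eval_idx, seed) {
    if (is.null(cache$x) || !identical(cache$x, x_all)) {
      cache$x <- x_all
      cache$feats <- switch(variant,
        multilayer = multilayer_features(model, x_all),
        dataset_stacking = dataset_stacking_features(model, x_all),
        stacking = single_source_features(model, x_all, families = families))
    }
    sm <- fit_stacking(cache$feats[shot, , drop = FALSE], y_shot,
                       lambda_grid = lambda_grid, seed = seed)
    predict(sm, cache$feats[eval_idx, , drop = FALSE])
  }
}

#' The five standard approaches of the evaluation protocol
#'
#' Classical KRR, transfer learning, single-source meta-matching with
#' stacking, meta-matching with dataset stacking, and multilayer
#' meta-matching, as a named list for [run_kshot_experiment()].
#'
#' @param model A [train_multilayer()] hierarchy (its extra-large bundle's
#'   network is the transfer-learning pretrained model).
#' @param lambda_grid Ridge/KRR grid.
#' @param finetune_cfg A [finetune_config()].
#' @return Named list of approach functions.
#' @export
standard_approaches <- function(model, lambda_grid = default_lambda_grid(),
                                finetune_cfg = finetune_config()) {
  stopifnot(inherits(model, "multilayer_model"))
  pre <- model$bundles[[model$order$xl]]$mlp
  list(
    classical_krr = approach_classical_krr(lambda_grid),
    transfer = approach_transfer(pre, finetune_cfg),
    stacking = approach_meta_matching(model, "stacking", lambda_grid = lambda_grid),
    dataset_stacking = approach_meta_matching(model, "dataset_stacking",
                                              lambda_grid = lambda_grid),
    multilayer = approach_meta_matching(model, "multilayer",
                                        lambda_grid = lambda_grid)
  )
}
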