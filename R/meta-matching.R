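# The translation strategies: base-learner bundles per source dataset,
# meta-matching with stacking (single source), meta-matching with dataset
# stacking, and the multilayer cascade that re-predicts each smaller
# dataset's phenotypes from upstream predictions before the final stacking.

#' Feature-count bookkeeping for the stacking variants
#'
#' With extra-large phenotype count `t_xl` and the other datasets' counts
#' `t_other`, dataset stacking exposes `2 * t_xl + sum(t_other)` prediction
#' features and the multilayer cascade `2 * t_xl + 2 * sum(t_other)` (each
#' non-extra-large dataset contributes its direct predictions plus as many
#' stacked ones). The reference configuration 67/36/23/42/61 gives 296 and
#' 458 = 134 + 72 + 46 + 84 + 122.
#'
#' @param t_xl Phenotype count of the extra-large dataset.
#' @param t_other Integer vector of the remaining datasets' counts.
#' @return Integer feature count.
#' @export
multilayer_feature_count <- function(t_xl, t_other = integer(0)) {
  as.integer(2 * t_xl + 2 * sum(t_other))
}

#' @rdname multilayer_feature_count
#' @export
dataset_stacking_feature_count <- function(t_xl, t_other = integer(0)) {
  as.integer(2 * t_xl + sum(t_other))
}

col_labels <- function(dataset, family, phenotypes) {
  paste(dataset, family, phenotypes, sep = "|")
}

#' Train the base learners of one source dataset
#'
#' For an extra-large dataset, a multi-output network plus one linear ridge
#' model per phenotype, both on the 80% training split (the network
#' early-stops on the 20% split; each ridge model's lambda is tuned by
#' 5-fold CV within the training split). For large/medium datasets, one
#' ridge model per phenotype tuned by 5-fold CV on the full dataset and
#' refit on the full dataset. Features are normalized per participant before
#' training.
#'
#' @param dataset A [source_dataset()].
#' @param lambda_grid Ridge grid, see [default_lambda_grid()].
#' @param mlp_cfg An [mlp_config()] (extra-large only).
#' @param seed Integer seed.
#' @return Object of class `base_bundle` with `families` `c("mlp", "lrr")`
#'   for extra-large datasets, `"lrr"` otherwise.
#' @export
train_base_bundle <- function(dataset, lambda_grid = default_lambda_grid(),
                              mlp_cfg = mlp_config(), seed = 1) {
  stopifnot(inherits(dataset, "source_dataset"))
  xn <- normalize_features(dataset$features)
  phen <- dataset$phenotypes
  t_n <- ncol(phen)
  seeds <- derive_seeds(seed, t_n + 1L)
  xl <- dataset$size_class == "extra_large"
  tr <- which(dataset$split == "train")
  mlp <- NULL
  if (xl) {
    cfg <- mlp_cfg
    cfg$seed <- seeds[t_n + 1L]
    mlp <- train_mlp(xn, phen, cfg, val_idx = which(dataset$split == "val"))
  }
  rows <- if (xl) tr else seq_len(nrow(xn))
  lrr_models <- lapply(seq_len(t_n), function(j) {
    lrr(xn[rows, , drop = FALSE], phen[rows, j], lambda_grid = lambda_grid,
        seed = seeds[j])
  })
  names(lrr_models) <- colnames(phen)
  structure(list(
    dataset_name = dataset$name, size_class = dataset$size_class,
    phenotype_names = colnames(phen),
    families = if (xl) c("mlp", "lrr") else "lrr",
    mlp = mlp, lrr = lrr_models, n_features = ncol(xn)
  ), class = "base_bundle")
}

#' Predictions of one bundle's base learners
#'
#' Applies the bundle's trained model families to new participants and
#' returns the prediction matrix in canonical column order (family, then
#' phenotype), with `dataset|family|phenotype` column labels.
#'
#' @param bundle A [train_base_bundle()].
#' @param x Feature matrix (raw or already normalized; rows are normalized
#'   per participant, an idempotent operation).
#' @param families Subset of the bundle's families to emit (default all).
#' @return Numeric matrix N x C with labeled columns.
#' @export
generate_base_predictions <- function(bundle, x, families = bundle$families) {
  stopifnot(inherits(bundle, "base_bundle"))
  if (!all(families %in% bundle$families)) {
    stop("bundle '", bundle$dataset_name, "' has no trained family: ",
         paste(setdiff(families, bundle$families), collapse = ", "),
         call. = FALSE)
  }
  if (ncol(x) != bundle$n_features) {
    stop("feature length mismatch: bundle trained on ", bundle$n_features,
         " edges, input has ", ncol(x), call. = FALSE)
  }
  xn <- normalize_features(x)
  blocks <- lapply(families, function(fam) {
    if (fam == "mlp") {
      p <- predict(bundle$mlp, xn)
    } else {
      p <- vapply(bundle$lrr, function(m) predict(m, xn), numeric(nrow(xn)))
      if (nrow(xn) == 1) p <- matrix(p, nrow = 1)
    }
    colnames(p) <- col_labels(bundle$dataset_name, fam, bundle$phenotype_names)
    p
  })
  do.call(cbind, blocks)
}

#' Train a stacking meta-learner on prediction features
#'
#' The meta-learner is correlation-kernel KRR over the base-learner
#' prediction vectors: lambda tuned by 5-fold CV on the K participants,
#' final model refit on all K. All C columns are always used (no feature
#' truncation at small K). Columns are z-scored with the K participants'
#' statistics before the kernel (stored, reapplied at prediction) so
#' heterogeneous phenotype units contribute comparably.
#'
#' @param features Numeric matrix K x C of base-learner predictions with
#'   column labels (C >= 2).
#' @param y Target vector, length K.
#' @param lambda_grid Grid for the KRR lambda.
#' @param n_folds CV folds (default 5; K must be >= this).
#' @param seed Integer seed.
#' @param target_name Stored label for the predicted phenotype.
#' @return Object of class `stacking_model`.
#' @export
fit_stacking <- function(features, y, lambda_grid = default_lambda_grid(),
                         n_folds = 5, seed = 1, target_name = "target") {
  stopifnot(is.matrix(features), length(y) == nrow(features))
  obs <- which(is.finite(y))
  if (length(obs) < n_folds) {
    stop("stacking needs >= ", n_folds, " participants with observed target (",
         n_folds, "-fold CV), got ", length(obs), call. = FALSE)
  }
  if (ncol(features) < 2) {
    stop("stacking needs >= 2 prediction features for the correlation kernel",
         call. = FALSE)
  }
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  }
  fo <- features[obs, , drop = FALSE]
  rowvar <- apply(fo, 1, stats::var)
  if (any(rowvar < 1e-24)) {
    stop("degenerate input: constant prediction-feature row(s) ",
         paste(utils::head(obs[rowvar < 1e-24], 3), collapse = ", "),
         call. = FALSE)
  }
  ctr <- colMeans(fo)
  scl <- apply(fo, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  fz <- sweep(sweep(fo, 2, ctr), 2, scl, "/")
  model <- krr(fz, y[obs], lambda_grid = lambda_grid, n_folds = n_folds,
               seed = seed)
  structure(list(
    krr = model, col_center = ctr, col_scale = scl,
    input_labels = colnames(features), target_name = target_name
  ), class = "stacking_model")
}

#' @export
predict.stacking_model <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(object$input_labels)) {
    stop("stacking model expects ", length(object$input_labels),
         " prediction features, got ", ncol(features), call. = FALSE)
  }
  if (!is.null(colnames(features))) {
    if (!setequal(colnames(features), object$input_labels)) {
      stop("prediction-feature labels do not match the training labels",
           call. = FALSE)
    }
    features <- features[, object$input_labels, drop = FALSE]
  }
  fz <- sweep(sweep(features, 2, object$col_center), 2, object$col_scale, "/")
  predict(object$krr, fz)
}

#' Train the full multilayer meta-matching hierarchy
#'
#' Stage 1 trains the extra-large dataset's network + ridge bundle. Stage 2
#' trains each large dataset's ridge bundle plus, per large phenotype, a
#' stacking model predicting it from the extra-large predictions (2 * T_xl
#' columns), on the full large dataset. Stage 3 does the same for each
#' medium dataset from the extra-large predictions plus the large datasets'
#' direct ridge predictions. The resulting hierarchy maps an FC vector to
#' `multilayer_feature_count()` stacked prediction features.
#'
#' @param sources List of [source_dataset()]; exactly one must have
#'   `size_class "extra_large"`.
#' @param lambda_grid Ridge/KRR grid.
#' @param mlp_cfg [mlp_config()] for the extra-large network.
#' @param seed Integer seed.
#' @return Object of class `multilayer_model`.
#' @export
train_multilayer <- function(sources, lambda_grid = default_lambda_grid(),
                             mlp_cfg = mlp_config(), seed = 1) {
  stopifnot(length(sources) >= 1,
            all(vapply(sources, inherits, TRUE, "source_dataset")))
  cls <- vapply(sources, function(s) s$size_class, character(1))
  if (sum(cls == "extra_large") != 1) {
    stop("multilayer training needs exactly one extra-large source dataset, got ",
         sum(cls == "extra_large"), call. = FALSE)
  }
  ord <- order(match(cls, c("extra_large", "large", "medium")))
  sources <- sources[ord]; cls <- cls[ord]
  seeds <- derive_seeds(seed, length(sources) * 2L)
  bundles <- lapply(seq_along(sources), function(i) {
    train_base_bundle(sources[[i]], lambda_grid, mlp_cfg, seed = seeds[i])
  })
  names(bundles) <- vapply(bundles, function(b) b$dataset_name, character(1))
  xl <- which(cls == "extra_large")
  large <- which(cls == "large")
  medium <- which(cls == "medium")

  stack_on <- function(di, upstream_of) {
    ds <- sources[[di]]
    up <- do.call(cbind, lapply(upstream_of, function(fn) fn(ds$features)))
    sseeds <- derive_seeds(seeds[length(sources) + di], ncol(ds$phenotypes))
    models <- lapply(seq_len(ncol(ds$phenotypes)), function(j) {
      fit_stacking(up, ds$phenotypes[, j], lambda_grid = lambda_grid,
                   seed = sseeds[j], target_name = colnames(ds$phenotypes)[j])
    })
    names(models) <- colnames(ds$phenotypes)
    models
  }
  xl_pred <- function(x) generate_base_predictions(bundles[[xl]], x)
  stackers <- list()
  for (di in large) {
    stackers[[sources[[di]]$name]] <- stack_on(di, list(xl_pred))
  }
  large_lrr_pred <- lapply(large, function(di) {
    force(di)
    function(x) generate_base_predictions(bundles[[di]], x, families = "lrr")
  })
  for (di in medium) {
    stackers[[sources[[di]]$name]] <- stack_on(di, c(list(xl_pred), large_lrr_pred))
  }
  t_xl <- length(bundles[[xl]]$phenotype_names)
  t_other <- vapply(bundles[-xl], function(b) length(b$phenotype_names), integer(1))
  structure(list(
    bundles = bundles,
    order = list(xl = xl, large = large, medium = medium),
    stackers = stackers,
    total_feature_count = multilayer_feature_count(t_xl, t_other),
    dataset_stacking_count = dataset_stacking_feature_count(t_xl, t_other)
  ), class = "multilayer_model")
}

#' @export
print.multilayer_model <- function(x, ...) {
  cat(sprintf("<multilayer_model> %d bundles (%s), %d multilayer / %d dataset-stacking features\n",
              length(x$bundles),
              paste(names(x$bundles), collapse = ", "),
              x$total_feature_count, x$dataset_stacking_count))
  invisible(x)
}

#' Stacked prediction features of the multilayer hierarchy
#'
#' Concatenates, in canonical order, the extra-large network + ridge
#' predictions, then per large dataset its direct ridge predictions and its
#' stacked re-predictions, then the same for each medium dataset. Column
#' count equals `model$total_feature_count`.
#'
#' @param model A [train_multilayer()] hierarchy.
#' @param x FC feature matrix (participants x edges).
#' @return Labeled numeric matrix, N x `total_feature_count`.
#' @export
multilayer_features <- function(model, x) {
  stopifnot(inherits(model, "multilayer_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  bs <- model$bundles
  xl <- model$order$xl
  up_xl <- generate_base_predictions(bs[[xl]], x)
  large_lrr <- lapply(model$order$large, function(di) {
    generate_base_predictions(bs[[di]], x, families = "lrr")
  })
  stacked_block <- function(di, upstream) {
    b <- bs[[di]]
    sm <- model$stackers[[b$dataset_name]]
    p <- vapply(sm, function(m) predict(m, upstream), numeric(nrow(x)))
    if (nrow(x) == 1) p <- matrix(p, nrow = 1)
    colnames(p) <- col_labels(b$dataset_name, "stack", b$phenotype_names)
    p
  }
  blocks <- list(up_xl)
  for (i in seq_along(model$order$large)) {
    di <- model$order$large[i]
    blocks <- c(blocks, list(large_lrr[[i]], stacked_block(di, up_xl)))
  }
  up_med <- if (length(model$order$large)) {
    do.call(cbind, c(list(up_xl), large_lrr))
  } else {
    up_xl
  }
  for (di in model$order$medium) {
    blocks <- c(blocks, list(
      generate_base_predictions(bs[[di]], x, families = "lrr"),
      stacked_block(di, up_med)))
  }
  out <- do.call(cbind, blocks)
  stopifnot(ncol(out) == model$total_feature_count)
  out
}

#' Prediction features for meta-matching with dataset stacking
#'
#' Extra-large network + ridge predictions concatenated with every other
#' dataset's direct ridge predictions (no intermediate stacking).
#'
#' @inheritParams multilayer_features
#' @return Labeled matrix, N x `model$dataset_stacking_count`.
#' @export
dataset_stacking_features <- function(model, x) {
  stopifnot(inherits(model, "multilayer_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  bs <- model$bundles
  blocks <- c(list(generate_base_predictions(bs[[model$order$xl]], x)),
              lapply(c(model$order$large, model$order$medium), function(di) {
                generate_base_predictions(bs[[di]], x, families = "lrr")
              }))
  do.call(cbind, blocks)
}

#' Prediction features for single-source meta-matching with stacking
#'
#' The extra-large dataset's predictions only; by default the network family
#' alone (T_xl columns), optionally both families (2 * T_xl).
#'
#' @inheritParams multilayer_features
#' @param families Families of the extra-large bundle to use.
#' @return Labeled matrix.
#' @export
single_source_features <- function(model, x, families = "mlp") {
  stopifnot(inherits(model, "multilayer_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  generate_base_predictions(model$bundles[[model$order$xl]], x,
                            families = families)
}

#' Adapt the trained hierarchy to a new target phenotype with K participants
#'
#' Builds the variant's prediction features for the K adaptation
#' participants and trains the final stacking KRR (lambda by 5-fold CV on
#' the K participants, refit on all K).
#'
#' @param model A [train_multilayer()] hierarchy.
#' @param x FC feature matrix of the K participants.
#' @param y Observed target values, length K.
#' @param variant `"stacking"` (single source), `"dataset_stacking"`, or
#'   `"multilayer"`.
#' @param families Extra-large families for `variant = "stacking"`.
#' @param lambda_grid,n_folds,seed Passed to [fit_stacking()].
#' @return Object of class `adapted_model`; `predict()` maps new FC rows to
#'   target-phenotype predictions.
#' @export
adapt_stacking <- function(model, x, y,
                           variant = c("multilayer", "dataset_stacking", "stacking"),
                           families = "mlp",
                           lambda_grid = default_lambda_grid(),
                           n_folds = 5, seed = 1) {
  variant <- match.arg(variant)
  feats <- switch(variant,
    multilayer = multilayer_features(model, x),
    dataset_stacking = dataset_stacking_features(model, x),
    stacking = single_source_features(model, x, families = families))
  sm <- fit_stacking(feats, y, lambda_grid = lambda_grid, n_folds = n_folds,
                     seed = seed)
  structure(list(model = model, stacker = sm, variant = variant,
                 families = families, n_shot = sum(is.finite(y))),
            class = "adapted_model")
}

#' @export
predict.adapted_model <- function(object, newx, ...) {
  feats <- switch(object$variant,
    multilayer = multilayer_features(object$model, newx),
    dataset_stacking = dataset_stacking_features(object$model, newx),
    stacking = single_source_features(object$model, newx,
                                      families = object$families))
  predict(object$stacker, feats)
}
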