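test_that("feature-count bookkeeping is conserved across variants", {
  # column-census oracle on the tiny trained hierarchy (T = 4/3/2)
  m <- tiny_multilayer()
  expect_identical(m$total_feature_count, multilayer_feature_count(4, c(3, 2)))
  expect_identical(m$dataset_stacking_count,
                   dataset_stacking_feature_count(4, c(3, 2)))
  x <- tiny_collection()$target$features[1:7, ]
  f <- multilayer_features(m, x)
  expect_identical(dim(f), c(7L, 18L))
  expected_labels <- c(
    paste0("xl|mlp|xl_phen_0", 1:4), paste0("xl|lrr|xl_phen_0", 1:4),
    paste0("lg|lrr|lg_phen_0", 1:3), paste0("lg|stack|lg_phen_0", 1:3),
    paste0("md|lrr|md_phen_0", 1:2), paste0("md|stack|md_phen_0", 1:2))
  expect_identical(colnames(f), expected_labels)

  fd <- dataset_stacking_features(m, x)
  expect_identical(ncol(fd), 13L)
  fs <- single_source_features(m, x)
  expect_identical(colnames(fs), paste0("xl|mlp|xl_phen_0", 1:4))

  # conservation identity: multilayer - dataset_stacking = sum of the other
  # datasets' phenotype counts, for arbitrary configurations
  for (t_other in list(c(36, 23, 42, 61), c(3, 2), integer(0), 7)) {
    expect_identical(multilayer_feature_count(20, t_other) -
                       dataset_stacking_feature_count(20, t_other),
                     as.integer(sum(t_other)))
  }
})

test_that("base-prediction generation validates bundle state and inputs", {
  m <- tiny_multilayer()
  md_bundle <- m$bundles[["md"]]
  expect_error(generate_base_predictions(md_bundle, tiny_collection()$target$features,
                                         families = "mlp"),
               "no trained family")
  expect_error(generate_base_predictions(m$bundles[["xl"]],
                                         matrix(rnorm(10), 2, 5)),
               "feature length mismatch")
  # single-phenotype single-family bundle yields one labeled column
  p <- generate_base_predictions(md_bundle, tiny_collection()$target$features[1:3, ],
                                 families = "lrr")
  expect_identical(ncol(p), 2L)
})

test_that("stacking protocol constraints and permutation covariance hold", {
  with_fixed_seed(50, {
    f <- matrix(rnorm(40 * 6), 40, 6)
    colnames(f) <- paste0("c", 1:6)
    y <- f[, 3] + rnorm(40, sd = 0.4)
  })
  expect_error(fit_stacking(f[1:4, ], y[1:4]), ">= 5")
  expect_error(fit_stacking(f[, 1, drop = FALSE], y), ">= 2 prediction features")
  f_const <- f; f_const[2, ] <- 5
  expect_error(fit_stacking(f_const, y), "constant prediction-feature row")

  sm <- fit_stacking(f, y, lambda_grid = fast_grid, seed = 1)
  with_fixed_seed(51, fnew <- matrix(rnorm(10 * 6), 10, 6,
                                     dimnames = list(NULL, paste0("c", 1:6))))
  p1 <- predict(sm, fnew)
  # permuting input columns together with their labels changes nothing
  perm <- c(4, 1, 6, 2, 5, 3)
  sm2 <- fit_stacking(f[, perm], y, lambda_grid = fast_grid, seed = 1)
  p2 <- predict(sm2, fnew[, perm])
  expect_equal(p1, p2, tolerance = 1e-10)
  # label-aware reordering at prediction time
  expect_equal(predict(sm, fnew[, perm]), p1, tolerance = 1e-12)

  # K = 10 with C = 67 prediction features: all columns retained
  with_fixed_seed(52, {
    f67 <- matrix(rnorm(10 * 67), 10, 67)
    y10 <- rnorm(10)
  })
  sm67 <- fit_stacking(f67, y10, lambda_grid = fast_grid, seed = 2)
  expect_length(sm67$input_labels, 67L)
})

test_that("stacking recovers a single informative column", {
  # target equals one input column plus noise; held-out correlation must be
  # close to (or better than) the best single column's
  with_fixed_seed(53, {
    f_tr <- matrix(rnorm(600 * 24), 600, 24)
    f_te <- matrix(rnorm(400 * 24), 400, 24)
    colnames(f_tr) <- colnames(f_te) <- paste0("c", 1:24)
    y_tr <- f_tr[, 5] + rnorm(600, sd = 0.3)
    y_te <- f_te[, 5] + rnorm(400, sd = 0.3)
  })
  sm <- fit_stacking(f_tr, y_tr, seed = 3)
  r_stack <- cor(predict(sm, f_te), y_te)
  r_best_col <- max(apply(f_te, 2, cor, y = y_te))
  expect_gte(r_stack, r_best_col - 0.05)
})

test_that("multilayer training validates grouping and degenerates gracefully", {
  coll <- tiny_collection()
  expect_error(train_multilayer(coll$sources[2:3]), "exactly one extra-large")
  # extra-large alone: two families, no intermediate stackers
  m1 <- train_multilayer(coll$sources[1], lambda_grid = fast_grid,
                         mlp_cfg = fast_mlp_cfg(), seed = 5)
  expect_identical(m1$total_feature_count, 8L)
  expect_length(m1$stackers, 0L)
  f <- multilayer_features(m1, coll$target$features[1:4, ])
  expect_identical(ncol(f), 8L)
})

test_that("adaptation wires the right feature set per variant", {
  m <- tiny_multilayer()
  coll <- tiny_collection()
  y <- coll$target$phenotypes[, 1]
  xk <- coll$target$features[1:30, ]
  for (cfg in list(list(v = "stacking", n = 4L), list(v = "dataset_stacking", n = 13L),
                   list(v = "multilayer", n = 18L))) {
    a <- adapt_stacking(m, xk, y[1:30], variant = cfg$v,
                        lambda_grid = fast_grid, seed = 6)
    expect_length(a$stacker$input_labels, cfg$n)
    p <- predict(a, coll$target$features[31:40, ])
    expect_length(p, 10L)
  }
})

test_that("meta-matching beats classical KRR when the target phenotype is an
          oracle copy of a source phenotype", {
  # target = same canonical direction as a source phenotype, plus noise:
  # at K = 20, every meta-matching variant should out-correlate a KRR
  # trained on the same 20 participants, averaged over 20 repetitions
  cfg <- simulation_config(
    list(dataset_spec("xl", 1500, 4, "extra_large", missing_rate = 0),
         dataset_spec("lg", 300, 3, "large", missing_rate = 0),
         dataset_spec("md", 120, 2, "medium", missing_rate = 0)),
    dataset_spec("tg", 250, 2, "target", noise_sd_phenotypes = 0.5),
    p = 10, l = 3, cross_loading_strength = 1, seed = 777)
  coll <- simulate_collection(cfg)
  m <- train_multilayer(coll$sources, lambda_grid = fast_grid,
                        mlp_cfg = mlp_config(hidden = c(64, 32), max_epochs = 100,
                                             batch_size = 64, seed = 2),
                        seed = 21)
  apps <- standard_approaches(m, lambda_grid = fast_grid)
  apps$transfer <- NULL
  res <- run_kshot_experiment(apps, coll$target, ks = 20, n_repetitions = 20,
                              seed = 22)
  s <- summarize_kshot(res)
  r_krr <- s$mean_pearson[s$approach == "classical_krr"]
  for (a in c("stacking", "dataset_stacking", "multilayer")) {
    expect_gt(s$mean_pearson[s$approach == a], r_krr)
  }
})

test_that("an uninformative extra medium dataset barely moves multilayer accuracy", {
  coll <- tiny_collection()
  noise_src <- local({
    with_fixed_seed(60, {
      x <- matrix(rnorm(80 * 45), 80, 45)
      y <- matrix(rnorm(80 * 2), 80, 2)
    })
    colnames(y) <- c("nz_phen_01", "nz_phen_02")
    source_dataset("nz", x, y, size_class = "medium", seed = 61)
  })
  m_base <- tiny_multilayer()
  m_plus <- train_multilayer(c(coll$sources, list(noise_src)),
                             lambda_grid = fast_grid,
                             mlp_cfg = fast_mlp_cfg(), seed = 11)
  expect_identical(m_plus$total_feature_count, 22L)
  apps <- list(
    base = approach_meta_matching(m_base, "multilayer", lambda_grid = fast_grid),
    plus = approach_meta_matching(m_plus, "multilayer", lambda_grid = fast_grid))
  res <- run_kshot_experiment(apps, coll$target, ks = 40, n_repetitions = 10,
                              seed = 62)
  s <- summarize_kshot(res)
  expect_lt(abs(diff(s$mean_pearson)), 0.05)
})
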