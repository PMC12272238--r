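test_that("K-shot splits respect the protocol and the sampling distribution", {
  expect_error(make_kshot_splits(50, 50), "no evaluation participants")
  expect_error(make_kshot_splits(50, 30, target_mask = rep(c(TRUE, FALSE), 25)),
               "cannot draw")
  s1 <- make_kshot_splits(40, 10, n_repetitions = 5, seed = 3)
  s2 <- make_kshot_splits(40, 10, n_repetitions = 5, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, function(s)
    length(intersect(s$shot, s$eval)) == 0, logical(1))))
  expect_true(all(vapply(s1, function(s)
    length(union(s$shot, s$eval)) == 40, logical(1))))

  # shot-frequency over 100 repetitions at N = 1000, K = 100: selection
  # counts behave like Binomial(100, 0.1) — ~99% of participants inside the
  # binomial 99% band, and the empirical variance near 100 * 0.1 * 0.9
  sp <- make_kshot_splits(1000, 100, n_repetitions = 100, seed = 8)
  counts <- tabulate(unlist(lapply(sp, `[[`, "shot")), nbins = 1000)
  lo <- qbinom(0.005, 100, 0.1); hi <- qbinom(0.995, 100, 0.1)
  expect_lte(mean(counts < lo | counts > hi), 0.02)
  expect_equal(mean(counts), 10)
  expect_lt(abs(var(counts) - 9), 2)
})

test_that("metrics match hand computations and record undefined cases as missing", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_metric(y, y), 1)
  expect_equal(pearson_metric(y, -y), -1)
  with_fixed_seed(80, {
    a <- rnorm(30); b <- rnorm(30)
  })
  expect_equal(pearson_metric(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  expect_true(is.na(pearson_metric(y, rep(2, 5))))
  expect_true(is.na(pearson_metric(y[1:2], y[1:2])))

  # predictive COD against a 5-point hand computation
  yt <- c(2, 4, 6, 8, 10); yp <- c(3, 3, 7, 7, 11); bm <- 5
  expect_equal(cod_metric(yt, yp, bm),
               1 - (1 + 1 + 1 + 1 + 1) / (9 + 1 + 1 + 9 + 25))
  expect_equal(cod_metric(yt, yt, bm), 1)
  expect_equal(cod_metric(yt, rep(bm, 5), bm), 0)
  expect_true(is.na(cod_metric(rep(5, 3), c(1, 2, 3), 5)))
})

test_that("the experiment grid is reproducible, paired, and leak-free", {
  coll <- tiny_collection()
  mean_app <- function(x_all, y_shot, shot, eval_idx, seed) {
    rep(mean(y_shot), length(eval_idx))
  }
  spy_env <- new.env(); spy_env$shots <- list()
  spy_app <- function(x_all, y_shot, shot, eval_idx, seed) {
    spy_env$shots[[length(spy_env$shots) + 1]] <- shot
    rep(mean(y_shot), length(eval_idx))
  }
  apps <- list(mean_pred = mean_app, spy = spy_app)
  r1 <- run_kshot_experiment(apps, coll$target, ks = c(10, 20),
                             n_repetitions = 4, seed = 5)
  r2 <- run_kshot_experiment(apps, coll$target, ks = c(10, 20),
                             n_repetitions = 4, seed = 5)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))

  # the mean predictor scores COD exactly 0 and an undefined Pearson r
  expect_true(all(r1$cod == 0))
  expect_true(all(is.na(r1$pearson)))

  # paired design: both approaches saw identical shot sets
  logged <- attr(r1, "splits")
  expect_identical(length(logged), 4L)  # 2 phenotypes x 2 Ks

  # an approach that errors is recorded and the run continues
  bad <- list(ok = mean_app,
              boom = function(...) stop("deliberate failure"))
  rb <- run_kshot_experiment(bad, coll$target, ks = 10, n_repetitions = 2,
                             seed = 6)
  expect_true(all(is.na(rb$cod[rb$approach == "boom"])))
  expect_true(all(rb$cod[rb$approach == "ok"] == 0))
  expect_gt(length(attr(rb, "failures")), 0)

  # no leakage: perturbing evaluation-participant targets cannot change an
  # adapted model (it never sees them); metrics change only through y_true
  tgt2 <- coll$target
  sp <- make_kshot_splits(nrow(tgt2$features), 10, n_repetitions = 1, seed = 7)[[1]]
  y <- tgt2$phenotypes[, 1]
  m <- tiny_multilayer()
  a1 <- adapt_stacking(m, tgt2$features[sp$shot, ], y[sp$shot],
                       "multilayer", lambda_grid = fast_grid, seed = 8)
  y_pert <- y; y_pert[sp$eval] <- y_pert[sp$eval] + 100
  a2 <- adapt_stacking(m, tgt2$features[sp$shot, ], y_pert[sp$shot],
                       "multilayer", lambda_grid = fast_grid, seed = 8)
  expect_identical(a1$stacker$krr$alpha, a2$stacker$krr$alpha)
})

test_that("mean accuracy does not degrade with more adaptation participants", {
  coll <- tiny_collection()
  apps <- list(multilayer = approach_meta_matching(tiny_multilayer(),
                                                   "multilayer",
                                                   lambda_grid = fast_grid))
  res <- run_kshot_experiment(apps, coll$target, ks = c(10, 60),
                              n_repetitions = 10, seed = 31)
  s <- summarize_kshot(res)
  expect_gte(s$mean_pearson[s$k == 60], s$mean_pearson[s$k == 10] - 0.05)
})

test_that("paired bootstrap comparison behaves at its edges and under the null", {
  coll <- tiny_collection()
  apps <- list(a = function(x_all, y_shot, shot, eval_idx, seed)
                 x_all[eval_idx, 1],
               b = function(x_all, y_shot, shot, eval_idx, seed)
                 x_all[eval_idx, 1] * 0 + seq_along(eval_idx))
  res <- run_kshot_experiment(apps, coll$target, ks = 15, n_repetitions = 5,
                              seed = 9)
  # an approach against itself: maximal p-value
  bc_self <- bootstrap_compare(res, "a", "a", 15, "pearson", n_boot = 199,
                               seed = 1)
  expect_equal(bc_self$p_value, 1)

  # a large constant shift separates at the minimal attainable p
  res_shift <- res
  res_shift$cod[res_shift$approach == "a"] <-
    res_shift$cod[res_shift$approach == "b"] + 5
  bc_sep <- bootstrap_compare(res_shift, "a", "b", 15, "cod", n_boot = 199,
                              seed = 2)
  expect_equal(bc_sep$p_value, 2 / 200)

  expect_error(bootstrap_compare(res, "a", "nope", 15), "no results")
})

test_that("the bootstrap p-value is approximately uniform under the null", {
  # 200 simulated null comparisons (identical generating processes):
  # Kolmogorov-Smirnov distance to uniform < 0.15
  ps <- numeric(200)
  with_fixed_seed(90, {
    for (i in 1:200) {
      grid <- expand.grid(repetition = 1:10, phenotype = paste0("p", 1:8))
      df <- rbind(
        cbind(grid, approach = "a", k = 10, pearson = rnorm(80), cod = 0),
        cbind(grid, approach = "b", k = 10, pearson = rnorm(80), cod = 0))
      class(df) <- c("kshot_result", class(df))
      ps[i] <- bootstrap_compare(df, "a", "b", 10, "pearson", n_boot = 200,
                                 seed = i)$p_value
    }
  })
  ks_stat <- suppressWarnings(ks.test(ps, "punif"))$statistic
  expect_lt(as.numeric(ks_stat), 0.15)
})

test_that("BH-FDR matches an independently coded step-up procedure", {
  expect_identical(nrow(fdr_correct(numeric(0))), 0L)
  one <- fdr_correct(0.01)
  expect_equal(one$p_adjusted, 0.01)
  expect_true(one$rejected)
  all1 <- fdr_correct(rep(1, 7))
  expect_false(any(all1$rejected))

  with_fixed_seed(91, p <- runif(20)^2)
  got <- fdr_correct(p)
  # step-up oracle: sort ascending, q_i = min_{j >= i} p_(j) * m / j
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  oracle <- numeric(m); oracle[o] <- q
  expect_equal(got$p_adjusted, oracle, tolerance = 1e-12)
  expect_identical(got$rejected, oracle <= 0.05)
})
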