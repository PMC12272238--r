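# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; the "tiny" collection and hierarchy are deliberately
# small so the full suite stays fast.

rand_sym_matrix <- function(p, seed = 1) {
  with_fixed_seed(seed, {
    m <- matrix(stats::rnorm(p * p), p, p)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

fast_mlp_cfg <- function(seed = 1) {
  mlp_config(hidden = c(16, 8), max_epochs = 8, batch_size = 32,
             patience = 4, seed = seed)
}

fast_grid <- c(0.001, 0.1, 10, 1000)

# Small three-source collection (extra-large / large / medium) + target.
tiny_collection <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- simulation_config(
        list(dataset_spec("xl", 300, 4, "extra_large", missing_rate = 0.1),
             dataset_spec("lg", 150, 3, "large", feature_shift = 0.4,
                          missing_rate = 0.1),
             dataset_spec("md", 80, 2, "medium", missing_rate = 0.1)),
        dataset_spec("tg", 120, 2, "target", feature_shift = 0.4),
        p = 10, l = 3, cross_loading_strength = 0.8, seed = 404)
      val <<- simulate_collection(cfg)
    }
    val
  }
})

tiny_multilayer <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- train_multilayer(tiny_collection()$sources,
                               lambda_grid = fast_grid,
                               mlp_cfg = fast_mlp_cfg(), seed = 11)
    }
    val
  }
})

# Trained default-suite hierarchy, shared by the suite-level tests.
suite_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      coll <- default_suite(seed = 7)
      model <- train_multilayer(coll$sources, seed = 8)
      val <<- list(coll = coll, model = model)
    }
    val
  }
})
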