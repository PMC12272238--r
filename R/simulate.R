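# Latent-factor generator for multi-dataset connectome-phenotype collections.
# Shared latent factors drive both the FC features and the transferable part
# of every phenotype battery; dataset-unique latent factors add phenotype
# variance that no feature can explain, which is what caps attainable
# accuracy below 1 for cross_loading_strength < 1.

#' A source or target dataset of FC features and phenotypes
#'
#' @param name Dataset name.
#' @param features Numeric matrix, participants x edges (raw FC edge vectors
#'   in canonical order; see [edge_index()]).
#' @param phenotypes Numeric matrix, participants x phenotypes, `NA` =
#'   missing.
#' @param size_class One of `"extra_large"`, `"large"`, `"medium"`,
#'   `"target"`, or `NULL` to assign by sample-size thresholds
#'   (N >= 10000 extra_large, 2000 <= N < 10000 large, else medium).
#' @param split Optional factor/character of `"train"`/`"val"` per
#'   participant (80/20); drawn at random with `seed` if `NULL`.
#' @param seed Seed for the split draw.
#' @return Object of class `source_dataset`.
#' @export
source_dataset <- function(name, features, phenotypes, size_class = NULL,
                           split = NULL, seed = 1) {
  stopifnot(is.matrix(features), is.matrix(phenotypes),
            nrow(features) == nrow(phenotypes))
  n <- nrow(features)
  mask <- is.finite(phenotypes)
  if (any(rowSums(mask) == 0)) {
    stop("participant(s) with no observed phenotype: ",
         paste(utils::head(which(rowSums(mask) == 0), 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(colSums(mask) == 0)) {
    stop("phenotype(s) with no observed participant", call. = FALSE)
  }
  if (is.null(size_class)) {
    size_class <- if (n >= 10000) "extra_large" else if (n >= 2000) "large" else "medium"
  }
  size_class <- match.arg(size_class, c("extra_large", "large", "medium", "target"))
  if (is.null(split)) {
    ntr <- round(0.8 * n)
    split <- rep("val", n)
    split[with_local_seed(seed, sample(n, ntr))] <- "train"
  }
  if (is.null(rownames(features))) {
    rownames(features) <- sprintf("%s_%04d", name, seq_len(n))
  }
  rownames(phenotypes) <- rownames(features)
  if (is.null(colnames(phenotypes))) {
    colnames(phenotypes) <- sprintf("phen_%02d", seq_len(ncol(phenotypes)))
  }
  structure(list(name = name, features = features, phenotypes = phenotypes,
                 size_class = size_class, split = split),
            class = "source_dataset")
}

#' @export
print.source_dataset <- function(x, ...) {
  cat(sprintf("<source_dataset '%s'> %d participants, %d edges, %d phenotypes (%s; %.1f%% missing)\n",
              x$name, nrow(x$features), ncol(x$features), ncol(x$phenotypes),
              x$size_class, 100 * mean(!is.finite(x$phenotypes))))
  invisible(x)
}

#' Reconstruct one participant's symmetric FC matrix
#'
#' @param dataset A [source_dataset()].
#' @param participant Row index or participant id.
#' @return Symmetric P x P matrix with unit diagonal.
#' @export
fc_matrix <- function(dataset, participant) {
  if (is.character(participant)) {
    participant <- match(participant, rownames(dataset$features))
  }
  devectorize_edges(dataset$features[participant, ])
}

#' Specify one dataset of a simulated collection
#'
#' @param name Dataset name.
#' @param n Participants (>= 10).
#' @param t Phenotype count (>= 1).
#' @param size_class Size class, see [source_dataset()].
#' @param feature_shift Constant added to every raw FC edge value; emulates
#'   the distribution-center difference between preprocessing pipelines
#'   (zero-centered vs. non-centered FC). Per-participant normalization must
#'   erase its effect.
#' @param noise_sd_features Feature noise standard deviation.
#' @param noise_sd_phenotypes Phenotype noise standard deviation (signal
#'   variance is 1, so this sets the noise-to-signal ratio).
#' @param missing_rate Completely-at-random phenotype missingness in
#'   `[0, 0.9]`.
#' @return A list of class `dataset_spec`.
#' @export
dataset_spec <- function(name, n, t, size_class = NULL, feature_shift = 0,
                         noise_sd_features = 3, noise_sd_phenotypes = 1,
                         missing_rate = 0) {
  stopifnot(n >= 10, t >= 1, missing_rate >= 0, missing_rate <= 0.9,
            noise_sd_features >= 0, noise_sd_phenotypes >= 0)
  structure(list(name = name, n = as.integer(n), t = as.integer(t),
                 size_class = size_class, feature_shift = feature_shift,
                 noise_sd_features = noise_sd_features,
                 noise_sd_phenotypes = noise_sd_phenotypes,
                 missing_rate = missing_rate),
            class = "dataset_spec")
}

#' Configuration of a simulated multi-dataset collection
#'
#' @param sources List of [dataset_spec()] for the source datasets.
#' @param target A [dataset_spec()] for the target dataset.
#' @param p Parcel count (features = p(p-1)/2 edges).
#' @param l Shared latent factor count.
#' @param cross_loading_strength Weight `c` in `[0, 1]` on the shared
#'   canonical phenotype directions: each phenotype loads `c` on a shared
#'   direction of the common latent space and `sqrt(1 - c^2)` on
#'   dataset-unique latent factors invisible to the features. `c = 0` gives
#'   no transferable signal; `c = 1` with zero noise makes targets exactly
#'   feature-recoverable.
#' @param loading_tilt Blend in `[0, 1)` of dataset-unique feature loadings
#'   against the common core (default 0.3).
#' @param seed Integer seed; the whole collection is a deterministic
#'   function of the config.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(sources, target, p = 40, l = 6,
                              cross_loading_strength = 0.7,
                              loading_tilt = 0.3, seed = 1) {
  stopifnot(p >= 2, l >= 1,
            cross_loading_strength >= 0, cross_loading_strength <= 1,
            loading_tilt >= 0, loading_tilt < 1)
  if (inherits(sources, "dataset_spec")) sources <- list(sources)
  stopifnot(length(sources) >= 1,
            all(vapply(sources, inherits, TRUE, "dataset_spec")),
            inherits(target, "dataset_spec"))
  structure(list(sources = sources, target = target, p = as.integer(p),
                 l = as.integer(l),
                 cross_loading_strength = cross_loading_strength,
                 loading_tilt = loading_tilt, seed = as.integer(seed)),
            class = "simulation_config")
}

# Unit-norm random rows.
unit_rows <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

#' Simulate a multi-dataset connectome-phenotype collection
#'
#' Per participant, shared latent factors `z` (length `l`) generate the FC
#' edge vector `x = A_d z + feature_shift + noise`, where `A_d` blends a
#' common loading core (shared across datasets) with a dataset tilt.
#' Phenotype `t` of dataset `d` is
#' `y = c * (z . g_t) + sqrt(1 - c^2) * (u_d . b_t) + noise`, where `g_t` is
#' a canonical direction from a pool shared by all datasets (phenotype `t`
#' maps to pool entry `(t - 1) mod pool size + 1`, so batteries are latently
#' correlated across datasets) and `u_d` are dataset-unique latent factors
#' the features do not see. Missingness is completely at random; rows or
#' columns left fully missing are repaired by unmasking one entry.
#'
#' @param config A [simulation_config()].
#' @return List with `sources` (list of [source_dataset()]) and `target`.
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  e <- n_edges(config$p)
  l <- config$l
  cc <- config$cross_loading_strength
  tau <- config$loading_tilt
  specs <- c(config$sources, list(config$target))
  n_pool <- max(vapply(specs, function(s) s$t, integer(1)))
  with_local_seed(config$seed, {
    a_core <- matrix(stats::rnorm(e * l, sd = 1 / sqrt(l)), e, l)
    g_pool <- unit_rows(n_pool, l)
    out <- lapply(seq_along(specs), function(si) {
      s <- specs[[si]]
      a_d <- sqrt(1 - tau^2) * a_core +
        tau * matrix(stats::rnorm(e * l, sd = 1 / sqrt(l)), e, l)
      z <- matrix(stats::rnorm(s$n * l), s$n, l)
      x <- tcrossprod(z, a_d) + s$feature_shift +
        matrix(stats::rnorm(s$n * e, sd = s$noise_sd_features), s$n, e)
      u <- matrix(stats::rnorm(s$n * l), s$n, l)     # dataset-unique factors
      b_u <- unit_rows(s$t, l)                        # unique-direction loadings
      g_idx <- ((seq_len(s$t) - 1L) %% n_pool) + 1L
      y <- cc * tcrossprod(z, g_pool[g_idx, , drop = FALSE]) +
        sqrt(1 - cc^2) * tcrossprod(u, b_u) +
        matrix(stats::rnorm(s$n * s$t, sd = s$noise_sd_phenotypes), s$n, s$t)
      if (s$missing_rate > 0) {
        miss <- matrix(stats::runif(s$n * s$t) < s$missing_rate, s$n, s$t)
        # repair degenerate rows/columns so dataset invariants hold
        bad_r <- which(rowSums(!miss) == 0)
        for (r in bad_r) miss[r, sample(s$t, 1)] <- FALSE
        bad_c <- which(colSums(!miss) == 0)
        for (ci in bad_c) miss[sample(s$n, 1), ci] <- FALSE
        y[miss] <- NA_real_
      }
      colnames(y) <- sprintf("%s_phen_%02d", s$name, seq_len(s$t))
      source_dataset(s$name, x, y,
                     size_class = if (si == length(specs)) "target" else s$size_class,
                     seed = stats::runif(1, 1, 2^30))
    })
    list(sources = out[-length(out)], target = out[[length(out)]])
  })
}

#' The canonical simulated study: five sources and one target
#'
#' Five source datasets with strongly imbalanced sizes — one extra-large
#' (N = 4000, 20 phenotypes), one large (N = 1500, 12), three medium
#' (N = 300, 8 each) — and a target dataset (N = 600, 10 phenotypes), at
#' P = 40 parcels (780 edges), 6 shared latent factors,
#' `cross_loading_strength = 0.7`, feature noise sd 1, phenotype noise sd
#' 0.7, 10% source phenotype missingness, and alternating feature shifts
#' (0 / 0.4) emulating mixed preprocessing. Sized so the full evaluation
#' grid runs on one CPU in minutes.
#'
#' @param seed Integer seed.
#' @return As [simulate_collection()].
#' @export
default_suite <- function(seed = 1) {
  cfg <- default_suite_config(seed)
  simulate_collection(cfg)
}

#' @rdname default_suite
#' @export
default_suite_config <- function(seed = 1) {
  src <- list(
    dataset_spec("src_xl", 4000, 20, "extra_large", feature_shift = 0,   missing_rate = 0.1),
    dataset_spec("src_l",  1500, 12, "large",       feature_shift = 0.4, missing_rate = 0.1),
    dataset_spec("src_m1",  300,  8, "medium",      feature_shift = 0,   missing_rate = 0.1),
    dataset_spec("src_m2",  300,  8, "medium",      feature_shift = 0.4, missing_rate = 0.1),
    dataset_spec("src_m3",  300,  8, "medium",      feature_shift = 0,   missing_rate = 0.1)
  )
  tgt <- dataset_spec("target", 600, 10, "target", feature_shift = 0.4,
                      missing_rate = 0)
  simulation_config(src, tgt, p = 40, l = 6, cross_loading_strength = 0.7,
                    seed = seed)
}
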