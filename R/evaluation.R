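# K-shot evaluation protocol: repeated random draws of K adaptation
# participants, paired across approaches, with Pearson r and predictive COD
# on the remaining N - K participants, plus paired bootstrap comparisons and
# BH-FDR over the pooled family of tests.

#' Draw the K-shot / evaluation splits for one phenotype
#'
#' Each repetition samples K participants with the target observed (the
#' "shot" set used to adapt models); the remaining N - K participants form
#' the evaluation set. Deterministic given the seed.
#'
#' @param n Total participants.
#' @param k Shot count.
#' @param target_mask Logical length-n vector, `TRUE` where the target is
#'   observed (default all).
#' @param n_repetitions Number of repetitions (default 100).
#' @param seed Integer seed.
#' @return List of length `n_repetitions`; each element has `k`, `shot`,
#'   `eval`, `repetition`.
#' @export
make_kshot_splits <- function(n, k, target_mask = rep(TRUE, n),
                              n_repetitions = 100, seed = 1) {
  stopifnot(length(target_mask) == n)
  eligible <- which(target_mask)
  if (length(eligible) < k) {
    stop("only ", length(eligible), " participants have the target observed; ",
         "cannot draw K = ", k, call. = FALSE)
  }
  if (k >= n) {
    stop("K = ", k, " leaves no evaluation participants (N = ", n, ")",
         call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_repetitions)
  lapply(seq_len(n_repetitions), function(r) {
    shot <- sort(with_local_seed(seeds[r], sample(eligible, k)))
    list(k = k, shot = shot, eval = setdiff(seq_len(n), shot), repetition = r)
  })
}

#' Pearson correlation metric
#'
#' Standard Pearson r over the jointly observed entries. Undefined cases
#' (fewer than 3 pairs, or a constant vector) are recorded as `NA`, never
#' silently zero.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return Pearson r, or `NA_real_` if undefined.
#' @export
pearson_metric <- function(y_true, y_pred) {
  ok <- is.finite(y_true) & is.finite(y_pred)
  if (sum(ok) < 3) return(NA_real_)
  yt <- y_true[ok]; yp <- y_pred[ok]
  if (stats::sd(yt) < 1e-300 || stats::sd(yp) < 1e-300) return(NA_real_)
  stats::cor(yt, yp)
}

#' Predictive coefficient of determination (COD)
#'
#' `1 - sum((y - yhat)^2) / sum((y - baseline)^2)` where the baseline is the
#' mean of the target over the K adaptation participants — so a model that
#' predicts that mean scores ~0 and worse models go negative. Undefined
#' (zero denominator) cases are `NA`.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @param baseline_mean Mean of the target over the adaptation sample.
#' @return COD (<= 1, possibly negative), or `NA_real_`.
#' @export
cod_metric <- function(y_true, y_pred, baseline_mean) {
  ok <- is.finite(y_true) & is.finite(y_pred)
  if (!any(ok)) return(NA_real_)
  den <- sum((y_true[ok] - baseline_mean)^2)
  if (den < 1e-300) return(NA_real_)
  1 - sum((y_true[ok] - y_pred[ok])^2) / den
}

#' Run the K-shot experiment over approaches, K values and repetitions
#'
#' All approaches see identical shot/evaluation splits per repetition (a
#' paired design). An approach is a function
#' `f(x_all, y_shot_values, shot, eval_idx, seed)` returning predictions for
#' `eval_idx`; it receives target values only for the shot participants, so
#' evaluation targets cannot leak into training. Failures of one approach on
#' one repetition are recorded as missing metrics and the run continues.
#'
#' @param approaches Named list of approach functions (see
#'   [approach_classical_krr()] and friends).
#' @param target A [source_dataset()]: the target dataset.
#' @param ks Integer vector of K values.
#' @param n_repetitions Repetitions per K (default 100).
#' @param seed Integer seed; splits are a deterministic function of
#'   (seed, K, phenotype).
#' @param phenotypes Phenotype columns to evaluate (default all).
#' @return A tibble of class `kshot_result` with columns `approach`, `k`,
#'   `repetition`, `phenotype`, `pearson`, `cod`, and attributes `splits`
#'   (the shot indices) and `failures`.
#' @export
run_kshot_experiment <- function(approaches, target, ks = c(10, 20, 50, 100),
                                 n_repetitions = 100, seed = 1,
                                 phenotypes = colnames(target$phenotypes)) {
  stopifnot(inherits(target, "source_dataset"), length(approaches) >= 1,
            !is.null(names(approaches)))
  x_all <- target$features
  n <- nrow(x_all)
  rows <- list(); splits_log <- list(); failures <- list()
  for (ph in phenotypes) {
    y_all <- target$phenotypes[, ph]
    mask <- is.finite(y_all)
    for (k in ks) {
      sp_seed <- derive_seeds(seed, 2L)[1] + 131L * k + 7L * match(ph, phenotypes)
      splits <- make_kshot_splits(n, k, mask, n_repetitions, seed = sp_seed)
      splits_log[[paste(ph, k, sep = "@")]] <- lapply(splits, `[[`, "shot")
      for (sp in splits) {
        ev_obs <- sp$eval[mask[sp$eval]]
        y_shot <- y_all[sp$shot]
        base_mean <- mean(y_shot)
        ap_seed <- sp_seed + 977L * sp$repetition
        for (an in names(approaches)) {
          pred <- tryCatch(
            approaches[[an]](x_all, y_shot, sp$shot, sp$eval, ap_seed),
            error = function(e) e)
          if (inherits(pred, "error")) {
            failures[[length(failures) + 1]] <- list(
              approach = an, k = k, repetition = sp$repetition,
              phenotype = ph, message = conditionMessage(pred))
            r_val <- NA_real_; cod_val <- NA_real_
          } else {
            pe <- pred[match(ev_obs, sp$eval)]
            r_val <- pearson_metric(y_all[ev_obs], pe)
            cod_val <- cod_metric(y_all[ev_obs], pe, base_mean)
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            approach = an, k = k, repetition = sp$repetition, phenotype = ph,
            pearson = r_val, cod = cod_val)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "splits") <- splits_log
  attr(out, "failures") <- failures
  class(out) <- c("kshot_result", class(out))
  out
}

#' Summarize a K-shot result: mean over repetitions, then phenotypes
#'
#' @param result A [run_kshot_experiment()] result.
#' @return Tibble with one row per approach x K: `mean_pearson`, `mean_cod`
#'   (per-phenotype means over repetitions, averaged across phenotypes,
#'   missing metrics excluded), and missing-metric counts.
#' @export
summarize_kshot <- function(result) {
  result |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$approach, .data$k, .data$phenotype) |>
    dplyr::summarize(
      pearson = mean(.data$pearson, na.rm = TRUE),
      cod = mean(.data$cod, na.rm = TRUE),
      n_missing = sum(is.na(.data$pearson)) + sum(is.na(.data$cod)),
      .groups = "drop") |>
    dplyr::group_by(.data$approach, .data$k) |>
    dplyr::summarize(
      mean_pearson = mean(.data$pearson, na.rm = TRUE),
      mean_cod = mean(.data$cod, na.rm = TRUE),
      n_missing = sum(.data$n_missing),
      .groups = "drop")
}

#' Paired bootstrap comparison of two approaches
#'
#' For a fixed K and metric, forms the per-(phenotype, repetition) paired
#' metric differences (a - b), then bootstrap-resamples phenotypes with
#' replacement and, within each sampled phenotype, repetitions with
#' replacement; the two-sided p-value is
#' `2 * min(P(mean <= 0), P(mean >= 0))` with a +1 continuity floor, capped
#' at 1.
#'
#' @param result A [run_kshot_experiment()] result.
#' @param approach_a,approach_b Approach names.
#' @param k K value to compare at.
#' @param metric `"pearson"` or `"cod"`.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @return List with `p_value`, `mean_difference`, `ci95` (percentile).
#' @export
bootstrap_compare <- function(result, approach_a, approach_b, k,
                              metric = c("pearson", "cod"), n_boot = 1000,
                              seed = 1) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(result)
  a <- df[df$approach == approach_a & df$k == k, c("repetition", "phenotype", metric)]
  b <- df[df$approach == approach_b & df$k == k, c("repetition", "phenotype", metric)]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("no results for the requested approaches at K = ", k, call. = FALSE)
  }
  m <- merge(a, b, by = c("repetition", "phenotype"), suffixes = c("_a", "_b"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    stop("unpaired result grids: approaches were not run on identical splits",
         call. = FALSE)
  }
  m$d <- m[[paste0(metric, "_a")]] - m[[paste0(metric, "_b")]]
  m <- m[is.finite(m$d), ]
  phens <- unique(m$phenotype)
  by_ph <- split(m$d, m$phenotype)
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ph_draw <- sample(phens, length(phens), replace = TRUE)
      mean(unlist(lapply(ph_draw, function(p) {
        v <- by_ph[[p]]
        v[sample.int(length(v), length(v), replace = TRUE)]
      })))
    }, numeric(1))
  })
  p <- 2 * min((1 + sum(boots <= 0)) / (n_boot + 1),
               (1 + sum(boots >= 0)) / (n_boot + 1))
  list(p_value = min(p, 1), mean_difference = mean(m$d),
       ci95 = stats::quantile(boots, c(0.025, 0.975), names = FALSE))
}

#' Benjamini-Hochberg FDR correction over a pooled family of p-values
#'
#' Applied once to the pooled family (all K values, all approach pairs, both
#' metrics), as the evaluation protocol pools it.
#'
#' @param p_values Numeric vector of p-values (possibly named).
#' @param q FDR level (default 0.05).
#' @return Tibble with `p`, `p_adjusted` (BH step-up), `rejected`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(tibble::tibble(comparison = character(0), p = numeric(0),
                          p_adjusted = numeric(0), rejected = logical(0)))
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(
    comparison = if (is.null(names(p_values))) as.character(seq_along(p_values)) else names(p_values),
    p = unname(p_values), p_adjusted = unname(adj), rejected = unname(adj <= q))
}
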