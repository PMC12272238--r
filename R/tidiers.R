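# broom-style tidiers and ggplot2 autoplot methods for the fitted objects
# and the K-shot result container.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy lrr_model
#' @export
tidy.lrr_model <- function(x, ...) {
  nm <- x$feature_names
  if (is.null(nm)) nm <- sprintf("edge_%05d", seq_along(x$weights))
  tibble::tibble(term = c("(Intercept)", nm),
                 estimate = c(x$intercept, x$weights))
}

#' @method glance lrr_model
#' @export
glance.lrr_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_train = x$n_train,
                 n_features = length(x$weights))
}

#' @method tidy krr_model
#' @export
tidy.krr_model <- function(x, ...) {
  tibble::tibble(participant = seq_along(x$alpha), alpha = x$alpha)
}

#' @method glance krr_model
#' @export
glance.krr_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_train = x$n_train,
                 y_mean = x$y_mean, dual_residual = x$dual_residual)
}

#' @method tidy mlp_model
#' @export
tidy.mlp_model <- function(x, ...) {
  s <- x$sizes
  tibble::tibble(layer = seq_len(length(s) - 1), d_in = s[-length(s)],
                 d_out = s[-1],
                 n_parameters = s[-length(s)] * s[-1] + s[-1])
}

#' @method glance mlp_model
#' @export
glance.mlp_model <- function(x, ...) {
  tibble::tibble(n_layers = length(x$layers), n_outputs = utils::tail(x$sizes, 1),
                 best_epoch = x$best_epoch,
                 val_loss = min(c(x$val_history, Inf)))
}

#' @method tidy multilayer_model
#' @export
tidy.multilayer_model <- function(x, ...) {
  dplyr::bind_rows(lapply(x$bundles, function(b) {
    tibble::tibble(dataset = b$dataset_name, size_class = b$size_class,
                   n_phenotypes = length(b$phenotype_names),
                   families = paste(b$families, collapse = "+"),
                   n_stackers = if (b$dataset_name %in% names(x$stackers))
                     length(x$stackers[[b$dataset_name]]) else 0L)
  }))
}

#' @method glance multilayer_model
#' @export
glance.multilayer_model <- function(x, ...) {
  tibble::tibble(n_bundles = length(x$bundles),
                 multilayer_features = x$total_feature_count,
                 dataset_stacking_features = x$dataset_stacking_count)
}

#' @method tidy stacking_model
#' @export
tidy.stacking_model <- function(x, ...) {
  tibble::tibble(feature = x$input_labels, center = x$col_center,
                 scale = x$col_scale)
}

#' @method glance stacking_model
#' @export
glance.stacking_model <- function(x, ...) {
  tibble::tibble(target = x$target_name, n_features = length(x$input_labels),
                 lambda = x$krr$lambda, n_train = x$krr$n_train)
}

#' @method tidy kshot_result
#' @export
tidy.kshot_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance kshot_result
#' @export
glance.kshot_result <- function(x, ...) {
  summarize_kshot(x)
}

#' Boxplots of K-shot prediction performance
#'
#' Distribution over repetitions of the phenotype-averaged metric, per
#' approach and K — the standard presentation of the K-shot protocol.
#'
#' @param object A [run_kshot_experiment()] result.
#' @param metric `"pearson"` or `"cod"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kshot_result
#' @export
autoplot.kshot_result <- function(object, metric = c("pearson", "cod"), ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$approach, .data$k, .data$repetition) |>
    dplyr::summarize(value = mean(.data[[metric]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k), y = .data$value,
                                   fill = .data$approach)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "K (adaptation participants)",
                  y = if (metric == "pearson") "Pearson r" else "predictive COD",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of an importance map as a symmetric parcel matrix
#'
#' @param map An [haufe_importance()] map.
#' @return A ggplot object.
#' @export
plot_importance <- function(map) {
  tab <- importance_table(map)
  tab2 <- tab[, c("edge_j", "edge_i", "value")]
  names(tab2) <- c("edge_i", "edge_j", "value")
  df <- dplyr::bind_rows(tab, tab2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$edge_i, y = .data$edge_j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "parcel", y = "parcel",
                  fill = "importance") +
    ggplot2::theme_minimal()
}
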