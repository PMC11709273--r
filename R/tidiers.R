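# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained learner's loss trace
#'
#' @param x An `omix_learner`.
#' @param ... Unused.
#' @return A long tibble: `epoch`, `component`, `loss`.
#' @method tidy omix_learner
#' @export
tidy.omix_learner <- function(x, ...) {
  stopifnot(!is.null(x$trace))
  tidyr::pivot_longer(x$trace, -"epoch", names_to = "component",
                      values_to = "loss")
}

#' One-row summary of a trained learner
#'
#' @param x An `omix_learner`.
#' @param ... Unused.
#' @return A tibble with architecture sizes, parameter count and final
#'   losses.
#' @method glance omix_learner
#' @export
glance.omix_learner <- function(x, ...) {
  n_par <- sum(vapply(flatten_params(x$params),
                      function(p) length(p$value), numeric(1)))
  last <- if (is.null(x$trace)) NULL else
    x$trace[nrow(x$trace), , drop = FALSE]
  tibble::tibble(
    n_omics = length(x$input_dims),
    n_features = sum(x$input_dims),
    n_classes = length(x$classes),
    d_h = x$config$d_h,
    rank = x$config$rank,
    n_parameters = n_par,
    epochs = if (is.null(last)) 0L else last$epoch,
    final_loss = if (is.null(last)) NA_real_ else last$loss,
    final_diagnosis_loss = if (is.null(last)) NA_real_ else last$diagnosis
  )
}

#' Loss-trace plot of a trained learner
#'
#' @param object An `omix_learner`.
#' @param ... Unused.
#' @return A ggplot of the per-epoch loss components.
#' @method autoplot omix_learner
#' @export
autoplot.omix_learner <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$loss,
                                 colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Top-feature importance plot
#'
#' @param object An `omix_importance` table.
#' @param n Features per omics to display.
#' @param ... Unused.
#' @return A ggplot of mean loss increases, faceted by omics.
#' @method autoplot omix_importance
#' @export
autoplot.omix_importance <- function(object, n = 10, ...) {
  top_features(object, n = n) |>
    dplyr::mutate(feature_id = stats::reorder(.data$feature_id,
                                              .data$mean_importance)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$mean_importance,
                                 y = .data$feature_id)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~omics, scales = "free_y") +
    ggplot2::labs(x = "mean diagnosis-loss increase", y = NULL) +
    ggplot2::theme_minimal()
}

#' Risk-score distribution plot
#'
#' @param object An `omix_ics` table.
#' @param ... Unused.
#' @return A ggplot histogram of the integrated score.
#' @method autoplot omix_ics
#' @export
autoplot.omix_ics <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ics)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "integrated subtype score", y = "patients") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
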