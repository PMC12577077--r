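#' Tidy a fitted variance-component model
#'
#' One row per free parameter: block, trait-column indices, estimate and
#' AI-based standard error.
#'
#' @param x an `mcg_reml` fit.
#' @param ... unused.
#' @return tibble with columns `param`, `block`, `i`, `j`, `type`,
#'   `estimate`, `se`.
#' @export
tidy.mcg_reml <- function(x, ...) {
  tibble::as_tibble(x$estimates)
}

#' One-line summary of a fitted variance-component model
#'
#' @param x an `mcg_reml` fit.
#' @param ... unused.
#' @return tibble with `method`, `traces`, `rounds`, `converged`, `reason`,
#'   final `minus2_logl`, `delta_theta`, `cv_logl`, `n_parameters`.
#' @export
glance.mcg_reml <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  tibble::tibble(
    method = x$method, traces = x$traces, rounds = x$rounds,
    converged = x$converged, reason = x$reason,
    minus2_logl = last$minus2_logl, delta_theta = last$delta_theta,
    cv_logl = last$cv_logl, n_parameters = nrow(x$index))
}

#' Plot the REML iteration trajectory
#'
#' Two panels: the restricted `-2 logL` per round, and the round-to-round
#' relative parameter change on a log scale (with the `t1` threshold drawn).
#'
#' @param object an `mcg_reml` fit.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mcg_reml <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[, c("round", "minus2_logl", "delta_theta")],
    cols = -"round", names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$round, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "REML round", y = NULL,
                  title = sprintf("%s-REML (%s traces)",
                                  toupper(object$method), object$traces)) +
    ggplot2::theme_minimal()
}

#' Plot parameter estimates with standard errors
#'
#' Point estimates with +/- 2 SE error bars, optionally against true values.
#'
#' @param fit an `mcg_reml` fit.
#' @param truth optional named numeric vector of true parameter values
#'   (names matching `param`).
#' @return a ggplot object.
#' @export
plot_estimates <- function(fit, truth = NULL) {
  d <- tidy(fit)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$param, y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - 2 * .data$se,
                                        ymax = .data$estimate + 2 * .data$se),
                           width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "estimate (+/- 2 SE)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    td <- tibble::tibble(param = names(truth), truth = as.numeric(truth))
    p <- p + ggplot2::geom_point(data = dplyr::inner_join(d, td, by = "param"),
                                 ggplot2::aes(y = .data$truth),
                                 colour = "red", shape = 4, size = 2)
  }
  p
}
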