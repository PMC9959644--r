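#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a moisture-ratio fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term` (`r0`..`rn`) and
#'   `estimate`.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  tibble::tibble(term = names(x$model$gamma),
                 estimate = unname(x$model$gamma))
}

#' One-row summary of a moisture-ratio fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A tibble with the algorithm, order, training metrics, final
#'   best fitness and run dimensions.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    order = x$order,
    r2 = x$metrics$r2,
    adj_r2 = x$metrics$adj_r2,
    rmse = x$metrics$rmse,
    mlf = x$trajectory$best_mlf[nrow(x$trajectory)],
    kmax = nrow(x$data),
    pop_size = x$control$pop_size,
    generations = x$control$generations
  )
}

#' Augment drying data with fitted values and residuals
#'
#' @param x An `mr_fit`.
#' @param data Data to augment; defaults to the training data.
#' @param ... Unused.
#' @return `data` plus `.fitted` and `.resid` columns.
#' @method augment mr_fit
#' @export
augment.mr_fit <- function(x, data = x$data, ...) {
  data <- validate_drying_data(data)
  data$.fitted <- predict(x$model, data)
  data$.resid <- data$moisture_ratio - data$.fitted
  data
}

#' Plot a fitted moisture-ratio curve over the data
#'
#' Observed moisture ratios against shrinkage, with the fitted polynomial
#' evaluated on a fine shrinkage grid.
#'
#' @param object An `mr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    shrinkage = seq(min(d$shrinkage), max(d$shrinkage), length.out = 200)
  )
  grid$moisture_ratio <- predict(object$model, grid)
  ggplot2::ggplot(d, ggplot2::aes(.data$shrinkage, .data$moisture_ratio)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(
      x = "shrinkage S", y = "moisture ratio MR",
      title = sprintf("%s fit, order %d", object$algorithm, object$order)
    )
}

#' Plot the best-fitness trajectory of a fit
#'
#' Best maximum-likelihood fitness after each generation, on a log scale;
#' greedy selection makes it non-increasing.
#'
#' @param fit An `mr_fit`.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(fit) {
  ggplot2::ggplot(fit$trajectory,
                  ggplot2::aes(.data$generation, .data$best_mlf)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best MLF",
                  title = sprintf("%s convergence", fit$algorithm))
}

#' Plot the scaling-factor and crossover-rate schedules of a fit
#'
#' For the improved estimator this shows the exponential decay of F and
#' the held sinusoidal oscillation of CR; for the classic estimator both
#' are flat lines.
#'
#' @param fit An `mr_fit`.
#' @return A ggplot object, faceted by schedule.
#' @export
plot_schedules <- function(fit) {
  tr <- fit$trajectory
  long <- tibble::tibble(
    generation = rep(tr$generation, 2),
    schedule = rep(c("scaling factor F", "crossover rate CR"),
                   each = nrow(tr)),
    value = c(tr$scaling_factor, tr$crossover_rate)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~schedule, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL)
}
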