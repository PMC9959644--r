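#' Coefficient of determination
#'
#' `R2 = 1 - RSS/TSS`, with the total sum of squares taken about the mean
#' of the observed series.
#'
#' @param predicted Predicted moisture-ratio series.
#' @param observed Observed moisture-ratio series, same length (>= 2), not
#'   all identical.
#' @return R-squared (at most 1; can be negative for fits worse than the
#'   mean).
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2) {
    stop("predicted and observed must have equal length >= 2", call. = FALSE)
  }
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) {
    stop("degenerate data: observed series has zero variance", call. = FALSE)
  }
  1 - sum((predicted - observed)^2) / tss
}

#' Adjusted coefficient of determination
#'
#' `adjR2 = 1 - (1 - R2) * (kmax - 1) / (kmax - (n + 1))`: penalises the
#' fit for the `n + 1` estimated coefficients so that models of different
#' order are comparable.
#'
#' @param r2 Plain R-squared.
#' @param kmax Number of observations (must exceed `n + 1`).
#' @param order Model order n.
#' @return Adjusted R-squared (never above `r2` when `r2 <= 1`).
#' @export
adjusted_r_squared <- function(r2, kmax, order) {
  if (kmax <= order + 1) {
    stop("kmax must exceed order + 1 for the adjusted R-squared",
         call. = FALSE)
  }
  1 - (1 - r2) * (kmax - 1) / (kmax - (order + 1))
}

#' Root-mean-square error
#'
#' For predictions produced by a polynomial model on its own dataset this
#' equals the square root of the maximum-likelihood fitness.
#'
#' @inheritParams r_squared
#' @return Non-negative RMSE.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 1) {
    stop("predicted and observed must have equal positive length",
         call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

fit_metric_row <- function(model, data) {
  pred <- predict(model, data)
  obs <- data$moisture_ratio
  r2 <- tryCatch(r_squared(pred, obs), error = function(e) NA_real_)
  adj <- if (is.na(r2) || nrow(data) <= model$order + 1) NA_real_ else {
    adjusted_r_squared(r2, nrow(data), model$order)
  }
  tibble::tibble(r2 = r2, adj_r2 = adj, rmse = rmse(pred, obs))
}

#' Select the polynomial order by adjusted R-squared
#'
#' Fits every candidate order with the chosen estimator and returns the
#' per-order metric table together with the order whose adjusted R-squared
#' is largest; ties go to the smaller order (parsimony).
#'
#' @param data Drying-data tibble.
#' @param orders Integer vector of candidate orders (each needs
#'   `kmax > order + 1`).
#' @param algorithm `"mlp-i-ie"` (improved, default), `"mlp-ie"`, or
#'   `"ols"` for the closed-form reference fit.
#' @param control A [de_control()] shared by all fits (ignored for
#'   `"ols"`).
#' @return A tibble with one row per order (columns `order`, coefficient
#'   list-column `gamma`, `r2`, `adj_r2`, `rmse`, `best`), attribute
#'   `best_order`.
#' @export
#' @examples
#' d <- simulate_drying(kmax = 40, sigma = 0, seed = 1)
#' sel <- select_order(d, orders = 1:3, algorithm = "ols")
#' attr(sel, "best_order")
select_order <- function(data, orders = 1:3,
                         algorithm = c("mlp-i-ie", "mlp-ie", "ols"),
                         control = de_control()) {
  algorithm <- match.arg(algorithm)
  data <- validate_drying_data(data)
  if (length(orders) == 0) stop("orders must be non-empty", call. = FALSE)
  rows <- purrr::map(orders, function(n) {
    model <- if (algorithm == "ols") {
      ols_fit(data, n)
    } else {
      fit_moisture_model(data, order = n, algorithm = algorithm,
                         control = control)$model
    }
    dplyr::bind_cols(
      tibble::tibble(order = as.integer(n), gamma = list(model$gamma)),
      fit_metric_row(model, data)
    )
  })
  out <- dplyr::bind_rows(rows)
  # largest adjusted R2 wins; ties resolved toward the smaller order
  ord <- order(-out$adj_r2, out$order)
  best <- out$order[ord[1]]
  out$best <- out$order == best
  attr(out, "best_order") <- best
  out
}

#' Score a fitted model on validation data
#'
#' Applies a fixed coefficient vector to a second drying dataset without
#' re-estimating anything, and computes R-squared, adjusted R-squared and
#' RMSE using the validation set's own mean and sample count. The order in
#' the adjusted R-squared penalty is the fitted model's order.
#'
#' @param model An `mr_model` or `mr_fit`.
#' @param data Validation drying-data tibble.
#' @return One-row tibble with `order`, `kmax`, `r2`, `adj_r2`, `rmse`.
#' @export
validate_model <- function(model, data) {
  if (inherits(model, "mr_fit")) model <- model$model
  if (!inherits(model, "mr_model")) {
    stop("model must be an mr_model or mr_fit", call. = FALSE)
  }
  data <- validate_drying_data(data)
  dplyr::bind_cols(
    tibble::tibble(order = model$order, kmax = nrow(data)),
    fit_metric_row(model, data)
  )
}
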