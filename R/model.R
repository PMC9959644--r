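#' Polynomial moisture-ratio model
#'
#' The model is MR = r0 + r1*S + ... + rn*S^n + w, an n-order polynomial in
#' the shrinkage S with additive white Gaussian noise w. The coefficient
#' vector gamma = (r0, ..., rn) has Q = n + 1 entries.
#'
#' @param gamma Numeric coefficient vector, constant term first.
#' @param order Polynomial order n; defaults to `length(gamma) - 1` and must
#'   agree with it when given.
#' @return An object of class `mr_model` with elements `order` and `gamma`
#'   (names `r0`..`rn`).
#' @export
#' @examples
#' m <- polynomial_model(c(-4.0180, 12.5609, -11.1670, 3.5632))
#' predict(m, newdata = 1)
polynomial_model <- function(gamma, order = length(gamma) - 1) {
  gamma <- as.numeric(gamma)
  if (length(gamma) < 1 || any(!is.finite(gamma))) {
    stop("gamma must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (order != length(gamma) - 1) {
    stop("order must equal length(gamma) - 1", call. = FALSE)
  }
  names(gamma) <- paste0("r", seq_along(gamma) - 1)
  structure(list(order = order, gamma = gamma), class = "mr_model")
}

#' @export
print.mr_model <- function(x, ...) {
  cat("Polynomial moisture-ratio model, order", x$order, "\n")
  print(signif(x$gamma, 6))
  invisible(x)
}

#' Information vector of powers of shrinkage
#'
#' tau(S) = (1, S, S^2, ..., S^n): the regressor vector the polynomial model
#' dots with its coefficients.
#'
#' @param s A single shrinkage value (any finite real).
#' @param order Polynomial order n >= 0.
#' @return Numeric vector of length n + 1; element q is `s^(q-1)`.
#' @export
#' @examples
#' information_vector(0.5, 3)
information_vector <- function(s, order) {
  if (length(order) != 1 || is.na(order) || order < 0 ||
      order != as.integer(order)) {
    stop("order must be a non-negative integer", call. = FALSE)
  }
  if (length(s) != 1 || !is.finite(s)) {
    stop("s must be a single finite value", call. = FALSE)
  }
  s^(0:order)
}

# Stacked information vectors: kmax x Q Vandermonde design matrix.
design_matrix <- function(s, order) {
  outer(as.numeric(s), 0:order, `^`)
}

#' Predict moisture ratio from shrinkage
#'
#' Evaluates the noise-free part of the model, tau(S)' gamma, at the given
#' shrinkage values.
#'
#' @param object An `mr_model`.
#' @param newdata Numeric vector of shrinkage values, or a data frame with a
#'   `shrinkage` column.
#' @param ... Unused.
#' @return Numeric vector of predicted moisture ratios.
#' @export
predict.mr_model <- function(object, newdata, ...) {
  s <- if (is.data.frame(newdata)) newdata$shrinkage else as.numeric(newdata)
  if (is.null(s)) stop("newdata must supply shrinkage values", call. = FALSE)
  drop(design_matrix(s, object$order) %*% object$gamma)
}

as_gamma <- function(gamma) {
  if (inherits(gamma, "mr_model")) gamma$gamma else as.numeric(gamma)
}

#' Maximum-likelihood fitness (mean squared residual)
#'
#' lambda(gamma) = (1/kmax) * sum_k [MR(k) - tau(k)' gamma]^2. Under the
#' Gaussian noise model, minimising this fitness maximises the profiled
#' likelihood, so it is the objective both evolutionary estimators descend.
#' It equals RMSE squared.
#'
#' @param gamma Coefficient vector (or an `mr_model`).
#' @param data A drying-data tibble.
#' @return Non-negative scalar fitness.
#' @export
#' @examples
#' d <- drying_data(c(1, 0.5), c(1, 0))
#' mlf(c(-1, 2), d) # exact interpolation: 0
mlf <- function(gamma, data) {
  gamma <- as_gamma(gamma)
  data <- validate_drying_data(data)
  X <- design_matrix(data$shrinkage, length(gamma) - 1)
  mean((data$moisture_ratio - drop(X %*% gamma))^2)
}

#' Maximum-likelihood estimate of the noise variance
#'
#' Treats the residuals of `gamma` as realisations of the additive white
#' Gaussian noise and returns their mean square, the value of sigma^2 that
#' zeroes the derivative of the log-likelihood.
#'
#' @inheritParams mlf
#' @return A list with element `sigma2` (equal to [mlf()]).
#' @export
noise_variance_mle <- function(gamma, data) {
  list(sigma2 = mlf(gamma, data))
}

#' Profiled Gaussian log-likelihood
#'
#' With the noise variance profiled out at its ML estimate, the
#' log-likelihood of a coefficient vector reduces to
#' `-(kmax/2) * (log(2*pi) + 1) - (kmax/2) * log(lambda)`, a strictly
#' decreasing function of the fitness lambda. The additive constant is fixed
#' so the function is fully defined; only differences matter for estimation.
#'
#' @inheritParams mlf
#' @return The profiled log-likelihood; `Inf` when the fit is exact
#'   (lambda = 0), flagged rather than thrown.
#' @export
log_likelihood_profile <- function(gamma, data) {
  lambda <- mlf(gamma, data)
  kmax <- nrow(data)
  const <- -(kmax / 2) * (log(2 * pi) + 1)
  if (lambda == 0) return(Inf)
  const - (kmax / 2) * log(lambda)
}

#' Exact least-squares fit (closed-form oracle)
#'
#' The fitness is a convex quadratic in gamma, so its global minimiser is
#' the least-squares solution of the Vandermonde system. This closed-form
#' fit is the independent reference the evolutionary estimators are checked
#' against; they never call it.
#'
#' @param data A drying-data tibble.
#' @param order Polynomial order n; needs `kmax >= n + 1` and a full-rank
#'   design (e.g. at least n + 1 distinct shrinkage values).
#' @return An `mr_model` with the minimising coefficients.
#' @export
ols_fit <- function(data, order) {
  data <- validate_drying_data(data)
  Q <- order + 1
  if (nrow(data) < Q) {
    stop("need at least order + 1 records to fit order ", order,
         call. = FALSE)
  }
  X <- design_matrix(data$shrinkage, order)
  qr_x <- qr(X)
  if (qr_x$rank < Q) {
    stop("singular design: shrinkage values do not support order ", order,
         call. = FALSE)
  }
  gamma <- qr.coef(qr_x, data$moisture_ratio)
  polynomial_model(unname(gamma))
}
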