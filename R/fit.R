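#' Fit the moisture-ratio polynomial by evolutionary maximum likelihood
#'
#' Runs one of the two differential-evolution estimators on a drying
#' dataset. Both minimise the maximum-likelihood fitness (mean squared
#' residual of moisture ratio on powers of shrinkage) with binomial
#' crossover and greedy survivor selection over exactly
#' `control$generations` sweeps:
#'
#' * `"mlp-ie"` — classic rand/1 mutation with fixed scaling factor and
#'   crossover rate;
#' * `"mlp-i-ie"` — improved variant: the three mutation partners are
#'   sorted by fitness (base = best, difference = suboptimal minus worst),
#'   the scaling factor decays exponentially over generations and the
#'   crossover rate follows a sinusoidal schedule held for two generations
#'   at a time.
#'
#' Partner fitnesses for the sorted mutation are evaluated against the
#' frozen parent population of the current generation (cached once per
#' sweep); survivors replace parents synchronously at the end of each
#' sweep. All randomness flows from one stream seeded by `control$seed`,
#' so identical inputs give bitwise-identical results.
#'
#' @param data Drying-data tibble (see [drying_data()]).
#' @param order Polynomial order n; needs `kmax >= n + 1`.
#' @param algorithm `"mlp-i-ie"` (default) or `"mlp-ie"`.
#' @param control A [de_control()].
#' @return An object of class `mr_fit`: the fitted `mr_model`, the
#'   per-generation trajectory (best fitness plus the scaling-factor and
#'   crossover-rate values in force), training metrics, and echoes of the
#'   control and data. Has [generics::tidy()], [generics::glance()],
#'   [generics::augment()] and [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' d <- simulate_drying(kmax = 60, sigma = 0.02, seed = 1)
#' fit <- fit_moisture_model(d, order = 3,
#'                           control = de_control(seed = 1))
#' glance(fit)
fit_moisture_model <- function(data, order,
                               algorithm = c("mlp-i-ie", "mlp-ie"),
                               control = de_control()) {
  algorithm <- match.arg(algorithm)
  data <- validate_drying_data(data)
  if (nrow(data) < order + 1) {
    stop("need at least order + 1 records to fit order ", order,
         call. = FALSE)
  }
  if (order >= 1 && length(unique(data$shrinkage)) < order + 1) {
    warning("degenerate dataset: fewer than order + 1 distinct shrinkage ",
            "values; the fitness landscape has no unique minimum",
            call. = FALSE)
  }

  improved <- algorithm == "mlp-i-ie"
  Q <- order + 1L
  P <- control$pop_size
  gmax <- control$generations
  X <- design_matrix(data$shrinkage, order)
  y <- data$moisture_ratio
  lam_of <- function(G) colMeans((y - X %*% t(G))^2)

  pop <- init_population(control, Q)  # seeds the stream when control$seed set
  lam <- lam_of(pop)

  traj <- f_used <- cr_used <- numeric(gmax)
  cr_prev <- NA_real_
  for (g1 in seq_len(gmax)) {
    if (improved) {
      f_g <- scaling_factor_schedule(g1, gmax, control$f1, control$f2,
                                     control$f3)
      cr_g <- if (g1 == 1 || g1 %% 2 == 0) {
        crossover_rate_schedule(g1, control$c1, control$c2)
      } else {
        cr_prev
      }
      cr_prev <- cr_g
    } else {
      f_g <- control$scaling_factor
      cr_g <- control$crossover_rate
    }
    trials <- matrix(0, P, Q)
    for (p in seq_len(P)) {
      mutant <- if (improved) {
        mutate_sorted(pop, p, f_g, mlf_values = lam)
      } else {
        mutate_rand1(pop, p, f_g)
      }
      trials[p, ] <- crossover_binomial(mutant, pop[p, ], cr_g)
    }
    lam_trial <- lam_of(trials)
    win <- lam_trial < lam  # greedy: ties keep the parent
    pop[win, ] <- trials[win, ]
    lam[win] <- lam_trial[win]
    traj[g1] <- min(lam)
    f_used[g1] <- f_g
    cr_used[g1] <- cr_g
  }

  i_best <- which.min(lam)  # ties broken by lowest index
  model <- polynomial_model(pop[i_best, ])
  structure(
    list(
      algorithm = algorithm,
      order = order,
      model = model,
      trajectory = tibble::tibble(
        generation = seq_len(gmax), best_mlf = traj,
        scaling_factor = f_used, crossover_rate = cr_used
      ),
      metrics = fit_metric_row(model, data),
      control = control,
      data = data
    ),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Moisture-ratio model fit (", x$algorithm, ", order ", x$order,
      ")\n", sep = "")
  print(signif(x$model$gamma, 6))
  m <- x$metrics
  cat(sprintf("R2 %.4f  adjR2 %.4f  RMSE %.4g  (kmax %d, %d generations)\n",
              m$r2, m$adj_r2, m$rmse, nrow(x$data),
              nrow(x$trajectory)))
  invisible(x)
}
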