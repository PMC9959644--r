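#' Differential-evolution control parameters
#'
#' Collects every tunable of the two evolutionary estimators. The classic
#' estimator uses the fixed `scaling_factor` and `crossover_rate`; the
#' improved estimator ignores those and derives per-generation values from
#' the schedule constants `f1, f2, f3` (exponential decay of the scaling
#' factor) and `c1, c2` (sinusoidal crossover rate with a two-generation
#' hold). Individuals are initialised uniformly on
#' `[init_low, init_high)`; the search is unbounded afterwards.
#'
#' Schedule constants must satisfy `2/c1 + c2 <= 1` so the crossover rate
#' stays a probability. The defaults decay F smoothly from about 0.88 of
#' `f1` and let CR oscillate over (0.2, 1.0].
#'
#' @param pop_size Population size P (at least 4; mutation needs three
#'   distinct partners besides the target).
#' @param generations Number of evolution sweeps gmax (no early stopping).
#' @param scaling_factor Fixed mutation scaling factor F for the classic
#'   estimator (positive).
#' @param crossover_rate Fixed crossover rate CR for the classic estimator,
#'   in [0, 1].
#' @param f1,f2,f3 Positive constants of the improved scaling-factor decay
#'   `F(g) = f1 * exp(-f2 * g / gmax^f3)`.
#' @param c1,c2 Positive constants of the improved crossover-rate schedule
#'   `CR(g) = (1 + sin(g)) / c1 + c2` (held over odd generations).
#' @param init_low,init_high Initialisation bounds (low < high). The default
#'   unit box matches the estimators' definition; recovery at few
#'   generations benefits from a wider box.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return A list of class `de_control`.
#' @export
de_control <- function(pop_size = 30, generations = 20,
                       scaling_factor = 0.5, crossover_rate = 0.9,
                       f1 = 0.9, f2 = 0.5, f3 = 1, c1 = 2.5, c2 = 0.2,
                       init_low = 0, init_high = 1, seed = NULL) {
  stopifnot(
    "pop_size must be >= 4" = pop_size >= 4,
    "generations must be >= 1" = generations >= 1,
    "scaling_factor must be positive" = scaling_factor > 0,
    "crossover_rate must lie in [0, 1]" =
      crossover_rate >= 0 && crossover_rate <= 1,
    "f1, f2, f3 must be positive" = f1 > 0 && f2 > 0 && f3 > 0,
    "c1, c2 must be positive" = c1 > 0 && c2 > 0,
    "need 2/c1 + c2 <= 1 so CR stays a probability" = 2 / c1 + c2 <= 1,
    "init_low must be below init_high" = init_low < init_high
  )
  structure(
    list(pop_size = as.integer(pop_size),
         generations = as.integer(generations),
         scaling_factor = scaling_factor, crossover_rate = crossover_rate,
         f1 = f1, f2 = f2, f3 = f3, c1 = c1, c2 = c2,
         init_low = init_low, init_high = init_high,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "de_control"
  )
}

#' Initialise a population of candidate coefficient vectors
#'
#' Draws a `pop_size` x Q matrix of independent uniforms on
#' `[init_low, init_high)`. If the control carries a seed the RNG is seeded
#' first, so the same control always yields the same population.
#'
#' @param control A [de_control()].
#' @param q Number of coefficients Q = order + 1.
#' @return Numeric matrix with `pop_size` rows (individuals) and `q`
#'   columns, attribute `generation = 0`.
#' @export
init_population <- function(control, q) {
  if (!inherits(control, "de_control")) {
    stop("control must be a de_control object", call. = FALSE)
  }
  if (q < 1) stop("q must be at least 1", call. = FALSE)
  if (!is.null(control$seed)) set.seed(control$seed)
  pop <- matrix(
    stats::runif(control$pop_size * q, control$init_low, control$init_high),
    nrow = control$pop_size, ncol = q
  )
  attr(pop, "generation") <- 0L
  pop
}

check_population <- function(pop, p) {
  if (!is.matrix(pop) || nrow(pop) < 4) {
    stop("population must be a matrix with at least 4 individuals",
         call. = FALSE)
  }
  if (p < 1 || p > nrow(pop)) stop("index p out of range", call. = FALSE)
}

draw_partners <- function(pop, p, partners) {
  if (is.null(partners)) partners <- sample((seq_len(nrow(pop)))[-p], 3)
  if (length(partners) != 3 || anyDuplicated(c(partners, p)) > 0) {
    stop("partners must be three distinct indices different from p",
         call. = FALSE)
  }
  partners
}

#' rand/1 mutation
#'
#' Classic difference mutation: three partners kappa1..kappa3 are drawn
#' without replacement from the population excluding the target index, and
#' the mutant is `gamma[kappa1] + F * (gamma[kappa2] - gamma[kappa3])`.
#'
#' @param pop Population matrix (individuals in rows).
#' @param p Target index (excluded from the partner draw).
#' @param scaling_factor Mutation scaling factor F.
#' @param partners Optional three distinct partner indices; drawn at random
#'   from the current RNG stream when `NULL`.
#' @return Mutant coefficient vector of length `ncol(pop)`.
#' @export
mutate_rand1 <- function(pop, p, scaling_factor, partners = NULL) {
  check_population(pop, p)
  kap <- draw_partners(pop, p, partners)
  pop[kap[1], ] + scaling_factor * (pop[kap[2], ] - pop[kap[3], ])
}

#' Fitness-sorted mutation
#'
#' The improved variant's mutation: the three drawn partners are ranked by
#' their fitness on the dataset (best = smallest mean squared residual) and
#' the mutant is `best + F * (suboptimal - worst)`, so the base vector
#' searches along the locally descending direction rather than a random
#' one. Ties in the ranking are broken by ascending partner index.
#'
#' @inheritParams mutate_rand1
#' @param data Drying-data tibble the partner fitnesses are evaluated on.
#' @param mlf_values Optional precomputed fitness per population row
#'   (a per-generation cache); computed from `data` when `NULL`.
#' @return Mutant coefficient vector.
#' @export
mutate_sorted <- function(pop, p, scaling_factor, data = NULL,
                          partners = NULL, mlf_values = NULL) {
  check_population(pop, p)
  kap <- draw_partners(pop, p, partners)
  if (is.null(mlf_values)) {
    if (is.null(data)) {
      stop("either data or mlf_values must be supplied", call. = FALSE)
    }
    lam <- vapply(kap, function(i) mlf(pop[i, ], data), numeric(1))
  } else {
    lam <- mlf_values[kap]
  }
  kap <- kap[order(lam, kap)]
  pop[kap[1], ] + scaling_factor * (pop[kap[2], ] - pop[kap[3], ])
}

#' Binomial crossover
#'
#' Builds the trial vector element by element: position q takes the mutant
#' element when an independent uniform draw falls below the crossover rate
#' or q equals a uniformly drawn forced position `q_rand`, and the parent
#' element otherwise. The forced position guarantees at least one mutant
#' element survives.
#'
#' @param mutant,parent Coefficient vectors of equal length Q.
#' @param crossover_rate CR in [0, 1].
#' @param q_rand Optional forced position in 1..Q; drawn uniformly when
#'   `NULL`.
#' @return Trial vector of length Q.
#' @export
crossover_binomial <- function(mutant, parent, crossover_rate,
                               q_rand = NULL) {
  Q <- length(mutant)
  if (length(parent) != Q) {
    stop("mutant and parent must have the same length", call. = FALSE)
  }
  if (crossover_rate < 0 || crossover_rate > 1) {
    stop("crossover_rate must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(q_rand)) q_rand <- sample.int(Q, 1)
  u <- stats::runif(Q)
  take <- u < crossover_rate | seq_len(Q) == q_rand
  ifelse(take, mutant, parent)
}

#' Greedy survivor selection
#'
#' The trial vector replaces the parent only when its fitness is strictly
#' smaller; ties keep the parent.
#'
#' @param trial,parent Coefficient vectors of equal length.
#' @param data Drying-data tibble.
#' @return The surviving vector, with attribute `accepted` (TRUE when the
#'   trial won).
#' @export
select_greedy <- function(trial, parent, data) {
  accepted <- mlf(trial, data) < mlf(parent, data)
  out <- if (accepted) trial else parent
  attr(out, "accepted") <- accepted
  out
}

#' Best individual of a population
#'
#' @param pop Population matrix.
#' @param data Drying-data tibble.
#' @return List with `index` (ties broken by lowest index), `gamma`, and
#'   `mlf`.
#' @export
best_individual <- function(pop, data) {
  if (!is.matrix(pop) || nrow(pop) < 1) {
    stop("population must be a non-empty matrix", call. = FALSE)
  }
  data <- validate_drying_data(data)
  X <- design_matrix(data$shrinkage, ncol(pop) - 1)
  lam <- colMeans((data$moisture_ratio - X %*% t(pop))^2)
  i <- which.min(lam)
  list(index = i, gamma = pop[i, ], mlf = lam[i])
}

#' Scaling-factor decay schedule
#'
#' `F(g) = f1 * exp(-f2 * g / gmax^f3)` for generation index g = 1..gmax:
#' large early for global search, shrinking to accelerate convergence.
#' Strictly decreasing in g.
#'
#' @param g_plus_1 Generation index, 1-based.
#' @param gmax Total number of generations.
#' @param f1,f2,f3 Positive schedule constants.
#' @return Scaling factor in (0, f1).
#' @export
#' @examples
#' scaling_factor_schedule(20, gmax = 20, f1 = 1, f2 = 1, f3 = 1) # exp(-1)
scaling_factor_schedule <- function(g_plus_1, gmax,
                                    f1 = 0.9, f2 = 0.5, f3 = 1) {
  if (any(c(f1, f2, f3) <= 0)) {
    stop("f1, f2, f3 must be positive", call. = FALSE)
  }
  if (any(g_plus_1 < 1) || any(g_plus_1 > gmax)) {
    stop("g_plus_1 must lie in 1..gmax", call. = FALSE)
  }
  f1 * exp(-f2 * g_plus_1 / gmax^f3)
}

#' Crossover-rate schedule with two-generation hold
#'
#' `CR(g) = (1 + sin(g)) / c1 + c2` evaluated in radians on the bare
#' integer generation index, recomputed at generation 1 and every even
#' generation; each odd generation above 1 reuses the previous value, so
#' the rate updates once while the generation advances twice. Values stay
#' in `(c2, 2/c1 + c2]`.
#'
#' @param g_plus_1 Generation index, 1-based.
#' @param c1,c2 Positive constants with `2/c1 + c2 <= 1`.
#' @return Crossover rate.
#' @export
#' @examples
#' crossover_rate_schedule(1, c1 = 4, c2 = 0.3) # (1 + sin(1))/4 + 0.3
crossover_rate_schedule <- function(g_plus_1, c1 = 2.5, c2 = 0.2) {
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive", call. = FALSE)
  if (2 / c1 + c2 > 1) {
    stop("need 2/c1 + c2 <= 1 so CR stays a probability", call. = FALSE)
  }
  if (any(g_plus_1 < 1)) stop("g_plus_1 must be >= 1", call. = FALSE)
  arg <- ifelse(g_plus_1 == 1 | g_plus_1 %% 2 == 0, g_plus_1, g_plus_1 - 1)
  (1 + sin(arg)) / c1 + c2
}
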