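test_that("population initialisation respects size, bounds and seed", {
  ctl <- de_control(pop_size = 30, seed = 5)
  pop <- init_population(ctl, 4)
  expect_equal(dim(pop), c(30, 4))
  expect_true(all(pop >= 0 & pop < 1))
  expect_identical(pop, init_population(ctl, 4))
  wide <- de_control(init_low = -5, init_high = 15, seed = 1)
  pw <- init_population(wide, 3)
  expect_true(all(pw >= -5 & pw < 15))
  expect_error(de_control(pop_size = 3), "pop_size")
  expect_error(de_control(init_low = 1, init_high = 0), "init_low")
  expect_error(de_control(c1 = 1.5, c2 = 0.5), "probability")
})

test_that("rand/1 mutation adds the scaled partner difference", {
  pop <- rbind(c(9, 9), c(1, 1), c(2, 0), c(0, 2))
  expect_equal(mutate_rand1(pop, 1, 0.5, partners = c(2, 3, 4)), c(2, 0))
  # identical second and third partners cancel
  pop2 <- rbind(c(9, 9), c(1, 1), c(5, 5), c(5, 5))
  expect_equal(mutate_rand1(pop2, 1, 0.7, partners = c(2, 3, 4)), c(1, 1))
  # F = 0 returns the base partner whatever the draw
  set.seed(1)
  for (i in 1:10) {
    z <- mutate_rand1(pop, 2, 0)
    expect_true(any(apply(pop[-2, ], 1, function(r) all(r == z))))
  }
  expect_error(mutate_rand1(pop[1:3, ], 1, 0.5), "at least 4")
  expect_error(mutate_rand1(pop, 1, 0.5, partners = c(1, 2, 3)), "distinct")
})

test_that("random mutation partners are distinct and exclude the target", {
  d <- toy_data()
  pop <- matrix(runif(12), 6, 2)
  set.seed(99)
  for (i in 1:200) {
    p <- sample.int(6, 1)
    base <- mutate_rand1(pop, p, 0)  # F = 0 exposes the base partner
    matches <- which(apply(pop, 1, function(r) all(r == base)))
    expect_length(matches, 1)   # base is an actual individual
    expect_false(matches == p)  # and never the target itself
  }
})

test_that("fitness-sorted mutation assigns base/sub/worst roles by MLF", {
  d <- toy_data()
  # engineered fitnesses: row 2 exact (lambda 0), row 3 mid, row 4 worst
  pop <- rbind(c(9, 9), c(-1, 2), c(0, 1), c(5, 5))
  lam <- vapply(1:4, function(i) mlf(pop[i, ], d), numeric(1))
  expect_true(lam[2] < lam[3] && lam[3] < lam[4])
  z <- mutate_sorted(pop, 1, 0.5, data = d, partners = c(4, 2, 3))
  expect_equal(z, c(-1, 2) + 0.5 * (c(0, 1) - c(5, 5)))
  # hand-arithmetic role check with explicit fitness cache
  pop2 <- rbind(c(7, 7), c(0, 0), c(1, 0), c(0, 1))
  z2 <- mutate_sorted(pop2, 1, 0.5, partners = c(2, 3, 4),
                      mlf_values = c(9, 0.1, 0.2, 0.3))
  expect_equal(z2, c(0.5, -0.5))
  # identical vectors at distinct indices collapse to that vector
  pop3 <- rbind(c(7, 7), c(2, 3), c(2, 3), c(2, 3))
  expect_equal(mutate_sorted(pop3, 1, 0.9, data = d, partners = c(2, 3, 4)),
               c(2, 3))
  # sorted partner fitnesses always satisfy base <= sub <= worst
  set.seed(4)
  pop4 <- matrix(rnorm(10), 5, 2)
  lam4 <- vapply(1:5, function(i) mlf(pop4[i, ], d), numeric(1))
  for (i in 1:50) {
    kap <- sample((1:5)[-2], 3)
    z <- mutate_sorted(pop4, 2, 0, partners = kap, mlf_values = lam4)
    expect_equal(mlf(z, d), min(lam4[kap]))
  }
})

test_that("binomial crossover mixes mutant and parent as specified", {
  mutant <- rep(1, 6)
  parent <- rep(0, 6)
  expect_equal(crossover_binomial(mutant, parent, 1), mutant)
  # CR = 0: only the forced position survives
  for (q in 1:6) {
    trial <- crossover_binomial(mutant, parent, 0, q_rand = q)
    expect_equal(sum(trial), 1)
    expect_equal(trial[q], 1)
  }
  # at least one mutant element always survives
  set.seed(2)
  for (i in 1:100) expect_gte(sum(crossover_binomial(mutant, parent, 0)), 1)
  expect_error(crossover_binomial(1:3, 1:2, 0.5), "same length")
  expect_error(crossover_binomial(1:3, 1:3, 1.5), "\\[0, 1\\]")
})

test_that("crossover takes mutant elements at about the crossover rate", {
  set.seed(7)
  q_len <- 100
  n_rep <- 100
  taken <- replicate(n_rep, sum(crossover_binomial(rep(1, q_len),
                                                   rep(0, q_len), 0.5)))
  frac <- sum(taken) / (q_len * n_rep)
  # binomial law: expectation CR + (1-CR)/Q (forced draw), 3 sigma band
  expected <- 0.5 + 0.5 / q_len
  sigma <- sqrt(0.25 / (q_len * n_rep))
  expect_lt(abs(frac - expected), 3 * sigma + 1e-6)
})

test_that("greedy selection keeps the parent on ties and never regresses", {
  d <- toy_data()
  winner <- select_greedy(c(-1, 2), c(0, 1), d)
  expect_equal(unname(winner[1:2]), c(-1, 2))
  expect_true(attr(winner, "accepted"))
  # (-1.5, 3) has residuals (-0.5, 0): same fitness 0.125 as (0, 1)
  expect_equal(mlf(c(-1.5, 3), d), mlf(c(0, 1), d))
  tie <- select_greedy(c(0, 1), c(-1.5, 3), d)
  expect_false(attr(tie, "accepted"))
  expect_equal(unname(tie[1:2]), c(-1.5, 3))
  # exhaustive toy check: survivor fitness never exceeds the parent's
  set.seed(3)
  pool <- matrix(rnorm(6), 3, 2)
  for (i in 1:3) for (j in 1:3) {
    surv <- select_greedy(pool[i, ], pool[j, ], d)
    expect_lte(mlf(surv, d), mlf(pool[j, ], d))
  }
})

test_that("best individual matches an exhaustive fitness scan", {
  d <- simulate_drying(kmax = 20, sigma = 0.05, seed = 8)
  set.seed(9)
  pop <- matrix(rnorm(40), 10, 4)
  best <- best_individual(pop, d)
  lam <- vapply(1:10, function(i) mlf(pop[i, ], d), numeric(1))
  expect_equal(best$index, which.min(lam))
  expect_equal(best$mlf, min(lam))
  # a population containing the least-squares solution is won by it
  ols <- ols_fit(d, 3)
  pop2 <- rbind(pop, ols$gamma)
  expect_equal(best_individual(pop2, d)$index, 11)
  # single individual
  expect_equal(best_individual(pop[1, , drop = FALSE], d)$index, 1)
})

test_that("scaling-factor schedule decays exponentially", {
  expect_equal(scaling_factor_schedule(20, 20, f1 = 1, f2 = 1, f3 = 1),
               exp(-1))
  # f2 -> 0 limit approaches f1
  expect_equal(scaling_factor_schedule(7, 20, f1 = 0.9, f2 = 1e-12, f3 = 1),
               0.9, tolerance = 1e-9)
  f <- scaling_factor_schedule(1:50, 50, f1 = 0.9, f2 = 0.5, f3 = 1)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f < 0.9))
  expect_error(scaling_factor_schedule(1, 20, f1 = -1), "positive")
  expect_error(scaling_factor_schedule(21, 20), "1..gmax")
})

test_that("crossover-rate schedule oscillates with a two-generation hold", {
  expect_equal(crossover_rate_schedule(1, c1 = 4, c2 = 0.3),
               (1 + sin(1)) / 4 + 0.3)
  expect_equal(crossover_rate_schedule(1, c1 = 4, c2 = 0.3), 0.7603678,
               tolerance = 1e-6)
  cr <- crossover_rate_schedule(1:40, c1 = 2.5, c2 = 0.2)
  # each odd generation above 1 repeats the preceding even one
  odd <- seq(3, 39, by = 2)
  expect_equal(cr[odd], cr[odd - 1])
  expect_true(all(cr > 0.2 & cr <= 2 / 2.5 + 0.2))
  expect_error(crossover_rate_schedule(1, c1 = 1.5, c2 = 0.5),
               "probability")
  expect_error(crossover_rate_schedule(0, c1 = 4, c2 = 0.3), ">= 1")
})
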