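# Branching-process calculus: outcome probabilities, the extinction
# fixed point, criticality, and the Monte Carlo oracle.

test_that("outcome probabilities sum to one over a random parameter sweep", {
  set.seed(42)
  n <- 1e4
  pr <- branching_probabilities(runif(n), runif(n), runif(n), runif(n))
  expect_true(all(abs(pr$p1 + pr$p2 + pr$p3 + pr$p4 - 1) < 1e-12))
  expect_true(all(pr[c("p1", "p2", "p3", "p4")] >= 0))
})

test_that("outcome probabilities match direct substitution", {
  pr <- branching_probabilities(0.001, 0.001, 0.01, 1)
  expect_equal(pr$p1, 0.001)
  expect_equal(pr$p2, 0.98901, tolerance = 1e-10)
  expect_equal(pr$p3, 0.00999, tolerance = 1e-10)
  expect_equal(pr$p4, 0)
  # no differentiation: the CSC count can never decrease
  expect_equal(branching_probabilities(0, 0.3, 0.2, 0.5)$p1, 0)
  # a doomed newborn CC can never dedifferentiate and divide symmetrically
  expect_equal(branching_probabilities(0.2, 0.3, 0.2, 1)$p4, 0)
})

test_that("extinction probability solves the cubic fixed point", {
  set.seed(7)
  grid <- tibble::tibble(p_d = runif(50), p_dd = runif(50),
                         p_s = runif(50), ap = runif(50))
  pr <- branching_probabilities(grid$p_d, grid$p_dd, grid$p_s, grid$ap)
  ok <- !is.na(pr$p)
  P <- extinction_probability(grid$p_d[ok], grid$p_dd[ok], grid$p_s[ok],
                              grid$ap[ok])
  p <- pr$p[ok]; q <- pr$q[ok]; r <- 1 - p - q
  # P satisfies the relation, and 1 is always a root
  expect_true(all(abs(P - (p + q * P^2 + r * P^3)) < 1e-9))
  expect_true(all(abs(1 - (p + q + r)) < 1e-12))
  expect_true(all(P >= 0 & P <= 1))
})

test_that("extinction probability reproduces the printed regimes", {
  # no differentiation: extinction impossible
  expect_equal(extinction_probability(0, 0.01, 0.01, 0.5), 0)
  # small symmetric plasticity: P ~ 0.1 (exactly p1/p3 when alpha' = 1)
  P <- extinction_probability(0.001, 0.001, 0.01, 1)
  expect_equal(P, 0.001 / 0.00999, tolerance = 1e-10)
  expect_equal(P, 0.1, tolerance = 2e-3)
  # high plasticity: certain remission for any alpha'
  expect_equal(extinction_probability(0.1, 0.1, 0.01, 0.01), 1)
  expect_equal(extinction_probability(0.1, 0.1, 0.01, 1), 1)
  # undefined when the CSC count can never change
  expect_error(extinction_probability(0, 0, 0, 0.5),
               class = "stemplast_error_undefined_extinction")
})

test_that("P is monotone in each parameter", {
  g <- seq(0.05, 0.95, by = 0.15)
  base <- list(p_d = 0.3, p_dd = 0.3, p_s = 0.3, ap = 0.5)
  P_pd <- extinction_probability(g, base$p_dd, base$p_s, base$ap)
  expect_true(all(diff(P_pd) >= -1e-12))
  P_ap <- extinction_probability(base$p_d, base$p_dd, base$p_s, g)
  expect_true(all(diff(P_ap) >= -1e-12))
  P_pdd <- extinction_probability(base$p_d, g, base$p_s, base$ap)
  expect_true(all(diff(P_pdd) <= 1e-12))
  P_ps <- extinction_probability(base$p_d, base$p_dd, g, base$ap)
  expect_true(all(diff(P_ps) <= 1e-12))
})

test_that("critical plasticity matches the known thresholds", {
  # the printed ~9.09% threshold at p_s = 1%, alpha' = 1%
  crit <- critical_plasticity(p_s = 0.01, alpha_prime = 0.01)
  expect_equal(as.numeric(crit), 0.0909, tolerance = 2e-3)
  # closed form p_s / (1 + p_s) when alpha' = 1
  expect_equal(as.numeric(critical_plasticity(0.01, 1)), 0.01 / 1.01,
               tolerance = 1e-8)
  # without symmetric division, any differentiation dooms the lineage
  expect_equal(as.numeric(critical_plasticity(0, 0.5)), 0)
  # consistency: certain extinction just above, uncertain just below
  x <- as.numeric(crit)
  expect_equal(extinction_probability(x + 1e-3, x + 1e-3, 0.01, 0.01), 1)
  expect_lt(extinction_probability(x - 1e-3, x - 1e-3, 0.01, 0.01), 1)
})

test_that("extinction_profile tabulates the grid", {
  tab <- extinction_profile(c(0, 0.001, 0.1), alpha_prime = c(0.01, 1))
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$P[tab$p_d == 0], c(0, 0))
  expect_equal(tab$P[tab$p_d == 0.1], c(1, 1))
})

test_that("the Galton-Watson oracle agrees with the closed form", {
  # a deeply subcritical point (certain extinction) and a clearly
  # supercritical one (interior P), both desk-sized
  for (case in list(list(pd = 0.05, ps = 0.01, ap = 1),
                    list(pd = 0.02, ps = 0.10, ap = 1))) {
    P <- extinction_probability(case$pd, case$pd, case$ps, case$ap)
    mc <- simulate_branching(case$pd, case$pd, case$ps, case$ap,
                             n_reps = 2e4, seed = 13)
    tol <- 3 * sqrt(max(P * (1 - P), 1e-6) / 2e4)
    expect_lt(abs(as.numeric(mc) - P), tol + 1e-12)
  }
  # no differentiation: no lineage ever dies
  expect_equal(as.numeric(simulate_branching(0, 0.01, 0.01, 1,
                                             n_reps = 200, seed = 1)), 0)
})

test_that("early-death events are impossible without differentiation and rare with certain rescue", {
  p0 <- model_params(p_d = 0)
  f0 <- early_death_probability(p0, n_reps = 20, seed = 2)
  expect_equal(as.numeric(f0), 0)
  # p_dd = 1: any surviving CC division dedifferentiates and rescues
  p1 <- model_params(p_d = 0.5, p_dd = 1)
  f1 <- early_death_probability(p1, n_reps = 200, seed = 2)
  expect_lt(as.numeric(f1), 0.1)
})
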