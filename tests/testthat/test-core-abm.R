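# The hourly lattice engine: per-cell update rules, division kernel,
# conservation and reproducibility properties.

test_that("degenerate dynamics behave as fixed points", {
  p <- model_params(p_p = 0, p_m = 0)
  # no events possible: population stays exactly one for all time
  sim <- simulate_tumor(p, days = 30, seed = 1)
  expect_true(all(sim$series$n_total == 1))
  expect_equal(sim$final_state$cells$rho, 10L)

  # an empty state is a fixed point: the run reports extinction right away
  empty <- tumor_state(tibble::tibble(x = integer(), y = integer(),
                                      phenotype = character(),
                                      rho = integer()))
  sim0 <- continue_simulation(empty, model_params(), days = 2, seed = 1)
  expect_equal(n_cells(sim0$final_state), 0L)
  expect_equal(sim0$status, "extinct")
  expect_gte(sim0$final_state$time_h, 1)

  # certain spontaneous death: alpha = 1 kills a nonstem cell in one step
  pa <- model_params(alpha = 1)
  s <- init_state(pa, founder_rho = 5, founder_phenotype = "N")
  sim1 <- continue_simulation(s, pa, days = 1, seed = 1)
  expect_equal(sim1$status, "extinct")
  expect_equal(sim1$final_state$time_h, 1)
})

test_that("division kernel follows stem/nonstem rules with one plasticity draw", {
  kern <- function(stem, rho, par, u1, u2) {
    stemplast:::.cpp_divide_kernel(stem, rho, par, u1, u2)
  }
  par <- stemplast:::par_list(model_params(p_d = 0, p_dd = 0, p_s = 0.5))

  # symmetric CSC division: both stem, no erosion
  r <- kern(1L, 10L, par, 0.9, 0.1)
  expect_equal(r[c("parent_stem", "parent_rho", "daughter_stem",
                   "daughter_rho")], list(parent_stem = 1L, parent_rho = 10L,
                                          daughter_stem = 1L,
                                          daughter_rho = 10L))
  # asymmetric CSC division: daughter nonstem with the parent's capacity
  r <- kern(1L, 10L, par, 0.9, 0.9)
  expect_equal(r$daughter_stem, 0L)
  expect_equal(r$daughter_rho, 10L)
  expect_equal(r$parent_rho, 10L)

  # plain nonstem division erodes both cells by one
  r <- kern(0L, 1L, par, 0.9, 0.9)
  expect_equal(r$parent_rho, 0L)
  expect_equal(r$daughter_rho, 0L)
  expect_equal(r$daughter_stem, 0L)

  # dedifferentiation at division: new CSC keeps its capacity (memory),
  # and the division proceeds under stem rules (no erosion)
  par2 <- stemplast:::par_list(model_params(p_d = 0, p_dd = 0.5, p_s = 0.01))
  r <- kern(0L, 7L, par2, 0.1, 0.9)           # dediff drawn, asymmetric
  expect_equal(r$parent_stem, 1L)
  expect_equal(r$parent_rho, 7L)
  expect_equal(r$daughter_stem, 0L)
  expect_equal(r$daughter_rho, 7L)

  # differentiation: the cell converts and divides under nonstem rules
  par3 <- stemplast:::par_list(model_params(p_d = 0.5, p_dd = 0, p_s = 0.5))
  r <- kern(1L, 10L, par3, 0.1, 0.1)
  expect_equal(r$parent_stem, 0L)
  expect_equal(r$parent_rho, 9L)
  expect_equal(r$daughter_stem, 0L)
  expect_equal(r$daughter_rho, 9L)
  expect_equal(r$event, 2L)
})

test_that("without plasticity phenotypes are closed and capacities bounded", {
  p <- model_params(p_d = 0, p_dd = 0)
  sim <- simulate_tumor(p, days = 120, seed = 7)
  # no phenotype transitions ever occurred
  expect_equal(sim$counters$divisions_differentiation, 0)
  expect_equal(sim$counters$divisions_dedifferentiation, 0)
  # CSC count is nondecreasing (CSCs cannot die or convert)
  expect_true(all(diff(sim$series$n_csc) >= 0))
  # stem capacity constant while stem; nonstem lineages only erode
  cells <- sim$final_state$cells
  expect_true(all(cells$rho[cells$phenotype == "S"] == 10L))
  expect_true(all(cells$rho[cells$phenotype == "N"] <= 10L))
  expect_true(all(cells$rho >= 0L))
})

test_that("occupancy stays single per site and counts balance the ledger", {
  sim <- simulate_tumor(model_params(), days = 90, seed = 11)
  cells <- sim$final_state$cells
  expect_equal(anyDuplicated(cells[c("x", "y")]), 0L)
  ct <- sim$counters
  # every division adds exactly one cell, so final count = 1 + divisions -
  # deaths; event-type counters can overlap (a dedifferentiation may also be
  # symmetric) but never undercount the total
  deaths <- ct$deaths_alpha + ct$deaths_exhaustion
  expect_equal(nrow(cells), 1 + ct$divisions_total - deaths)
  expect_gte(ct$divisions_symmetric + ct$divisions_plain +
               ct$divisions_differentiation + ct$divisions_dedifferentiation,
             ct$divisions_total)
})

test_that("a lone migrating cell moves at the nominal migration rate", {
  p <- model_params(alpha = 0, p_p = 0, p_m = 15 / 24)
  s <- init_state(p, founder_rho = 5, founder_phenotype = "N")
  out <- stemplast:::run_engine(s, p, hours = 1e4, seed = 21)
  moves <- out$counters$migrations
  expect_true(within_3se(moves / 1e4, 15 / 24, 1e4))
})

test_that("identical seeds give bit-identical runs, different seeds differ", {
  a <- simulate_tumor(model_params(), days = 60, seed = 5)
  b <- simulate_tumor(model_params(), days = 60, seed = 5)
  expect_identical(a$series, b$series)
  expect_identical(a$final_state$cells, b$final_state$cells)
  c <- simulate_tumor(model_params(), days = 60, seed = 6)
  expect_false(identical(a$series, c$series))
})

test_that("grow_to_size returns the first state at or past the target", {
  p <- model_params()
  expect_equal(n_cells(grow_to_size(p, 1, seed = 1)), 1L)
  st <- grow_to_size(p, 2000, seed = 1)
  expect_gte(n_cells(st), 2000)
  expect_gt(csc_fraction(st), 0)
  expect_lt(csc_fraction(st), 1)
  # high plasticity and a small founder capacity make extinction certain
  px <- model_params(p_d = 0.1, p_dd = 0.1, p_s = 0.01)
  expect_error(grow_to_size(px, 1e6, seed = 1, founder_rho = 3),
               class = "stemplast_error_extinct")
  # immobile, non-proliferating founder times out
  p0 <- model_params(p_p = 0, p_m = 0)
  expect_error(grow_to_size(p0, 2, seed = 1, max_days = 1),
               class = "stemplast_error_timeout")
})

test_that("stop_when predicates halt the chunked run", {
  sim <- simulate_tumor(model_params(), days = 200, seed = 8,
                        stop_when = function(s) n_cells(s) >= 50)
  expect_equal(sim$status, "stopped")
  expect_gte(n_cells(sim$final_state), 50)
  expect_lt(sim$final_state$time_h / 24, 200)
})
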