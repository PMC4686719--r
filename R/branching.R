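# Branching-process theory of CSC lineage survival.
#
# Consider the CSCs of one capacity index. A division event of such a CSC
# changes their number by -1 (differentiation), 0, +1 or +2; the +1/+2 routes
# include an asymmetric division whose nonstem daughter survives to its first
# division (probability 1 - alpha') and dedifferentiates there. The embedded
# jump chain over the non-neutral outcomes gives the extinction probability P
# as the smallest root in [0, 1] of P = p + q P^2 + (1 - p - q) P^3.

#' Division-outcome probabilities of the CSC branching process
#'
#' For a CSC of a fixed capacity index, the probabilities that one division
#' event decreases the count by one (`p1`), leaves it unchanged (`p2`),
#' increases it by one (`p3`) or by two (`p4`):
#' \deqn{p_1 = p_d}
#' \deqn{p_2 = (1-p_d)(1-p_s)[\alpha' + (1-\alpha')(1-p_{dd})]}
#' \deqn{p_3 = (1-p_d)[p_s + (1-p_s)(1-\alpha')p_{dd}(1-p_s)]}
#' \deqn{p_4 = (1-p_d)(1-p_s)(1-\alpha')p_{dd}p_s}
#' where `alpha_prime` is the probability that a newly created nonstem cell
#' dies before any proliferation attempt. The four probabilities sum to one
#' identically. `p` and `q` are the normalized jump-chain weights
#' `p1/(p1+p3+p4)` and `p3/(p1+p3+p4)` (NA when the denominator is zero).
#'
#' @param p_d,p_dd,p_s Plasticity and symmetric-division probabilities.
#' @param alpha_prime Probability that a newborn nonstem cell dies before a
#'   proliferation attempt; bounded below by the hourly death rate `alpha`.
#'   All four arguments are recycled to a common length.
#' @return A tibble with columns `p_d`, `p_dd`, `p_s`, `alpha_prime`,
#'   `p1`..`p4`, `p`, `q`.
#' @examples
#' branching_probabilities(0.001, 0.001, 0.01, 1)
#' @export
branching_probabilities <- function(p_d, p_dd, p_s = 0.01, alpha_prime = 1) {
  check_prob(p_d, "p_d"); check_prob(p_dd, "p_dd")
  check_prob(p_s, "p_s"); check_prob(alpha_prime, "alpha_prime")
  n <- max(length(p_d), length(p_dd), length(p_s), length(alpha_prime))
  p_d <- rep_len(p_d, n); p_dd <- rep_len(p_dd, n)
  p_s <- rep_len(p_s, n); ap <- rep_len(alpha_prime, n)
  p1 <- p_d
  p2 <- (1 - p_d) * (1 - p_s) * (ap + (1 - ap) * (1 - p_dd))
  p3 <- (1 - p_d) * (p_s + (1 - p_s) * (1 - ap) * p_dd * (1 - p_s))
  p4 <- (1 - p_d) * (1 - p_s) * (1 - ap) * p_dd * p_s
  denom <- p1 + p3 + p4
  tibble(p_d = p_d, p_dd = p_dd, p_s = p_s, alpha_prime = ap,
         p1 = p1, p2 = p2, p3 = p3, p4 = p4,
         p = ifelse(denom > 0, p1 / denom, NA_real_),
         q = ifelse(denom > 0, p3 / denom, NA_real_))
}

#' Extinction probability of the CSC lineage
#'
#' Probability `P` that all CSCs of the founder's capacity index eventually
#' die out after seeding one such CSC. `P = 1` is always a root of the cubic
#' fixed-point relation; factoring it out leaves the quadratic
#' `r X^2 + (q + r) X - p = 0` with `r = 1 - p - q`, and `P` is the smaller
#' of 1 and the positive quadratic root. For `alpha_prime = 1` this reduces
#' to `P = min((1 - q)/q, 1)`, and `p_d = 0` gives `P = 0`.
#'
#' If `P = 1`, every tumor dies out regardless of its initial CSC count.
#'
#' @inheritParams branching_probabilities
#' @return Numeric vector of extinction probabilities in [0, 1].
#' @examples
#' extinction_probability(0.001, 0.001, 0.01, 1)   # ~ 0.1
#' extinction_probability(0.10, 0.10, 0.01, 0.01)  # 1: certain remission
#' @export
extinction_probability <- function(p_d, p_dd = p_d, p_s = 0.01,
                                   alpha_prime = 1) {
  pr <- branching_probabilities(p_d, p_dd, p_s, alpha_prime)
  if (anyNA(pr$p)) {
    abort("extinction probability undefined: p1 + p3 + p4 = 0 (the CSC count never changes)",
          class = "stemplast_error_undefined_extinction")
  }
  p <- pr$p; q <- pr$q; r <- 1 - p - q
  P <- numeric(length(p))
  lin <- r < .Machine$double.eps
  # r = 0: linear case (no +2 outcome), root p / q
  P[lin] <- ifelse(q[lin] > 0, p[lin] / q[lin], 1)
  disc <- (q + r)^2 + 4 * r * p
  P[!lin] <- (-(q[!lin] + r[!lin]) + sqrt(disc[!lin])) / (2 * r[!lin])
  pmin(1, pmax(0, P))
}

#' Critical plasticity rate for certain remission
#'
#' Smallest plasticity rate `x` (with `p_d = p_dd = x`) at which extinction
#' of the CSC lineage becomes certain, found as the root of the criticality
#' condition `p3 + 2 p4 = p1` (zero mean change in CSC count per event) by
#' bisection to absolute tolerance 1e-10. Above this rate every simulated
#' tumor eventually dies off spontaneously.
#'
#' @inheritParams branching_probabilities
#' @return The critical rate in [0, 1]. If the lineage is never certain to
#'   die for any rate, returns 1 with attribute `status = "never_certain"`;
#'   otherwise `status = "ok"`.
#' @examples
#' critical_plasticity(p_s = 0.01, alpha_prime = 0.01)  # ~ 0.0909
#' critical_plasticity(p_s = 0.01, alpha_prime = 1)     # p_s / (1 + p_s)
#' @export
critical_plasticity <- function(p_s = 0.01, alpha_prime = 1) {
  check_prob(p_s, "p_s"); check_prob(alpha_prime, "alpha_prime")
  f <- function(x) {
    pr <- branching_probabilities(x, x, p_s, alpha_prime)
    pr$p3 + 2 * pr$p4 - pr$p1
  }
  if (f(0) <= 0) return(structure(0, status = "ok"))
  if (f(1) > 0) return(structure(1, status = "never_certain"))
  lo <- 0; hi <- 1
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, status = "ok")
}

#' Tabulate extinction probability over parameter grids
#'
#' Convenience grid evaluation of [extinction_probability()] with
#' `p_d = p_dd`, e.g. to reproduce remission-probability curves over
#' plasticity rates for several `alpha_prime` values.
#'
#' @param p_d Vector of plasticity rates (used for both `p_d` and `p_dd`).
#' @param alpha_prime Vector of newborn-CC death probabilities.
#' @param p_s Symmetric division probability.
#' @return A tibble with one row per grid point and column `P`.
#' @export
extinction_profile <- function(p_d, alpha_prime = c(0.01, 1), p_s = 0.01) {
  grid <- tidyr::expand_grid(p_d = p_d, alpha_prime = alpha_prime)
  grid$p_s <- p_s
  grid$P <- extinction_probability(grid$p_d, grid$p_d, p_s, grid$alpha_prime)
  grid
}

#' Monte Carlo extinction fraction of the CSC branching process
#'
#' Simulates the four-outcome Galton-Watson process (offspring 0/1/2/3 with
#' probabilities `p1`..`p4`) from a single ancestor and returns the fraction
#' of lineages that die out. A lineage still alive after `max_generations`
#' generations, or whose population reaches `survival_cap`, counts as
#' surviving. Serves as an independent check on
#' [extinction_probability()]. Uses R's RNG (seeded via `seed`).
#'
#' @inheritParams branching_probabilities
#' @param n_reps Number of simulated lineages.
#' @param seed Integer seed.
#' @param max_generations Per-lineage generation cap.
#' @param survival_cap Population size at which survival is declared.
#' @return The extinct fraction, with attribute `n_extinct`.
#' @export
simulate_branching <- function(p_d, p_dd = p_d, p_s = 0.01, alpha_prime = 1,
                               n_reps = 1e5, seed = 1,
                               max_generations = 1e4, survival_cap = 1e6) {
  stopifnot(n_reps >= 1)
  pr <- branching_probabilities(p_d, p_dd, p_s, alpha_prime)
  stopifnot(nrow(pr) == 1)
  set.seed(seed)
  n_ext <- .cpp_branching_mc(pr$p1, pr$p2, pr$p3, pr$p4,
                             as.integer(n_reps), as.integer(max_generations),
                             survival_cap)
  structure(n_ext / n_reps, n_extinct = n_ext)
}

#' Alpha-prime implied by the hourly death/proliferation rule
#'
#' In the agent-based model a newborn nonstem cell risks spontaneous death
#' (probability `alpha`) before its proliferation draw (probability `p_p`)
#' each hour, so absent any spatial inhibition it dies before its first
#' proliferation attempt with probability
#' `alpha / (alpha + (1 - alpha) * p_p)`. Spatial crowding can only raise
#' the realized value, so this is the lower end of the admissible
#' `alpha_prime` range.
#'
#' @param params A [model_params()] object.
#' @return A probability.
#' @export
implied_alpha_prime <- function(params) {
  with(params, alpha / (alpha + (1 - alpha) * p_p))
}

#' Empirical division-outcome frequencies with vacancy constraints disabled
#'
#' Simulates independent CSC division events under the engine's division
#' kernel and hourly death-then-proliferation rule with unlimited vacancy,
#' following each asymmetric division's nonstem daughter to its death or
#' first division, and tallies the resulting change in the CSC count. The
#' frequencies converge to [branching_probabilities()] evaluated at
#' `alpha_prime = implied_alpha_prime(params)`.
#'
#' @param params A [model_params()] object.
#' @param n_divisions Number of division events to simulate.
#' @param seed Integer seed.
#' @return A tibble with columns `outcome` (-1, 0, +1, +2), `n`, `freq` and
#'   the matching theoretical `prob`.
#' @export
division_outcome_frequencies <- function(params, n_divisions = 1e5,
                                         seed = 1) {
  counts <- .cpp_division_outcomes(par_list(params),
                                   as.integer(n_divisions), as.double(seed))
  pr <- branching_probabilities(params$p_d, params$p_dd, params$p_s,
                                implied_alpha_prime(params))
  tibble(outcome = c(-1L, 0L, 1L, 2L), n = counts,
         freq = counts / n_divisions,
         prob = c(pr$p1, pr$p2, pr$p3, pr$p4))
}

#' Probability of early tumor death by premature founder differentiation
#'
#' Fraction of agent-based replicates, each seeded with a single CSC, in
#' which the founding CSC differentiates before any symmetric division and
#' the resulting all-nonstem population then dies out without a single
#' dedifferentiation event. Each replicate terminates early at extinction,
#' at the first symmetric division, or at the first dedifferentiation, which
#' keeps the full spatial simulation desk-scale. This early-death route is
#' approximately constant (about 0.5%) across plasticity rates under default
#' parameters.
#'
#' @param params A [model_params()] object (the founder capacity is
#'   `params$rho_init`).
#' @param n_reps Number of replicates.
#' @param seed Integer seed; replicate `i` uses stream `i` of the seed.
#' @param max_days Safety horizon per replicate (reaching it counts as no
#'   event; tallied in the `n_capped` attribute).
#' @return The event fraction, with attributes `n_event`, `n_symmetric`,
#'   `n_dedifferentiation`, `n_capped`, `n_reps`.
#' @export
early_death_probability <- function(params, n_reps = 1e4, seed = 1,
                                    max_days = 3650) {
  stopifnot(n_reps >= 1)
  out <- .cpp_early_death_mc(par_list(params), params$rho_init,
                             as.integer(n_reps), max_days * 24,
                             as.double(seed))
  structure(out$n_event / n_reps,
            n_event = out$n_event, n_symmetric = out$n_symmetric,
            n_dedifferentiation = out$n_dedifferentiation,
            n_capped = out$n_capped, n_reps = out$n_reps)
}
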