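#' Model parameters for the tumor growth simulator
#'
#' Bundles the per-cell rates and probabilities of the agent-based model.
#' Defaults are the nominal values of the model's parameter table: founder
#' proliferation capacity `rho_init = 10`, spontaneous nonstem death
#' `alpha = 1%` per hour, symmetric CSC division `p_s = 1%`, differentiation
#' and dedifferentiation `p_d = p_dd = 1%` per division, a proliferation
#' attempt once per day (`p_p = 1/24` per hourly step) and migration
#' `p_m = 15/24` per hourly step (150 um per day at 10 um lattice spacing)
#' when no proliferation is attempted.
#'
#' @param rho_init Non-negative integer; initial proliferation capacity of
#'   nonstem lineages (telomere-length proxy). A nonstem cell with capacity 0
#'   dies at its next mitotic attempt.
#' @param alpha Probability per hourly step of spontaneous nonstem cell death.
#'   CSCs are exempt.
#' @param p_s Probability that a CSC division is symmetric (two CSCs, no
#'   capacity erosion).
#' @param p_d Probability of CSC differentiation at a successful division.
#' @param p_dd Probability of nonstem dedifferentiation at a successful
#'   division; the new CSC keeps its current capacity.
#' @param p_p Probability per hourly step of a proliferation attempt.
#' @param p_m Probability per hourly step of migration, drawn only when no
#'   proliferation was attempted.
#' @param dt_hours Length of one simulation step in hours. The engine is
#'   hourly; only `1` is supported.
#' @param site_um Lattice spacing in micrometers (bookkeeping only).
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(p_d = 0.001, p_dd = 0.001)
#' p
#' @export
model_params <- function(rho_init = 10, alpha = 0.01, p_s = 0.01, p_d = 0.01,
                         p_dd = 0.01, p_p = 1 / 24, p_m = 15 / 24,
                         dt_hours = 1, site_um = 10) {
  if (!is.numeric(rho_init) || length(rho_init) != 1L || is.na(rho_init) ||
      rho_init < 0 || rho_init != round(rho_init)) {
    abort_invalid("`rho_init` must be a non-negative integer.")
  }
  for (nm in c("alpha", "p_s", "p_d", "p_dd", "p_p", "p_m")) {
    check_prob(get(nm), nm)
  }
  if (!identical(as.numeric(dt_hours), 1)) {
    abort_invalid("`dt_hours` is fixed at 1 hour.")
  }
  if (!is.numeric(site_um) || site_um <= 0) {
    abort_invalid("`site_um` must be a positive lattice spacing.")
  }
  structure(
    list(rho_init = as.integer(rho_init), alpha = alpha, p_s = p_s,
         p_d = p_d, p_dd = p_dd, p_p = p_p, p_m = p_m,
         dt_hours = 1, site_um = site_um),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  rho_init: %d   alpha: %g   p_s: %g\n",
              x$rho_init, x$alpha, x$p_s))
  cat(sprintf("  p_d: %g   p_dd: %g\n", x$p_d, x$p_dd))
  cat(sprintf("  p_p: %g /h   p_m: %g /h   (dt = %g h, site = %g um)\n",
              x$p_p, x$p_m, x$dt_hours, x$site_um))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-running all
#' validity checks.
#'
#' @param params A [model_params()] object.
#' @param ... Named fields to replace (e.g. `p_d = 0.1`).
#' @return A `model_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  new <- utils::modifyList(unclass(params), list(...))
  do.call(model_params, new)
}

#' Radiotherapy parameters (linear-quadratic model)
#'
#' Defaults describe a conventional fractionation course: 30 fractions of
#' 2 Gy, one every 24 h, with LQ coefficients a = 0.3859 / Gy and
#' b = 0.01148 / Gy^2, a quiescence radioresistance factor xi = 0.5 applied
#' to cells with no vacant Moore neighbor, and a CSC radioresistance factor
#' lambda = 0.1376.
#'
#' @param dose Dose per fraction in Gy.
#' @param n_fractions Number of fractions.
#' @param interval_h Hours of simulated growth between fractions.
#' @param xi Radioresistance multiplier for quiescent cells, in (0, 1].
#' @param lambda_csc Radioresistance multiplier for CSCs, in (0, 1].
#' @param a,b Linear and quadratic LQ coefficients (1/Gy and 1/Gy^2).
#' @return An object of class `rt_params`.
#' @export
rt_params <- function(dose = 2, n_fractions = 30, interval_h = 24,
                      xi = 0.5, lambda_csc = 0.1376,
                      a = 0.3859, b = 0.01148) {
  if (dose < 0) abort_invalid("`dose` must be non-negative.")
  if (n_fractions < 0 || n_fractions != round(n_fractions)) {
    abort_invalid("`n_fractions` must be a non-negative integer.")
  }
  if (xi <= 0 || xi > 1) abort_invalid("`xi` must lie in (0, 1].")
  if (lambda_csc <= 0 || lambda_csc > 1) {
    abort_invalid("`lambda_csc` must lie in (0, 1].")
  }
  if (a < 0 || b < 0) abort_invalid("`a` and `b` must be non-negative.")
  structure(
    list(dose = dose, n_fractions = as.integer(n_fractions),
         interval_h = interval_h, xi = xi, lambda_csc = lambda_csc,
         a = a, b = b),
    class = "rt_params"
  )
}

#' @export
print.rt_params <- function(x, ...) {
  cat(sprintf("<rt_params> %d x %g Gy every %g h; xi = %g, lambda = %g, a = %g, b = %g\n",
              x$n_fractions, x$dose, x$interval_h, x$xi, x$lambda_csc,
              x$a, x$b))
  invisible(x)
}

# engine-facing list
par_list <- function(params) {
  params[c("alpha", "p_s", "p_d", "p_dd", "p_p", "p_m")]
}
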