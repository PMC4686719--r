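# Fractionated radiotherapy under the linear-quadratic survival model with
# radioresistance modifiers for CSCs (lambda) and quiescent cells (xi).

#' Linear-quadratic surviving fraction
#'
#' Probability that a cell survives a dose `D`:
#' \deqn{SF(D) = \exp(-\xi \lambda (aD + bD^2))}
#' with `xi` applied only to quiescent cells (no vacant Moore neighbor;
#' `xi = 1` otherwise) and `lambda` only to CSCs (`lambda = 1` for nonstem
#' cells). Since both factors are below 1, CSCs and quiescent cells are
#' radioresistant relative to proliferating nonstem cells.
#'
#' @param dose Dose in Gy (non-negative; vectorized).
#' @param is_stem,is_quiescent Logical flags (vectorized).
#' @param rt An [rt_params()] object.
#' @return Survival probabilities in (0, 1].
#' @examples
#' surviving_fraction(2)                      # proliferating CC at 2 Gy
#' surviving_fraction(2, TRUE, TRUE)          # quiescent CSC at 2 Gy
#' @export
surviving_fraction <- function(dose, is_stem = FALSE, is_quiescent = FALSE,
                               rt = rt_params()) {
  if (any(dose < 0)) abort_invalid("`dose` must be non-negative.")
  xi_eff <- ifelse(is_quiescent, rt$xi, 1)
  lam_eff <- ifelse(is_stem, rt$lambda_csc, 1)
  exp(-xi_eff * lam_eff * (rt$a * dose + rt$b * dose^2))
}

#' Apply one radiation fraction to a tumor state
#'
#' Each cell independently survives with its [surviving_fraction()];
#' quiescence is evaluated at irradiation time from the current occupancy
#' pattern. Non-survivors are removed immediately (no mitotic-death delay).
#' Draws use R's RNG: call `set.seed()` for reproducibility.
#'
#' @param state A [tumor_state()].
#' @param rt An [rt_params()] object.
#' @return The surviving [tumor_state()] (time unchanged: the dose is
#'   instantaneous).
#' @export
apply_fraction <- function(state, rt = rt_params()) {
  cells <- state$cells
  if (nrow(cells) == 0) return(state)
  m <- state_to_mask(state, pad = 1)
  cnt <- moore_neighbor_count(m)
  rows <- cells$y - attr(m, "y0") + 1
  cols <- cells$x - attr(m, "x0") + 1
  quiescent <- cnt[cbind(rows, cols)] == 8
  sf <- surviving_fraction(rt$dose, cells$phenotype == "S", quiescent, rt)
  keep <- runif(nrow(cells)) < sf
  tumor_state(cells[keep, ], time_h = state$time_h)
}

#' Simulate a fractionated radiotherapy course with follow-up
#'
#' Alternates `interval_h` hours of simulated growth with one radiation
#' fraction, for `rt$n_fractions` fractions, then continues unperturbed
#' growth for `followup_days`. With `n_fractions = 0` this is identical to
#' continuing the plain simulation with the same seed.
#'
#' @param state Pretreatment [tumor_state()] (e.g. from [grow_to_size()]).
#' @param params A [model_params()] object.
#' @param rt An [rt_params()] object.
#' @param followup_days Days of post-treatment growth.
#' @param seed Integer seed. Growth segments use deterministic sub-streams of
#'   this seed; the survival draws use R's RNG seeded with it.
#' @return An object of class `rt_course`: `$series` (daily `day`,
#'   `n_total`, `n_csc`, `csc_fraction`, `phase` in
#'   `{"pre", "rt", "followup"}`), `$final_state`, `$nadir` (minimum cell
#'   count from treatment start through follow-up) and inputs.
#' @export
run_treatment_course <- function(state, params, rt = rt_params(),
                                 followup_days = 0, seed = 1) {
  stopifnot(inherits(state, "tumor_state"), inherits(rt, "rt_params"))
  set.seed(seed)
  series <- dplyr::bind_cols(series_head(state), tibble(phase = "pre"))
  for (k in seq_len(rt$n_fractions)) {
    out <- run_engine(state, params, hours = rt$interval_h, seed = seed,
                      stream = k, record_every = 0)
    state <- apply_fraction(out$state, rt)
    series <- dplyr::bind_rows(
      series,
      dplyr::bind_cols(series_head(state), tibble(phase = "rt"))
    )
  }
  status <- if (n_cells(state) == 0) "extinct" else "max_hours"
  if (followup_days > 0 && n_cells(state) > 0) {
    out <- run_engine(state, params, hours = followup_days * 24, seed = seed,
                      stream = 0, record_every = 24)
    fu <- dplyr::bind_cols(out$series, tibble(phase = "followup"))
    series <- dplyr::bind_rows(series, fu)
    state <- out$state
    status <- out$status
  } else if (followup_days > 0) {
    # extinct during the course; pad the follow-up horizon with zeros
    last_day <- series$day[nrow(series)]
    fu <- tibble(day = last_day + seq_len(followup_days), n_total = 0L,
                 n_csc = 0L, csc_fraction = NA_real_, phase = "followup")
    series <- dplyr::bind_rows(series, fu)
    status <- "extinct"
  }
  post <- series[series$phase != "pre", ]
  structure(
    list(series = series, final_state = state, status = status,
         nadir = if (nrow(post) > 0) min(post$n_total) else n_cells(state),
         params = params, rt = rt, seed = seed),
    class = "rt_course"
  )
}

#' @export
print.rt_course <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("<rt_course> %d x %g Gy; nadir %d cells; day %.0f: %d cells (%s)\n",
              x$rt$n_fractions, x$rt$dose, x$nadir, last$day, last$n_total,
              x$status))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rt_course <- function(x, ...) x$series

#' @exportS3Method generics::glance
glance.rt_course <- function(x, ...) {
  pre <- x$series$n_total[1]
  last <- x$series[nrow(x$series), ]
  tibble(n_pre = pre, nadir = x$nadir,
         log10_reduction = log10(pre / max(x$nadir, 1)),
         n_final = last$n_total, status = x$status, seed = x$seed)
}
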