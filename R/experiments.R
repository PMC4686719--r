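# Cohort-level experiment runners. Every experiment is bit-reproducible from
# (configuration, master seed): replicate i consumes stream i of the seed.
# Defaults are desk-scale (tens of replicates, ~120-day horizons); the
# published-scale settings (100 replicates, 720 days) are available by
# argument and documented in the methods vignette.

#' Simulate a cohort of independently grown tumors
#'
#' Runs `n_reps` independent simulations from a single founder CSC and
#' collects their daily time series, plus per-day cohort summaries (mean, SD
#' and coefficient of variation of the total count; mean CSC fraction).
#'
#' @inheritParams simulate_tumor
#' @param n_reps Number of replicates.
#' @param days Simulated horizon per replicate.
#' @param max_cells Per-replicate population cap (stops that replicate).
#' @return An object of class `growth_cohort`: `$replicates` (tibble `rep`,
#'   `day`, `n_total`, `n_csc`, `csc_fraction`), `$summary` (per-day mean,
#'   sd, cv, mean CSC fraction), `$outcomes` (one row per replicate with
#'   final status). Following the standard protocol, the per-day summary
#'   considers only successfully grown tumors — replicates that went extinct
#'   within the horizon are excluded from it (all replicates stay in
#'   `$replicates`). `tidy()` returns the replicate series, `glance()` a
#'   one-row summary.
#' @export
run_growth_cohort <- function(params = model_params(), n_reps = 20,
                              days = 120, seed = 1,
                              founder_rho = params$rho_init,
                              max_cells = Inf) {
  sims <- purrr::map(seq_len(n_reps), function(i) {
    state <- init_state(params, founder_rho, "S")
    out <- run_engine(state, params, hours = days * 24, seed = seed,
                      stream = i,
                      target_n = if (is.finite(max_cells)) max_cells else 0)
    list(rep = i, series = dplyr::bind_rows(series_head(state), out$series),
         status = out$status, state = out$state)
  })
  replicates <- purrr::map_dfr(sims, function(s) {
    dplyr::bind_cols(tibble(rep = s$rep), s$series)
  })
  outcomes <- purrr::map_dfr(sims, function(s) {
    last <- s$series[nrow(s$series), ]
    tibble(rep = s$rep, status = s$status, final_day = last$day,
           n_final = last$n_total, n_csc_final = last$n_csc,
           extinct = s$status == "extinct")
  })
  grown <- outcomes$rep[!outcomes$extinct]
  summary <- replicates |>
    dplyr::filter(.data$rep %in% grown) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      mean_n = mean(.data$n_total),
      sd_n = stats::sd(.data$n_total),
      cv_n = ifelse(mean(.data$n_total) > 0,
                    stats::sd(.data$n_total) / mean(.data$n_total), NA_real_),
      mean_csc_fraction = mean(.data$csc_fraction, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(replicates = replicates, summary = summary, outcomes = outcomes,
         params = params, n_reps = n_reps, days = days, seed = seed),
    class = "growth_cohort"
  )
}

#' @export
print.growth_cohort <- function(x, ...) {
  if (nrow(x$summary) == 0) {
    cat(sprintf("<growth_cohort> %d reps x %d days; all replicates extinct\n",
                x$n_reps, x$days))
    return(invisible(x))
  }
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("<growth_cohort> %d reps x %d days; day %.0f mean %0.1f cells (CV %.2f), %d extinct\n",
              x$n_reps, x$days, last$day, last$mean_n, last$cv_n,
              sum(x$outcomes$extinct)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_cohort <- function(x, ...) x$replicates

#' @exportS3Method generics::glance
glance.growth_cohort <- function(x, ...) {
  if (nrow(x$summary) == 0) {
    return(tibble(n_reps = x$n_reps, days = x$days, mean_n_final = NA_real_,
                  cv_n_final = NA_real_, mean_csc_fraction_final = NA_real_,
                  extinct_fraction = 1, seed = x$seed))
  }
  last <- x$summary[nrow(x$summary), ]
  tibble(n_reps = x$n_reps, days = x$days, mean_n_final = last$mean_n,
         cv_n_final = last$cv_n,
         mean_csc_fraction_final = last$mean_csc_fraction,
         extinct_fraction = mean(x$outcomes$extinct), seed = x$seed)
}

#' Spontaneous remission experiment
#'
#' Simulates a cohort of tumors from a single founder CSC of low capacity
#' and reports the fraction that die out within the observation window. The
#' published protocol uses founder capacity 3 with symmetric-division
#' probability 1% or 3% and plasticity 10%.
#'
#' @inheritParams run_growth_cohort
#' @param founder_rho Founder CSC capacity (default 3).
#' @param window_days Observation window in days.
#' @return An object of class `remission_expt` with `$outcomes` (tibble:
#'   `rep`, `extinct`, `end_day`, `n_final`) and `$extinction_fraction`.
#' @export
run_remission_experiment <- function(params = model_params(), n_reps = 20,
                                     founder_rho = 3, window_days = 720,
                                     seed = 1) {
  outcomes <- purrr::map_dfr(seq_len(n_reps), function(i) {
    state <- init_state(params, founder_rho, "S")
    out <- run_engine(state, params, hours = window_days * 24, seed = seed,
                      stream = i, record_every = 0)
    tibble(rep = i, extinct = out$status == "extinct",
           end_day = out$state$time_h / 24, n_final = n_cells(out$state))
  })
  structure(
    list(outcomes = outcomes,
         extinction_fraction = mean(outcomes$extinct),
         params = params, founder_rho = founder_rho,
         window_days = window_days, n_reps = n_reps, seed = seed),
    class = "remission_expt"
  )
}

#' @export
print.remission_expt <- function(x, ...) {
  cat(sprintf("<remission_expt> %d/%d tumors extinct within %d days (rho0 = %d, p_s = %g, p_d = %g)\n",
              sum(x$outcomes$extinct), x$n_reps, x$window_days,
              x$founder_rho, x$params$p_s, x$params$p_d))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.remission_expt <- function(x, ...) x$outcomes

#' @exportS3Method generics::glance
glance.remission_expt <- function(x, ...) {
  tibble(n_reps = x$n_reps, extinction_fraction = x$extinction_fraction,
         window_days = x$window_days, founder_rho = x$founder_rho,
         seed = x$seed)
}

#' Deterministic fixture masks for morphometry
#'
#' Rasterized test shapes: a disk of radius `r`, a solid `n x n` square, a
#' `1 x k` line, or two separated blobs of 5 and 20 pixels.
#'
#' @param shape One of `"disk"`, `"square"`, `"line"`, `"two_blobs"`.
#' @param r Disk radius (sites).
#' @param n Square side (sites).
#' @param k Line length (sites).
#' @return A logical matrix.
#' @examples
#' sum(make_fixture_mask("disk", r = 50))   # ~ pi * 50^2
#' @export
make_fixture_mask <- function(shape = c("disk", "square", "line",
                                        "two_blobs"),
                              r = 50, n = 50, k = 100) {
  shape <- match.arg(shape)
  switch(shape,
    disk = {
      d <- 2L * r + 3L
      c0 <- r + 2L
      xs <- matrix(rep(seq_len(d), each = d), d, d)
      ys <- matrix(rep(seq_len(d), d), d, d)
      (xs - c0)^2 + (ys - c0)^2 <= r^2
    },
    square = {
      m <- matrix(FALSE, n + 2L, n + 2L)
      m[2:(n + 1L), 2:(n + 1L)] <- TRUE
      m
    },
    line = {
      m <- matrix(FALSE, 3L, k + 2L)
      m[2L, 2:(k + 1L)] <- TRUE
      m
    },
    two_blobs = {
      m <- matrix(FALSE, 12L, 20L)
      m[3:7, 3:6] <- TRUE        # 20 px blob
      m[10, 10:14] <- TRUE       # 5 px blob
      m
    }
  )
}
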