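# Simulation drivers over the compiled lattice engine.

# Single engine call; returns new state + raw series + status/events/counters.
run_engine <- function(state, params, hours, seed, stream = 0,
                       record_every = 24, target_n = 0,
                       stop_on_symmetric = FALSE, stop_on_dediff = FALSE,
                       allow = NULL, terminal = NULL) {
  v <- state_vectors(state)
  out <- .cpp_abm_run(v$x, v$y, v$stem, v$rho, par_list(params),
                      start_hour = state$time_h, max_hours = hours,
                      record_every = as.integer(record_every),
                      target_n = target_n,
                      stop_on_symmetric = stop_on_symmetric,
                      stop_on_dediff = stop_on_dediff,
                      allow_mask = allow, terminal_mask = terminal,
                      seed = as.double(seed), stream = as.double(stream))
  series <- tibble(
    day = out$series_t / 24,
    n_total = out$series_n,
    n_csc = out$series_s,
    csc_fraction = ifelse(out$series_n > 0, out$series_s / out$series_n, NA_real_)
  )
  list(state = state_from_engine(out), series = series, status = out$status,
       events = out$events, counters = out$counters)
}

series_head <- function(state) {
  n <- n_cells(state)
  tibble(day = state$time_h / 24, n_total = n, n_csc = n_csc(state),
         csc_fraction = if (n > 0) n_csc(state) / n else NA_real_)
}

new_tumor_sim <- function(series, final_state, status, params, seed,
                          counters = NULL, events = NULL) {
  structure(
    list(series = series, final_state = final_state, status = status,
         params = params, seed = seed, counters = counters, events = events),
    class = "tumor_sim"
  )
}

#' Simulate tumor growth from a single founder cell
#'
#' Runs the hourly agent-based model: cells are visited in a fresh uniformly
#' random order each step; a nonstem cell first risks spontaneous death
#' (probability `alpha`), a surviving cell attempts proliferation with
#' probability `p_p` (dying instead if it is nonstem with exhausted capacity,
#' staying quiescent if it has no vacant Moore neighbor), and otherwise
#' migrates with probability `p_m` to a random vacant Moore neighbor. At a
#' successful division one plasticity draw is made (differentiation for a
#' CSC, dedifferentiation for a CC), after which the division executes under
#' the resulting phenotype's rules; nonstem divisions erode capacity by one
#' in both cells, CSC divisions never erode.
#'
#' The run stops at `days`, at extinction, or when `max_cells` is reached,
#' whichever comes first. Identical seeds give bit-identical results.
#'
#' @param params A [model_params()] object.
#' @param days Number of simulated days.
#' @param founder_rho,founder_phenotype Founder cell specification (defaults:
#'   one CSC with `params$rho_init`).
#' @param seed Integer seed for the simulation's random stream.
#' @param max_cells Stop once the population reaches this size (`Inf` to
#'   disable).
#' @param stop_when Optional predicate `function(state)`; evaluated once per
#'   simulated day, stops the run when it returns `TRUE`. When supplied, the
#'   run is advanced in one-day chunks, which consumes the random stream in a
#'   different (still deterministic) order than an unchunked run.
#' @return A `tumor_sim` object: `$series` (tibble of daily `day`, `n_total`,
#'   `n_csc`, `csc_fraction`), `$final_state`, `$status` (`"max_hours"`,
#'   `"extinct"` or `"target"`), plus event counters.
#' @examples
#' sim <- simulate_tumor(model_params(), days = 30, seed = 1)
#' tail(sim$series)
#' @export
simulate_tumor <- function(params = model_params(), days = 720,
                           founder_rho = params$rho_init,
                           founder_phenotype = "S", seed = 1,
                           max_cells = Inf, stop_when = NULL) {
  state <- init_state(params, founder_rho, founder_phenotype)
  continue_simulation(state, params, days, seed = seed,
                      max_cells = max_cells, stop_when = stop_when)
}

#' Continue a simulation from an existing state
#'
#' @param state A [tumor_state()] to resume from (e.g. a snapshot or the
#'   final state of another run).
#' @inheritParams simulate_tumor
#' @return A `tumor_sim` object; its series starts at the state's current day.
#' @export
continue_simulation <- function(state, params, days, seed = 1,
                                max_cells = Inf, stop_when = NULL) {
  stopifnot(inherits(state, "tumor_state"))
  target <- if (is.finite(max_cells)) max_cells else 0
  series <- series_head(state)
  if (is.null(stop_when)) {
    out <- run_engine(state, params, hours = days * 24, seed = seed,
                      target_n = target)
    series <- dplyr::bind_rows(series, out$series)
    return(new_tumor_sim(series, out$state, out$status, params, seed,
                         out$counters, out$events))
  }
  status <- "max_hours"
  counters <- NULL
  for (d in seq_len(days)) {
    out <- run_engine(state, params, hours = 24, seed = seed, stream = d,
                      target_n = target)
    state <- out$state
    series <- dplyr::bind_rows(series, out$series)
    counters <- accumulate_counters(counters, out$counters)
    if (out$status != "max_hours") { status <- out$status; break }
    if (isTRUE(stop_when(state))) { status <- "stopped"; break }
  }
  new_tumor_sim(series, state, status, params, seed, counters, NULL)
}

accumulate_counters <- function(a, b) {
  if (is.null(a)) return(b)
  Map(`+`, a, b)
}

#' Grow a tumor to a target size
#'
#' Runs the simulator until the population first reaches `target_n` cells.
#' The caller must choose parameters that permit growth: if the tumor goes
#' extinct first, an error of class `stemplast_error_extinct` is raised; if
#' the safety cap `max_days` is hit first, `stemplast_error_timeout`.
#'
#' @inheritParams simulate_tumor
#' @param target_n Positive integer target population size.
#' @param max_days Safety cap on the simulated horizon.
#' @return The first [tumor_state()] with at least `target_n` cells, with the
#'   elapsed time in its `time_h` field.
#' @export
grow_to_size <- function(params, target_n, seed = 1,
                         founder_rho = params$rho_init,
                         founder_phenotype = "S", max_days = 7300) {
  if (!is.numeric(target_n) || target_n < 1) {
    abort_invalid("`target_n` must be a positive integer.")
  }
  state <- init_state(params, founder_rho, founder_phenotype)
  if (n_cells(state) >= target_n) return(state)
  out <- run_engine(state, params, hours = max_days * 24, seed = seed,
                    target_n = target_n)
  if (out$status == "extinct") {
    abort(sprintf("tumor went extinct at day %.1f before reaching %d cells",
                  out$state$time_h / 24, target_n),
          class = "stemplast_error_extinct")
  }
  if (out$status != "target") {
    abort(sprintf("tumor did not reach %d cells within %d days",
                  target_n, max_days),
          class = "stemplast_error_timeout")
  }
  out$state
}

#' @export
print.tumor_sim <- function(x, ...) {
  n <- nrow(x$series)
  last <- x$series[n, ]
  cat(sprintf("<tumor_sim> %s after %.0f days: %d cells (%d CSC)\n",
              x$status, last$day, last$n_total, last$n_csc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tumor_sim <- function(x, ...) x$series

#' @exportS3Method generics::glance
glance.tumor_sim <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  tibble(status = x$status, days = last$day, n_total = last$n_total,
         n_csc = last$n_csc, csc_fraction = last$csc_fraction,
         seed = x$seed)
}
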