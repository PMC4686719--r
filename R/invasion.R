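# Virtual multi-well invasion assay: circular wells connected by narrow
# canals, a founder CSC seeded in the center of the first well, and
# termination when the first CSC enters the blind-ended canal after the last
# well (invasion) or the population dies out (extinction).

#' Geometry of the virtual well plate
#'
#' Default full-scale geometry: five circular wells of 500 um radius (50
#' lattice sites) connected sequentially by canals 100 um wide and 400 um
#' long (10 x 40 sites), with a blind-ended terminal canal of the same
#' dimensions after the last well. `scale` shrinks all dimensions for
#' desk-scale experiments (each scaled dimension is rounded, with a floor of
#' 1 site; canal width keeps a floor of 2 so cells can pass each other).
#'
#' @param n_wells Number of wells.
#' @param well_radius Well radius in lattice sites.
#' @param canal_width,canal_length Canal dimensions in lattice sites.
#' @param scale Scale factor applied to all dimensions.
#' @param terminal_canal Whether a blind-ended terminal canal follows the
#'   last well (required for invasion runs; `FALSE` gives plain wells).
#' @return An object of class `well_plate_geometry`.
#' @export
well_plate_geometry <- function(n_wells = 5, well_radius = 50,
                                canal_width = 10, canal_length = 40,
                                scale = 1, terminal_canal = TRUE) {
  if (n_wells < 1) abort_invalid("`n_wells` must be >= 1.")
  if (scale <= 0) abort_invalid("`scale` must be positive.")
  g <- list(
    n_wells = as.integer(n_wells),
    well_radius = max(1L, as.integer(round(well_radius * scale))),
    canal_width = max(2L, as.integer(round(canal_width * scale))),
    canal_length = max(1L, as.integer(round(canal_length * scale))),
    terminal_canal = isTRUE(terminal_canal)
  )
  structure(g, class = "well_plate_geometry")
}

#' Build the admissible-site mask of a well plate
#'
#' Wells are aligned on a horizontal axis with centers spaced
#' `2 * well_radius + canal_length` apart; canals are centered on the axis.
#' Cells may only occupy admissible sites: division and migration into
#' non-admissible sites are forbidden.
#'
#' @param geom A [well_plate_geometry()].
#' @return A list of class `well_plate`: `allow` and `terminal` logical
#'   matrices (rows = y, cols = x), well `centers` (tibble), and `geom`.
#' @export
build_plate <- function(geom = well_plate_geometry()) {
  stopifnot(inherits(geom, "well_plate_geometry"))
  r <- geom$well_radius; L <- geom$canal_length; wd <- geom$canal_width
  cy <- r + 2L
  cxs <- r + 2L + (seq_len(geom$n_wells) - 1L) * (2L * r + L)
  W <- cxs[geom$n_wells] + r + L + 2L
  H <- 2L * r + 3L
  allow <- matrix(FALSE, H, W)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  for (cx in cxs) {
    allow <- allow | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
  }
  band <- ys >= cy - floor(wd / 2) & ys <= cy + ceiling(wd / 2) - 1L
  for (i in seq_len(geom$n_wells - 1L)) {
    allow <- allow | (band & xs >= cxs[i] & xs <= cxs[i + 1L])
  }
  # blind-ended terminal canal beyond the last well
  last <- cxs[geom$n_wells]
  if (geom$terminal_canal) {
    allow <- allow | (band & xs >= last & xs <= last + r + L)
    terminal <- band & xs > last + r & xs <= last + r + L & allow
  } else {
    terminal <- matrix(FALSE, H, W)
  }
  structure(
    list(allow = allow, terminal = terminal,
         centers = tibble(well = seq_len(geom$n_wells), x = cxs, y = cy),
         geom = geom),
    class = "well_plate"
  )
}

#' Run one virtual invasion assay
#'
#' Seeds a single CSC at the geometric center of the first well and
#' simulates growth restricted to the plate's admissible sites until the
#' first CSC occupies any site of the terminal blind canal (`"INVADED"`),
#' the population dies out (`"EXTINCT"`), or `max_days` elapse
#' (`"CAPPED"`).
#'
#' @param params A [model_params()] object.
#' @param geom A [well_plate_geometry()].
#' @param seed Integer seed.
#' @param founder_rho Founder proliferation capacity.
#' @param max_days Horizon cap.
#' @param .stream Internal replicate stream index.
#' @return A one-row tibble: `seed`, `result`, `day`, `n_final`,
#'   `n_csc_final`, and per-well CSC fractions `csc_frac_w1`, ... (the CSC
#'   share among cells inside each well disk at termination; `NA` for an
#'   empty well).
#' @export
run_invasion_assay <- function(params = model_params(),
                               geom = well_plate_geometry(), seed = 1,
                               founder_rho = params$rho_init,
                               max_days = 3650, .stream = 0) {
  plate <- build_plate(geom)
  if (!geom$terminal_canal) {
    abort_invalid("the invasion assay needs a terminal blind canal.")
  }
  c1 <- plate$centers[1, ]
  founder <- tumor_state(
    tibble(x = c1$x, y = c1$y, phenotype = "S",
           rho = as.integer(founder_rho))
  )
  out <- run_engine(founder, params, hours = max_days * 24, seed = seed,
                    stream = .stream, record_every = 0,
                    allow = plate$allow, terminal = plate$terminal)
  result <- switch(out$status, invaded = "INVADED", extinct = "EXTINCT",
                   "CAPPED")
  cells <- out$state$cells
  r <- plate$geom$well_radius
  fracs <- purrr::map_dbl(seq_len(nrow(plate$centers)), function(i) {
    cw <- plate$centers[i, ]
    inside <- (cells$x - cw$x)^2 + (cells$y - cw$y)^2 <= r^2
    if (!any(inside)) return(NA_real_)
    mean(cells$phenotype[inside] == "S")
  })
  row <- tibble(seed = seed, result = result,
                day = ceiling(out$state$time_h / 24),
                n_final = nrow(cells),
                n_csc_final = sum(cells$phenotype == "S"))
  fr <- as_tibble(setNames(as.list(fracs),
                           paste0("csc_frac_w", seq_along(fracs))))
  dplyr::bind_cols(row, fr)
}

#' Run a cohort of invasion assays
#'
#' @inheritParams run_invasion_assay
#' @param n_reps Number of independent replicates (replicate `i` uses stream
#'   `i` of `seed`).
#' @return A tibble with one row per replicate (see
#'   [run_invasion_assay()]), plus a `rep` column.
#' @export
run_invasion_cohort <- function(params = model_params(), n_reps = 10,
                                geom = well_plate_geometry(), seed = 1,
                                founder_rho = params$rho_init,
                                max_days = 3650) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    dplyr::bind_cols(
      tibble(rep = i),
      run_invasion_assay(params, geom, seed = seed,
                         founder_rho = founder_rho, max_days = max_days,
                         .stream = i)
    )
  })
}
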