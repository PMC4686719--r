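#' Tumor lattice state
#'
#' A `tumor_state` holds the cell list of an on-lattice tumor: one row per
#' cell with integer lattice coordinates, phenotype (`"S"` for a cancer stem
#' cell, `"N"` for a nonstem cancer cell) and remaining proliferation
#' capacity `rho`. At most one cell may occupy a lattice site. The lattice
#' itself is unbounded and expands dynamically during simulation.
#'
#' @param cells A data frame with columns `x`, `y` (integers), `phenotype`
#'   (`"S"`/`"N"`) and `rho` (non-negative integers).
#' @param time_h Elapsed simulated hours.
#' @return An object of class `tumor_state`.
#' @export
tumor_state <- function(cells, time_h = 0) {
  cells <- as_tibble(cells)
  req <- c("x", "y", "phenotype", "rho")
  if (!all(req %in% names(cells))) {
    abort_invalid("`cells` needs columns x, y, phenotype, rho.")
  }
  cells$x <- as.integer(cells$x)
  cells$y <- as.integer(cells$y)
  cells$rho <- as.integer(cells$rho)
  cells$phenotype <- normalize_phenotype(cells$phenotype)
  if (nrow(cells) > 0 && any(cells$rho < 0)) {
    abort_invalid("proliferation capacity `rho` must be non-negative.")
  }
  if (anyDuplicated(cells[c("x", "y")])) {
    abort_invalid("at most one cell per lattice site.")
  }
  structure(
    list(cells = cells[req], time_h = as.numeric(time_h)),
    class = "tumor_state"
  )
}

normalize_phenotype <- function(p) {
  p <- as.character(p)
  p[p %in% c("STEM", "stem", "CSC")] <- "S"
  p[p %in% c("NONSTEM", "nonstem", "CC")] <- "N"
  if (length(p) > 0 && !all(p %in% c("S", "N"))) {
    abort_invalid('phenotype must be "S" (stem) or "N" (nonstem).')
  }
  p
}

#' Initialize a tumor from a single founder cell
#'
#' Places one founder cell at the lattice center (0, 0). The standard
#' simulation protocol seeds a single CSC with full proliferation capacity.
#'
#' @param params A [model_params()] object; supplies the default founder
#'   capacity.
#' @param founder_rho Non-negative integer capacity of the founder.
#' @param founder_phenotype `"S"` (default) or `"N"`.
#' @return A [tumor_state()] with exactly one cell and `time_h = 0`.
#' @examples
#' init_state(model_params())            # one CSC, rho = 10
#' init_state(model_params(), 3, "S")    # one CSC, rho = 3
#' @export
init_state <- function(params = model_params(),
                       founder_rho = params$rho_init,
                       founder_phenotype = "S") {
  if (!is.numeric(founder_rho) || length(founder_rho) != 1L ||
      is.na(founder_rho) || founder_rho < 0 ||
      founder_rho != round(founder_rho)) {
    abort_invalid("`founder_rho` must be a non-negative integer.")
  }
  tumor_state(
    tibble(x = 0L, y = 0L,
           phenotype = normalize_phenotype(founder_phenotype),
           rho = as.integer(founder_rho)),
    time_h = 0
  )
}

#' @export
print.tumor_state <- function(x, ...) {
  n <- nrow(x$cells)
  s <- sum(x$cells$phenotype == "S")
  cat(sprintf("<tumor_state> %d cells (%d CSC, %.1f%%) at t = %g h (day %.1f)\n",
              n, s, if (n > 0) 100 * s / n else 0, x$time_h, x$time_h / 24))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.tumor_state <- function(x, ...) x$cells

#' Number of cells / CSCs in a state
#' @param state A [tumor_state()].
#' @return Integer count.
#' @export
n_cells <- function(state) nrow(state$cells)

#' @rdname n_cells
#' @export
n_csc <- function(state) sum(state$cells$phenotype == "S")

#' CSC fraction of a state
#' @param state A [tumor_state()].
#' @return `n_csc / n_cells`, or `NaN` for an empty state.
#' @export
csc_fraction <- function(state) {
  n <- n_cells(state)
  if (n == 0) return(NaN)
  n_csc(state) / n
}

# cell list <-> engine vectors ----------------------------------------------

state_vectors <- function(state) {
  list(x = state$cells$x, y = state$cells$y,
       stem = as.integer(state$cells$phenotype == "S"),
       rho = state$cells$rho)
}

state_from_engine <- function(out) {
  tumor_state(
    tibble(x = out$cells$x, y = out$cells$y,
           phenotype = out$cells$phenotype, rho = out$cells$rho),
    time_h = out$time_h
  )
}
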