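# Plain-text interchange: cell-list snapshots and time series as CSV, masks
# as CSV 0/1 grids or plain (P2) PGM, simulation configs as YAML or JSON.

#' Read / write cell-list snapshots
#'
#' Snapshots are CSV files with header `x,y,phenotype,rho` (phenotype `S` or
#' `N`, integer lattice coordinates), usable to resume or analyze
#' simulations.
#'
#' @param state A [tumor_state()].
#' @param path File path.
#' @param time_h Elapsed hours to attach to the state on read.
#' @return `read_cell_snapshot()` returns a [tumor_state()];
#'   `write_cell_snapshot()` returns `path` invisibly.
#' @export
write_cell_snapshot <- function(state, path) {
  readr::write_csv(state$cells, path)
  invisible(path)
}

#' @rdname write_cell_snapshot
#' @export
read_cell_snapshot <- function(path, time_h = 0) {
  cells <- readr::read_csv(path, col_types = readr::cols(
    x = readr::col_integer(), y = readr::col_integer(),
    phenotype = readr::col_character(), rho = readr::col_integer()
  ))
  tumor_state(cells, time_h = time_h)
}

#' Read / write daily time series
#'
#' CSV with header `day,n_total,n_csc,csc_fraction`.
#'
#' @param series A tibble as produced by [simulate_tumor()].
#' @param path File path.
#' @return `read_time_series()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_time_series <- function(series, path) {
  readr::write_csv(series[c("day", "n_total", "n_csc", "csc_fraction")], path)
  invisible(path)
}

#' @rdname write_time_series
#' @export
read_time_series <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    day = readr::col_double(), n_total = readr::col_integer(),
    n_csc = readr::col_integer(), csc_fraction = readr::col_double()
  ))
}

#' Read / write binary masks
#'
#' Masks travel as plain-text PGM (P2) images or CSV 0/1 grids; the format
#' is chosen by file extension (`.pgm` vs anything else).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param path File path.
#' @return `read_mask()` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  m <- (mask > 0) * 1L
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "1"), con)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    if (lines[1] != "P2") abort_invalid("only plain (P2) PGM is supported.")
    dims <- scan(text = lines[2], quiet = TRUE)
    vals <- scan(text = paste(lines[-(1:3)], collapse = " "), quiet = TRUE)
    matrix(vals > 0, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  } else {
    as.matrix(utils::read.table(path, sep = ",")) > 0
  }
}

#' Read a simulation configuration file
#'
#' Flat key/value YAML or JSON (by extension) mirroring [model_params()]
#' field names; unknown keys raise an error. Returns a validated
#' `model_params` object; keys supplied in `...` override the file.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param ... Overrides (e.g. from CLI flags).
#' @return A [model_params()] object.
#' @export
read_sim_config <- function(path, ...) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort_invalid("config must be a .yaml/.yml or .json file.")
  }
  known <- names(formals(model_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort_invalid(paste("unknown config keys:", paste(extra, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, list(...))
  do.call(model_params, cfg)
}
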