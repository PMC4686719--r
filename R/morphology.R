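# Mask-based tumor morphometry.
#
# Masks are logical matrices with rows indexing y and columns indexing x.
# Frequent migration detaches single cells from the tumor mass, so the
# periphery is defined on a smoothed mask: each pixel is replaced by the mean
# occupancy of its 8 Moore neighbors and thresholded at 3/8, which removes
# isolated cells and fills vacant sites having 3+ occupied neighbors.

#' Rasterize a tumor state to a binary mask
#'
#' @param state A [tumor_state()].
#' @param pad Empty border width added around the bounding box.
#' @return A logical matrix (rows = y, cols = x) with attributes `x0`, `y0`
#'   giving the lattice coordinates of element `[1, 1]`.
#' @export
state_to_mask <- function(state, pad = 2) {
  cells <- state$cells
  if (nrow(cells) == 0) {
    return(structure(matrix(FALSE, 1, 1), x0 = 0L, y0 = 0L))
  }
  x0 <- min(cells$x) - pad; y0 <- min(cells$y) - pad
  W <- max(cells$x) - x0 + 1 + pad
  H <- max(cells$y) - y0 + 1 + pad
  m <- matrix(FALSE, H, W)
  m[cbind(cells$y - y0 + 1, cells$x - x0 + 1)] <- TRUE
  structure(m, x0 = as.integer(x0), y0 = as.integer(y0))
}

moore_neighbor_count <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m * 1L
  acc <- matrix(0L, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    acc <- acc + p[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  }
  acc
}

#' Smooth a binary mask by Moore-neighborhood averaging
#'
#' Keeps a pixel iff at least 3 of its 8 Moore neighbors are occupied
#' (average occupancy >= 3/8). Vacant pixels with three or more occupied
#' neighbors are included; isolated cells are removed.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical matrix of the same dimensions (attributes preserved).
#' @export
smooth_and_threshold <- function(mask) {
  m <- mask > 0
  out <- moore_neighbor_count(m) >= 3
  attr(out, "x0") <- attr(mask, "x0")
  attr(out, "y0") <- attr(mask, "y0")
  out
}

#' Select large connected regions of a mask
#'
#' Labels the 8-connected components and keeps those with strictly more than
#' `min_size` pixels. The analysis default of `1e4` matches full-scale
#' tumors; tests and small snapshots use smaller values.
#'
#' @param mask Logical matrix.
#' @param min_size Minimum (exclusive) component pixel count.
#' @return An integer matrix labeling the retained regions `1..k` in
#'   decreasing size order, with attribute `sizes`.
#' @export
select_regions <- function(mask, min_size = 1e4) {
  if (min_size < 1) abort_invalid("`min_size` must be >= 1.")
  lab <- .cpp_label_components(mask > 0)
  if (max(lab) == 0) {
    return(structure(lab, sizes = integer(0)))
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes > min_size)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- relab[lab[pos]]
  structure(out, sizes = sizes[keep])
}

#' Area, perimeter and circularity of selected regions
#'
#' The periphery of each region is its traced outer boundary (interior holes
#' are ignored); the perimeter sums the traced steps with orthogonal steps
#' weighted 1 and diagonal steps sqrt(2). Circularity is `4 * pi * A / S^2`,
#' equal to 1 for a perfect circle; the pooled value treats all regions as
#' one shape set (summed areas and perimeters).
#'
#' @param regions Integer label matrix from [select_regions()].
#' @return A one-row tibble (`area`, `perimeter`, `circularity`,
#'   `n_regions`) with a per-region tibble in attribute `regions` and the
#'   traced boundary pixels (matrix of row, col) in attribute `boundary`.
#' @export
circularity_metrics <- function(regions) {
  labs <- sort(unique(regions[regions > 0]))
  if (length(labs) == 0) {
    abort("no regions selected; cannot compute periphery metrics",
          class = "stemplast_error_no_region")
  }
  per_region <- purrr::map_dfr(labs, function(l) {
    tr <- .cpp_trace_boundary(regions, l)
    tibble(region = l, area = sum(regions == l), perimeter = tr$perimeter,
           circularity = 4 * pi * sum(regions == l) / tr$perimeter^2)
  })
  boundary <- do.call(rbind, lapply(labs, function(l) {
    .cpp_trace_boundary(regions, l)$boundary
  }))
  A <- sum(per_region$area); S <- sum(per_region$perimeter)
  structure(
    tibble(area = A, perimeter = S, circularity = 4 * pi * A / S^2,
           n_regions = length(labs)),
    regions = per_region, boundary = boundary
  )
}

#' Fraction of quiescent cells
#'
#' A cell is quiescent when all 8 of its Moore neighbor sites are occupied,
#' i.e. it has no available space to divide or migrate into.
#'
#' @param state A non-empty [tumor_state()].
#' @return Fraction in [0, 1].
#' @examples
#' quiescent_fraction(init_state(model_params()))  # single cell: 0
#' @export
quiescent_fraction <- function(state) {
  if (n_cells(state) == 0) {
    abort("quiescent fraction undefined for an empty state",
          class = "stemplast_error_undefined_fraction")
  }
  m <- state_to_mask(state, pad = 1)
  cnt <- moore_neighbor_count(m)
  mean(cnt[m] == 8)
}

#' CSC fraction near the tumor boundary
#'
#' Dilates the traced tumor periphery by `dilation_px` lattice sites in the
#' four orthogonal directions (a city-block ball, i.e. all sites within L1
#' distance `dilation_px` of the periphery; 20 sites = 200 um at the default
#' spacing) and returns the fraction of all CSCs lying inside the dilated
#' zone.
#'
#' @param state A [tumor_state()] containing at least one CSC.
#' @param dilation_px Dilation radius in lattice sites.
#' @param min_size Region-size cutoff passed to [select_regions()].
#' @return Fraction of CSCs within `dilation_px` of the periphery.
#' @export
boundary_csc_fraction <- function(state, dilation_px = 20, min_size = 1) {
  stem <- state$cells[state$cells$phenotype == "S", ]
  if (nrow(stem) == 0) {
    abort("boundary CSC fraction undefined: no CSC in state",
          class = "stemplast_error_undefined_fraction")
  }
  mask <- state_to_mask(state, pad = dilation_px + 2)
  sm <- smooth_and_threshold(mask)
  regions <- select_regions(sm, min_size)
  met <- circularity_metrics(regions)
  zone <- .cpp_l1_zone(attr(met, "boundary"), nrow(mask), ncol(mask),
                       as.integer(dilation_px))
  rows <- stem$y - attr(mask, "y0") + 1
  cols <- stem$x - attr(mask, "x0") + 1
  mean(zone[cbind(rows, cols)])
}

#' Full morphometry of a tumor state
#'
#' One-stop pipeline: rasterize, smooth and threshold, select regions of
#' more than `min_size` pixels, trace the periphery, and report pooled
#' area/perimeter/circularity together with the quiescent cell fraction and
#' the boundary-proximal CSC fraction. Metrics that are undefined for the
#' given state (no region large enough, no CSC) are returned as `NA` rather
#' than raising.
#'
#' @inheritParams boundary_csc_fraction
#' @param min_size Region-size cutoff (pixels, exclusive).
#' @return A one-row tibble with columns `n_total`, `n_csc`, `area`,
#'   `perimeter`, `circularity`, `n_regions`, `quiescent_fraction`,
#'   `boundary_csc_fraction`.
#' @export
tumor_morphology <- function(state, min_size = 1e4, dilation_px = 20) {
  base <- tibble(n_total = n_cells(state), n_csc = n_csc(state))
  met <- tryCatch({
    mask <- state_to_mask(state, pad = dilation_px + 2)
    regions <- select_regions(smooth_and_threshold(mask), min_size)
    circularity_metrics(regions)
  }, stemplast_error_no_region = function(e) NULL)
  if (is.null(met)) {
    met <- tibble(area = NA_real_, perimeter = NA_real_,
                  circularity = NA_real_, n_regions = 0L)
  }
  qf <- tryCatch(quiescent_fraction(state),
                 stemplast_error_undefined_fraction = function(e) NA_real_)
  bf <- tryCatch(boundary_csc_fraction(state, dilation_px, min_size),
                 stemplast_error_undefined_fraction = function(e) NA_real_,
                 stemplast_error_no_region = function(e) NA_real_)
  dplyr::bind_cols(base, as_tibble(met)[1, ],
                   tibble(quiescent_fraction = qf,
                          boundary_csc_fraction = bf))
}
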