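# Morphometry: smoothing/threshold rule, region selection, circularity,
# quiescence, boundary-proximal CSC fraction.

test_that("smoothing keeps vacant sites with 3+ occupied neighbors and drops isolated cells", {
  g <- matrix(FALSE, 5, 5)
  expect_false(any(smooth_and_threshold(g)))        # empty stays empty

  g1 <- matrix(FALSE, 5, 5); g1[3, 3] <- TRUE
  expect_false(any(smooth_and_threshold(g1)))       # isolated cell removed

  # vacant center pixel with exactly 3 occupied Moore neighbors is kept
  g3 <- matrix(FALSE, 5, 5)
  g3[cbind(c(2, 2, 4), c(2, 4, 3))] <- TRUE
  expect_true(smooth_and_threshold(g3)[3, 3])
  # with only 2 occupied neighbors it is not
  g2 <- matrix(FALSE, 5, 5)
  g2[cbind(c(2, 2), c(2, 4))] <- TRUE
  expect_false(smooth_and_threshold(g2)[3, 3])
})

test_that("smoothing preserves the interior of large solid blocks", {
  m <- make_fixture_mask("square", n = 30)
  sm <- smooth_and_threshold(m)
  expect_true(all(sm[m]))  # every original pixel of a solid block survives
})

test_that("region selection keeps only components above the size cutoff", {
  tb <- make_fixture_mask("two_blobs")
  reg <- select_regions(tb, min_size = 10)
  expect_equal(attr(reg, "sizes"), 20L)
  expect_equal(sum(reg > 0), 20L)
  # cutoff larger than everything: empty selection, metrics refuse
  reg0 <- select_regions(tb, min_size = 1000)
  expect_equal(max(reg0), 0L)
  expect_error(circularity_metrics(reg0), class = "stemplast_error_no_region")
  # a 120 x 120 solid square passes the full-scale 1e4 cutoff
  sq <- make_fixture_mask("square", n = 120)
  reg2 <- select_regions(sq, min_size = 1e4)
  expect_equal(attr(reg2, "sizes"), 14400L)
})

test_that("circularity is ~1 for disks, ~pi/4 for squares, tiny for lines", {
  disk <- circularity_metrics(select_regions(make_fixture_mask("disk", r = 50),
                                             min_size = 10))
  expect_gte(disk$circularity, 0.90)
  expect_lte(disk$circularity, 1.10)
  expect_equal(disk$area, sum(make_fixture_mask("disk", r = 50)))

  sq <- circularity_metrics(select_regions(make_fixture_mask("square", n = 50),
                                           min_size = 10))
  expect_equal(sq$circularity, pi / 4, tolerance = 0.05 / (pi / 4))
  expect_equal(sq$perimeter, 4 * 49, tolerance = 1e-8)

  ln <- circularity_metrics(select_regions(make_fixture_mask("line", k = 100),
                                           min_size = 10))
  expect_lt(ln$circularity, 0.5)
})

test_that("circularity is invariant to translation and 90-degree rotation", {
  m <- make_fixture_mask("disk", r = 20)
  base <- circularity_metrics(select_regions(m, min_size = 10))$circularity
  shifted <- rbind(cbind(matrix(FALSE, nrow(m), 7), m),
                   matrix(FALSE, 5, ncol(m) + 7))
  rotated <- t(m)[ncol(m):1, ]
  for (v in list(shifted, rotated)) {
    cv <- circularity_metrics(select_regions(v, min_size = 10))$circularity
    expect_equal(cv, base, tolerance = 1e-12)
  }
})

test_that("quiescent fraction counts fully enclosed cells", {
  single <- tumor_state(tibble::tibble(x = 0, y = 0, phenotype = "N", rho = 1))
  expect_equal(quiescent_fraction(single), 0)
  expect_equal(quiescent_fraction(block_state(3)), 1 / 9)
  expect_equal(quiescent_fraction(block_state(100)), 98^2 / 100^2)
  empty <- tumor_state(tibble::tibble(x = integer(), y = integer(),
                                      phenotype = character(), rho = integer()))
  expect_error(quiescent_fraction(empty),
               class = "stemplast_error_undefined_fraction")
})

test_that("boundary CSC fraction matches geometry in canonical layouts", {
  # a tumor smaller than the dilated band: every CSC is near the boundary
  small <- disk_state(r = 8, stem_prob = 0.3)
  expect_equal(boundary_csc_fraction(small, dilation_px = 20), 1)

  # all CSCs at the exact center of a large disk: none near the boundary
  g <- expand.grid(x = -50:50, y = -50:50)
  g <- g[g$x^2 + g$y^2 <= 50^2, ]
  phen <- ifelse(g$x == 0 & g$y == 0, "S", "N")
  centered <- tumor_state(tibble::tibble(x = g$x, y = g$y, phenotype = phen,
                                         rho = 5L))
  expect_equal(boundary_csc_fraction(centered, dilation_px = 20), 0)

  # no CSC at all: undefined
  allN <- block_state(5)
  expect_error(boundary_csc_fraction(allN),
               class = "stemplast_error_undefined_fraction")
})

test_that("boundary CSC fraction agrees with a brute-force L1 oracle", {
  st <- disk_state(r = 25, stem_prob = 0.25, seed = 4)
  got <- boundary_csc_fraction(st, dilation_px = 10)

  # oracle: periphery = smoothed-mask pixels with a background 4-neighbor;
  # a CSC counts if its L1 distance to any periphery pixel is <= 10
  mask <- state_to_mask(st, pad = 12)
  sm <- smooth_and_threshold(mask)
  H <- nrow(sm); W <- ncol(sm)
  bnd <- which(sm & !(rbind(sm[-1, ], FALSE) & rbind(FALSE, sm[-H, ]) &
                        cbind(sm[, -1], FALSE) & cbind(FALSE, sm[, -W])),
               arr.ind = TRUE)
  stem <- st$cells[st$cells$phenotype == "S", ]
  rows <- stem$y - attr(mask, "y0") + 1
  cols <- stem$x - attr(mask, "x0") + 1
  near <- vapply(seq_len(nrow(stem)), function(i) {
    min(abs(bnd[, 1] - rows[i]) + abs(bnd[, 2] - cols[i])) <= 10
  }, logical(1))
  expect_equal(got, mean(near), tolerance = 0.05)

  # uniformly mixed disk: roughly the annulus area ratio
  st50 <- disk_state(r = 50, stem_prob = 0.2, seed = 5)
  f <- boundary_csc_fraction(st50, dilation_px = 20)
  expect_gt(f, 0.45)
  expect_lt(f, 0.80)

  # nonincreasing as the dilation radius shrinks
  f5 <- boundary_csc_fraction(st50, dilation_px = 5)
  f10 <- boundary_csc_fraction(st50, dilation_px = 10)
  expect_lte(f5, f10)
  expect_lte(f10, f)
})

test_that("tumor_morphology reports NA where metrics are undefined", {
  sim <- simulate_tumor(model_params(), days = 60, seed = 14)
  row <- tumor_morphology(sim$final_state, min_size = 25, dilation_px = 5)
  expect_equal(nrow(row), 1L)
  expect_gt(row$circularity, 0)
  expect_true(row$quiescent_fraction >= 0 && row$quiescent_fraction <= 1)
  expect_true(row$boundary_csc_fraction >= 0 &&
                row$boundary_csc_fraction <= 1)
  # cutoff too large for this tumor: shape metrics NA, counts intact
  row2 <- tumor_morphology(sim$final_state, min_size = 1e6)
  expect_true(is.na(row2$circularity))
  expect_equal(row2$n_regions, 0L)
  expect_equal(row2$n_total, n_cells(sim$final_state))
})

test_that("masks round-trip through PGM and CSV", {
  m <- make_fixture_mask("disk", r = 9)
  pgm <- withr::local_tempfile(fileext = ".pgm")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_mask(m, pgm)
  write_mask(m, csv)
  expect_equal(unname(read_mask(pgm)), unname(m))
  expect_equal(unname(read_mask(csv)), unname(m))
  expect_equal(readLines(pgm, n = 1), "P2")
})
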