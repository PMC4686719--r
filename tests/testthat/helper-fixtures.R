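# Shared fixtures built in code.

# a solid block of nonstem cells
block_state <- function(n, phenotype = "N", rho = 5L) {
  g <- expand.grid(x = seq_len(n) - 1L, y = seq_len(n) - 1L)
  tumor_state(tibble::tibble(x = g$x, y = g$y, phenotype = phenotype,
                             rho = rho))
}

# a rasterized disk of cells with a reproducible stem subset
disk_state <- function(r = 25, stem_prob = 0.2, seed = 99) {
  g <- expand.grid(x = -r:r, y = -r:r)
  g <- g[g$x^2 + g$y^2 <= r^2, ]
  set.seed(seed)
  phen <- ifelse(runif(nrow(g)) < stem_prob, "S", "N")
  tumor_state(tibble::tibble(x = g$x, y = g$y, phenotype = phen, rho = 10L))
}

# binomial three-sigma band check
within_3se <- function(observed, expected, n) {
  se <- sqrt(expected * (1 - expected) / n)
  abs(observed - expected) <= 3 * se
}
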