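# Independent oracles used across the suite: plain-arithmetic chi-squared,
# ray-casting point-in-polygon, and a seeded random-table source that does
# not go through the package's fixture generator.

chi2_direct <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# random tables with all cells in [lo, hi]
random_cells <- function(count, seed, lo = 1, hi = 60) {
  set.seed(seed)
  replicate(count, sample(lo:hi, 4, replace = TRUE), simplify = FALSE)
}

# classic even-odd ray casting (boundary handled by nudging the ray),
# deliberately a different algorithm from eoi::polygon_contains
pip_raycast <- function(poly, px, py) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}
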