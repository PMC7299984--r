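# Independent brute-force Mann-Kendall oracle: explicit O(n^2) double loop
# for S, run-length tie counting, textbook variance/Z/p formulas. Kept
# deliberately naive and separate from the package implementation.
mk_brute <- function(x, continuity = TRUE, tie_correction = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] > x[i]) s <- s + 1
      if (x[j] < x[i]) s <- s - 1
    }
  }
  var_s <- n * (n - 1) * (2 * n + 5) / 18
  if (tie_correction) {
    runs <- rle(sort(x))$lengths
    for (t in runs[runs > 1]) {
      var_s <- var_s - t * (t - 1) * (2 * t + 5) / 18
    }
  }
  cc <- if (continuity) 1 else 0
  z <- if (s > 0) (s - cc) / sqrt(var_s) else if (s < 0) {
    (s + cc) / sqrt(var_s)
  } else 0
  list(s = s, var_s = var_s, z = z, p_value = min(2 * pnorm(-abs(z)), 1))
}

# Small deterministic scene used across tests.
tiny_scene <- function(..., n_rows = 6, n_cols = 6, years = 2003:2005,
                       n_composites = 12) {
  make_scene(n_rows = n_rows, n_cols = n_cols, years = years,
             n_composites = n_composites, ...)
}
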