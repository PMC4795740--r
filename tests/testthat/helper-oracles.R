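# Independent oracles, deliberately written with naive algorithms so they
# share no code path with the package implementations.

# Edge-repeating mirror of an index into 1..n, by stepwise reflection.
oracle_reflect <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# Dense direct convolution with a normalized Gaussian kernel truncated at
# 4 sigma, reflected boundaries.
oracle_gauss_smooth <- function(y, sigma) {
  n <- length(y)
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (d in seq(-r, r)) {
      s <- s + k[d + r + 1L] * y[oracle_reflect(i + d, n)]
    }
    out[i] <- s
  }
  out
}

# Exhaustive neighbor-comparison peak enumeration: a bin is a peak when it
# is the leftmost bin of a maximal equal-valued run whose neighbors beyond
# the run (where present) are strictly lower, and its value is positive.
oracle_find_peaks <- function(y) {
  n <- length(y)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (y[i] <= 0) next
    if (i > 1L && y[i - 1L] == y[i]) next  # not leftmost of its run
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    left_ok <- i == 1L || y[i - 1L] < y[i]
    right_ok <- j == n || y[j + 1L] < y[i]
    if (left_ok && right_ok) hits <- c(hits, i)
  }
  ord <- order(-y[hits], hits)
  data.frame(bin_index = hits[ord], height = y[hits][ord])
}

# Write a per-cell data.frame to a temporary CSV and return its path.
write_cells_csv <- function(df, path = tempfile(fileext = ".csv"), sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Histogram on the normalized DNA axis with a hand-drawn smoothed curve
# passing through the given (x, y) control points (piecewise linear).
drawn_norm_hist <- function(points_x, points_y, from = 0.4, to = 3.5,
                            bins = 120L) {
  edges <- 2^seq(log2(from), log2(to), length.out = bins + 1L)
  h <- hist_vector(edges, rep(1, bins))
  cen <- bin_centers(h)
  h$smoothed <- approx(points_x, points_y, xout = cen, rule = 2)$y
  h$sigma_bins <- 1.5
  h
}
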