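test_that("build_histogram counts half-open bins with a closed top edge", {
  h <- build_histogram(c(1, 1, 1, 2), bin_edges = c(0.5, 1.5, 2.5))
  expect_equal(h$counts, c(3, 1))
  # value exactly at the top edge lands in the last bin
  h2 <- build_histogram(c(1, 2.5), bin_edges = c(0.5, 1.5, 2.5))
  expect_equal(h2$counts, c(1, 1))
  # interior edges are half-open: the value belongs to the upper bin
  h3 <- build_histogram(c(1.5), bin_edges = c(0.5, 1.5, 2.5))
  expect_equal(h3$counts, c(0, 1))
})

test_that("build_histogram conserves mass and tallies out-of-range values", {
  set.seed(11)
  v <- runif(1000)
  h <- build_histogram(v, bin_edges = seq(0, 1, length.out = 11))
  expect_equal(sum(h$counts), 1000)
  expect_equal(h$n_outside, 0L)
  h2 <- build_histogram(c(v, -1, 2, 5), bin_edges = seq(0, 1, length.out = 11))
  expect_equal(sum(h2$counts), 1000)
  expect_equal(h2$n_outside, 3L)
  expect_equal(sum(h2$counts) + h2$n_outside, 1003)
})

test_that("build_histogram rejects bad input", {
  expect_error(build_histogram(numeric(0)), "empty")
  expect_error(build_histogram(1:3, bin_edges = c(1, 1, 2)), "increasing")
  expect_error(build_histogram(c(1, NA)), "finite")
})

test_that("smoothing keeps constants fixed, is symmetric and conserves mass", {
  h <- smooth_histogram(hist_vector(0:10, rep(4, 10)))
  expect_equal(h$smoothed, rep(4, 10), tolerance = 1e-12)
  expect_equal(h$counts, rep(4, 10))  # raw counts untouched

  imp <- smooth_histogram(hist_vector(0:5, c(0, 0, 10, 0, 0)))
  expect_equal(imp$smoothed, rev(imp$smoothed), tolerance = 1e-12)
  expect_equal(which.max(imp$smoothed), 3L)

  set.seed(21)
  for (i in 1:20) {
    y <- rpois(sample(5:80, 1), 15)
    if (sum(y) == 0) y[1] <- 1
    sm <- smooth_histogram(hist_vector(seq_len(length(y) + 1), y),
                           sigma_bins = runif(1, 0.4, 4))$smoothed
    expect_lte(abs(sum(sm) - sum(y)) / sum(y), 0.005)
  }
})

test_that("smoothing commutes with uniform scaling of the counts", {
  set.seed(31)
  y <- rpois(40, 8)
  e <- 0:40
  a <- smooth_histogram(hist_vector(e, y), 1.5)$smoothed
  b <- smooth_histogram(hist_vector(e, 3.5 * y), 1.5)$smoothed
  expect_equal(b, 3.5 * a, tolerance = 1e-12)
})

test_that("smoothing validates its arguments", {
  expect_error(smooth_histogram(hist_vector(0:10, rep(1, 10)), -1), "positive")
  expect_error(smooth_histogram(hist_vector(0:2, c(1, 2))), "3 bins")
})

test_that("find_peaks orders by height with plateau and tie rules", {
  h <- hist_vector(0:5, c(1, 5, 2, 7, 3))
  pk <- find_peaks(h)
  expect_equal(pk$bin_index, c(4L, 2L))
  expect_equal(pk$height, c(7, 5))
  expect_equal(pk$location, bin_centers(h)[c(4, 2)])

  # a whole-array plateau is one peak at its leftmost bin
  expect_equal(find_peaks(hist_vector(0:3, c(3, 3, 3)))$bin_index, 1L)
  # equal-height peaks: lower bin index first
  expect_equal(find_peaks(hist_vector(0:3, c(7, 2, 7)))$bin_index, c(1L, 3L))
  # zero-height bins never qualify
  expect_equal(nrow(find_peaks(hist_vector(0:3, c(0, 0, 0)))), 0L)
})

test_that("find_peaks mirrors on a reversed histogram", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    y <- rpois(n, 3) + runif(n, 0, 0.01)  # jitter: no plateaus, clean mirror
    f <- find_peaks(hist_vector(seq_len(n + 1), y))
    r <- find_peaks(hist_vector(seq_len(n + 1), rev(y)))
    expect_setequal(n + 1L - r$bin_index, f$bin_index)
  }
})
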