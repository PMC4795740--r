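test_that("to_log2_dna transforms and applies the exclusion policy", {
  expect_equal(as.numeric(to_log2_dna(c(2, 4, 8))), c(1, 2, 3))
  expect_equal(as.numeric(to_log2_dna(1)), 0)

  v <- c(rep(100, 9999), 0)
  expect_warning(l2 <- to_log2_dna(v), "excluded 1 cell")
  expect_length(l2, 9999L)
  expect_equal(attr(l2, "n_excluded"), 1L)

  expect_error(to_log2_dna(c(0, 0, 100)), "corrupt")
})

test_that("normalization anchors 2N at 1 and 4N at 2", {
  pk <- reference_peaks(100, 200)
  expect_equal(normalize_dna_content(c(100, 200, 400), pk), c(1, 2, 4))

  # sub-proportional staining still hits both anchors exactly
  pk18 <- reference_peaks(100, 180)
  expect_equal(normalize_dna_content(c(100, 180), pk18), c(1, 2))
  # affine-in-log2: the geometric mean of the anchors maps to sqrt(2)
  expect_equal(normalize_dna_content(sqrt(100 * 180), pk18), sqrt(2),
               tolerance = 1e-12)
  # strictly increasing
  v <- seq(40, 500, length.out = 50)
  expect_true(all(diff(normalize_dna_content(v, pk18)) > 0))
  # proportional staining reduces to x / p2N
  expect_equal(normalize_dna_content(c(50, 150, 321), pk),
               c(50, 150, 321) / 100)

  expect_error(reference_peaks(200, 100), "p4N > p2N")
  expect_error(normalize_dna_content(c(-1, 100), pk), "positive")
})

test_that("default gates are the five canonical classes", {
  g <- default_gates()
  expect_equal(nrow(g), 5L)
  expect_equal(g$name, c("<2N", "2N", "S", "4N", ">4N"))
  expect_equal(g$upper[1:4], c(0.75, 1.25, 1.75, 2.5))
  expect_equal(g$lower, c(0, 0.75, 1.25, 1.75, 2.5))
  expect_equal(g$upper[5], Inf)

  # boundary membership: a value at a threshold joins the upper class
  res <- apply_gates(c(1.0, 0.75, 3.0), g)
  expect_equal(res$counts[["2N"]], 2L)    # 1.0 and the 0.75 boundary
  expect_equal(res$counts[[">4N"]], 1L)
  expect_error(default_gates(c(1.25, 0.75, 1.75, 2.5)), "increasing")
})

test_that("reference peaks are found on a synthetic bimodal control", {
  sp <- plate_spec(list(well_spec(
    "A01", n_cells = 5000,
    class_weights = c(0.02, 0.60, 0.05, 0.30, 0.03))), seed = 7)
  v <- generate_plate(sp)$cells$IntegratedIntensity
  l2 <- to_log2_dna(v)
  edges <- dna_bin_edges(l2)
  bw <- diff(edges)[1]
  ch <- smooth_histogram(build_histogram(l2, edges))
  pk <- detect_reference_peaks(ch)
  # detected centers within one bin of the generator's 100 / 200
  expect_lt(abs(log2(pk$p2N) - log2(100)), bw)
  expect_lt(abs(log2(pk$p4N) - log2(200)), bw)
})

test_that("a unimodal control is a reference-detection error", {
  set.seed(13)
  l2 <- rnorm(3000, 7, 0.1)
  ch <- smooth_histogram(build_histogram(l2, dna_bin_edges(l2)))
  expect_error(detect_reference_peaks(ch), "manual")
  expect_error(detect_reference_peaks(build_histogram(l2, dna_bin_edges(l2))),
               "smoothed")
})

test_that("a tall sub-G1 debris peak is never mistaken for 4N", {
  # debris taller than G2 but left of G1: 4N must come from the right
  set.seed(17)
  n <- 6000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.30, 0.55, 0.15))
  centers <- c(40, 100, 200)
  v <- centers[comp] * exp(rnorm(n, 0, 0.05))
  l2 <- to_log2_dna(v)
  ch <- smooth_histogram(build_histogram(l2, dna_bin_edges(l2)))
  pk <- detect_reference_peaks(ch)
  bw <- diff(ch$bin_edges)[1]
  expect_lt(abs(log2(pk$p2N) - log2(100)), bw)
  expect_lt(abs(log2(pk$p4N) - log2(200)), bw)
  expect_gt(pk$p4N, pk$p2N)
})

test_that("adaptation moves boundaries to drawn valleys and clamps them", {
  # hand-drawn smoothed curves with peaks in the 2N, S and 4N regions
  shifted <- drawn_norm_hist(
    c(0.4, 1.0, 1.2, 1.45, 1.68, 1.95, 3.5),
    c(0,   100, 20,  60,   10,   90,   0))
  g <- adapt_gates(shifted, default_gates())
  bw <- diff(shifted$bin_edges)
  bw_at <- bw[findInterval(1.68, shifted$bin_edges)]
  expect_lt(abs(g$upper[3] - 1.68), bw_at)       # S/4N boundary at the valley
  expect_equal(g$name, c("<2N", "2N", "S", "4N", ">4N"))
  expect_true(all(diff(g$upper[1:4]) > 0))

  clamped <- drawn_norm_hist(
    c(0.4, 1.0, 1.17, 1.30, 1.40, 2.0, 3.5),
    c(0,   100, 40,   60,   10,   90,  0))
  g2 <- adapt_gates(clamped, default_gates())
  expect_equal(g2$upper[3], 1.6)                 # 1.75 - 0.15, clamp binds
})

test_that("adaptation is conservative on control-shaped histograms", {
  sp <- plate_spec(list(well_spec("A01", n_cells = 5000)), seed = 7)
  v <- generate_plate(sp)$cells$IntegratedIntensity
  l2 <- to_log2_dna(v)
  edges <- dna_bin_edges(l2)
  pk <- detect_reference_peaks(smooth_histogram(build_histogram(l2, edges)))
  nv <- normalize_dna_content(v, pk)
  # the pipeline's plate-wide bins, transformed to the normalized axis
  nedges <- 2^((edges - log2(pk$p2N)) / (log2(pk$p4N) - log2(pk$p2N)))
  wh <- smooth_histogram(build_histogram(nv, nedges))
  g0 <- default_gates()
  g <- adapt_gates(wh, g0)
  # no S-region local maximum on a control: 2N/S and S/4N stay put
  expect_equal(g$upper[2:3], g0$upper[2:3])
  # any moved outer boundary stays inside the clamp and changes no cell
  expect_true(all(abs(g$upper[1:4] - g0$upper[1:4]) <= 0.15 + 1e-9))
  expect_equal(classify_cells(nv, g)$class_counts,
               classify_cells(nv, g0)$class_counts)
})

test_that("adaptation falls back to control gates without peaks", {
  flat <- hist_vector(2^seq(log2(0.4), log2(3.5), length.out = 61),
                      rep(0, 60))
  flat$smoothed <- rep(0, 60)
  g0 <- default_gates()
  expect_identical(adapt_gates(flat, g0), g0)
  expect_error(adapt_gates(hist_vector(0:10, rep(1, 10)), g0), "smoothed")
})

test_that("classification partitions every cell into one class", {
  g <- default_gates()
  prof <- classify_cells(c(0.5, 1.0, 1.5, 2.0, 3.0), g, "A01")
  expect_equal(unname(prof$class_counts), rep(1L, 5))
  expect_equal(unname(prof$class_fractions), rep(0.2, 5))
  expect_equal(sum(prof$class_fractions), 1, tolerance = 1e-9)

  empty <- classify_cells(numeric(0), g)
  expect_true(empty$zero_cells)
  expect_equal(unname(empty$class_counts), rep(0L, 5))
  expect_equal(unname(empty$class_fractions), rep(0, 5))

  # non-covering gates are rejected up front
  expect_error(classify_cells(1, make_gates(data.frame(
    name = "mid", lower = 1, upper = 2))), "cover")
})

test_that("classification recovers known class probabilities", {
  set.seed(23)
  probs <- c(0.05, 0.55, 0.15, 0.20, 0.05)
  n <- 10000
  comp <- sample(1:5, n, replace = TRUE, prob = probs)
  centers <- c(0.5, 1, sqrt(2), 2, 4)
  nv <- centers[comp] * 2^rnorm(n, 0, 0.07)
  prof <- classify_cells(nv, default_gates())
  expect_equal(prof$cell_count, n)
  expect_lt(max(abs(prof$class_fractions - probs)), 0.02)
})
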