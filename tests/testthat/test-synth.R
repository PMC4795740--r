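test_that("well and plate specs validate their inputs", {
  expect_error(well_spec("A01", class_weights = c(0.5, 0.5, 0, 0, 0.5)),
               "summing to 1")
  expect_error(well_spec("A01", n_cells = -1), ">= 0")
  expect_error(plate_spec(list(well_spec("A01"), well_spec("A01"))),
               "unique")
})

test_that("a zero-cell well yields zero rows and all-zero truth", {
  pl <- generate_plate(plate_spec(list(well_spec("A01", n_cells = 0)),
                                  seed = 3))
  expect_equal(nrow(pl$cells), 0L)
  expect_equal(pl$truth$n_cells, 0L)
  expect_equal(sum(as.numeric(pl$truth[1, grep("^count_",
                                               names(pl$truth))])), 0)
})

test_that("generation is byte-identical under a fixed seed", {
  sp <- preset_plate(n_cells = 200, seed = 99)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_plate(generate_plate(sp), d1)
  write_plate(generate_plate(sp), d2)
  expect_identical(readLines(file.path(d1, "cells.csv")),
                   readLines(file.path(d2, "cells.csv")))
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  # a different seed gives a different byte stream
  sp2 <- preset_plate(n_cells = 200, seed = 100)
  write_plate(generate_plate(sp2), d3)
  expect_false(identical(readLines(file.path(d1, "cells.csv")),
                         readLines(file.path(d3, "cells.csv"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(555)
  a <- runif(1)
  set.seed(555)
  invisible(generate_plate(plate_spec(list(well_spec("A01", n_cells = 10)),
                                      seed = 1)))
  expect_identical(runif(1), a)
})

test_that("presets encode the treatment archetypes on the simplex", {
  lib <- preset_plates()
  expect_named(lib, c("control", "s_arrest", "g2m_arrest", "stress",
                      "crosslinker"))
  for (p in lib) {
    expect_equal(sum(p$class_weights), 1, tolerance = 1e-9)
    expect_true(all(p$class_weights >= 0))
  }
  w <- lib$control$class_weights
  expect_gt(w[2], w[4])                       # control: 2N above 4N
  g <- lib$g2m_arrest$class_weights
  expect_equal(which.max(g), 4L)              # G2/M arrest: 4N dominant
  expect_gt(lib$s_arrest$class_weights[3], w[3])  # S arrest piles up S mass
  expect_gt(lib$stress$class_weights[1], w[1])    # stress raises sub-G1
})

test_that("realized fractions converge to nominal weights at large n", {
  w <- c(0.02, 0.60, 0.13, 0.22, 0.03)
  pl <- generate_plate(plate_spec(list(
    well_spec("A01", n_cells = 50000, class_weights = w)), seed = 12))
  fr <- as.numeric(pl$truth[1, grep("^frac_", names(pl$truth))])
  expect_lt(max(abs(fr - w)), 0.01)
})

test_that("the full cell-cycle pipeline recovers realized ground truth", {
  sp <- plate_spec(list(well_spec("A01", "DMSO", 5000,
                                  c(0.02, 0.60, 0.13, 0.22, 0.03))),
                   seed = 41)
  pl <- generate_plate(sp)
  d <- tempfile()
  paths <- write_plate(pl, d)
  res <- suppressMessages(
    run_profile(run_config(paths[["cells"]], gating_mode = "fixed")))
  got <- as.numeric(res$table[res$table$well == "A01",
                              grep("^frac_", names(res$table))])
  truth <- as.numeric(pl$truth[1, grep("^frac_", names(pl$truth))])
  expect_lt(max(abs(got - truth)), 0.02)
})

test_that("row-wise well labels follow plate geometry", {
  expect_equal(wellpop:::well_labels_rowwise(3), c("A01", "A02", "A03"))
  expect_equal(wellpop:::well_labels_rowwise(13)[13], "B01")
})
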