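# Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic well
#'
#' A well is a five-component mixture over the cell-cycle classes
#' `<2N, 2N, S, 4N, >4N`. Component intensity centers sit at
#' `intensity_2N * c(0.5, 1, sqrt(r), r, 2 r)` with `r = stain_ratio_4N`
#' (the 4N/2N intensity ratio, 2 for proportional staining): the S center
#' is the geometric mean of the 2N and 4N centers, and the `<2N` / `>4N`
#' debris and polyploid stand-ins sit at half the 2N and twice the 4N
#' center — synthetic conventions, not biology. Each cell draws a component
#' by `class_weights` and multiplies its center by log-normal noise with
#' the given coefficient of variation (median-centered, so the component
#' mode stays at the center).
#'
#' @param well_label e.g. `"A01"`.
#' @param treatment_label treatment text label.
#' @param n_cells number of cells (>= 0).
#' @param class_weights 5 non-negative weights summing to 1.
#' @param intensity_2N center of the 2N component, intensity units.
#' @param stain_ratio_4N 4N/2N center ratio; set below 2 to emulate
#'   sub-proportional staining.
#' @param cv per-component multiplicative coefficient of variation.
#' @return object of class `well_spec`.
#' @export
well_spec <- function(well_label, treatment_label = "DMSO", n_cells = 2000L,
                      class_weights = c(0.02, 0.60, 0.13, 0.22, 0.03),
                      intensity_2N = 100, stain_ratio_4N = 2, cv = 0.05) {
  class_weights <- as.numeric(class_weights)
  if (length(class_weights) != 5L || any(class_weights < 0) ||
      abs(sum(class_weights) - 1) > 1e-6) {
    stop("`class_weights` must be 5 non-negative numbers summing to 1",
         call. = FALSE)
  }
  if (n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  if (intensity_2N <= 0 || stain_ratio_4N <= 1 || cv <= 0) {
    stop("need intensity_2N > 0, stain_ratio_4N > 1, cv > 0", call. = FALSE)
  }
  structure(list(well_label = as.character(well_label),
                 treatment_label = as.character(treatment_label),
                 n_cells = as.integer(n_cells),
                 class_weights = class_weights,
                 intensity_2N = intensity_2N,
                 stain_ratio_4N = stain_ratio_4N,
                 cv = cv),
            class = "well_spec")
}

#' Specification of a synthetic plate
#'
#' @param wells list of [well_spec()]s with unique well labels.
#' @param seed integer seed making the plate reproducible.
#' @return object of class `plate_spec`.
#' @export
plate_spec <- function(wells, seed = 1L) {
  stopifnot(is.list(wells), length(wells) > 0L)
  labs <- vapply(wells, function(w) w$well_label, character(1))
  if (anyDuplicated(labs)) {
    stop("well labels must be unique within a plate", call. = FALSE)
  }
  structure(list(wells = wells, seed = as.integer(seed)),
            class = "plate_spec")
}

#' Generate a synthetic per-cell plate with known ground truth
#'
#' Draws every cell of every well from its [well_spec()] mixture,
#' deterministically under the plate seed. The ground-truth table records
#' the *realized* per-well component counts (what was actually drawn, not
#' the nominal weights), which is the exact oracle for recovery tests.
#'
#' @param spec a [plate_spec()].
#' @return object of class `synthetic_plate`: list with `cells` (data.frame
#'   `Well`, `Treatment`, `IntegratedIntensity` — the schema
#'   [read_measurements()] expects), `truth` (per-well realized class
#'   counts and fractions) and `spec`.
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  classes <- CELL_CYCLE_CLASSES
  with_seed(spec$seed, {
    cells <- list()
    truth <- list()
    for (w in spec$wells) {
      n <- w$n_cells
      comp <- if (n > 0L) {
        sample.int(5L, n, replace = TRUE, prob = w$class_weights)
      } else integer(0)
      r <- w$stain_ratio_4N
      centers <- w$intensity_2N * c(0.5, 1, sqrt(r), r, 2 * r)
      sdlog <- sqrt(log(1 + w$cv^2))
      intensity <- if (n > 0L) {
        centers[comp] * exp(stats::rnorm(n, 0, sdlog))
      } else numeric(0)
      cells[[length(cells) + 1L]] <- data.frame(
        Well = rep(w$well_label, n),
        Treatment = rep(w$treatment_label, n),
        IntegratedIntensity = intensity,
        stringsAsFactors = FALSE)
      counts <- tabulate(comp, nbins = 5L)
      truth[[length(truth) + 1L]] <- data.frame(
        well = w$well_label, treatment = w$treatment_label, n_cells = n,
        as.list(stats::setNames(counts, paste0("count_", classes))),
        as.list(stats::setNames(
          if (n > 0L) counts / n else rep(0, 5L),
          paste0("frac_", classes))),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    structure(list(cells = do.call(rbind, cells),
                   truth = do.call(rbind, truth),
                   spec = spec),
              class = "synthetic_plate")
  })
}

#' Write a synthetic plate to disk
#'
#' Emits `cells.csv` (per-cell table readable by [read_measurements()]) and
#' `truth.csv` (realized ground truth) into a directory. Output is
#' byte-identical across runs for the same plate.
#'
#' @param plate a [generate_plate()] result.
#' @param dir output directory, created if missing.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "synthetic_plate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells_path <- file.path(dir, "cells.csv")
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(plate$cells, cells_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(plate$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(cells = cells_path, truth = truth_path))
}

#' Treatment archetype presets
#'
#' Named class-weight presets emulating common cell-cycle perturbation
#' archetypes on a screening plate: an unperturbed control (bimodal, 2N
#' dominant), an S-phase arrest (mass between the 2N and 4N peaks), a G2/M
#' arrest (4N dominant), an osmotic-stress profile (elevated sub-G1) and a
#' DNA-crosslinker profile (S/G2 accumulation). The weight values are
#' illustrative synthetic conventions chosen to look like typical screens,
#' not measured data.
#'
#' @return named list; each entry has `treatment` (a plausible label) and
#'   `class_weights`.
#' @export
preset_plates <- function() {
  list(
    control = list(treatment = "DMSO",
                   class_weights = c(0.02, 0.60, 0.13, 0.22, 0.03)),
    s_arrest = list(treatment = "Aphidicolin",
                    class_weights = c(0.03, 0.42, 0.40, 0.12, 0.03)),
    g2m_arrest = list(treatment = "Nocodazole",
                      class_weights = c(0.03, 0.12, 0.13, 0.60, 0.12)),
    stress = list(treatment = "NaCl",
                  class_weights = c(0.12, 0.48, 0.15, 0.20, 0.05)),
    crosslinker = list(treatment = "Cisplatin",
                       class_weights = c(0.05, 0.25, 0.35, 0.30, 0.05))
  )
}

#' Build a preset demonstration plate
#'
#' A compact plate with `n_control` control wells (row A) followed by
#' `wells_per_preset` wells of each requested preset archetype, filled
#' row-wise from `A01`.
#'
#' @param presets preset names from [preset_plates()].
#' @param n_control number of control (DMSO) wells.
#' @param wells_per_preset wells per treatment archetype.
#' @param n_cells cells per well.
#' @param seed plate seed.
#' @param ... passed to every [well_spec()] (e.g. `stain_ratio_4N`, `cv`).
#' @return a [plate_spec()].
#' @export
preset_plate <- function(presets = c("s_arrest", "g2m_arrest", "stress",
                                     "crosslinker"),
                         n_control = 2L, wells_per_preset = 1L,
                         n_cells = 2000L, seed = 1L, ...) {
  lib <- preset_plates()
  unknown <- setdiff(presets, names(lib))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown preset(s): %s; available: %s",
                 paste(sQuote(unknown), collapse = ", "),
                 paste(sQuote(names(lib)), collapse = ", ")), call. = FALSE)
  }
  n_wells <- n_control + length(presets) * wells_per_preset
  labels <- well_labels_rowwise(n_wells)
  wells <- list()
  k <- 0L
  for (i in seq_len(n_control)) {
    k <- k + 1L
    wells[[k]] <- well_spec(labels[k], lib$control$treatment, n_cells,
                            lib$control$class_weights, ...)
  }
  for (p in presets) {
    for (i in seq_len(wells_per_preset)) {
      k <- k + 1L
      wells[[k]] <- well_spec(labels[k], lib[[p]]$treatment, n_cells,
                              lib[[p]]$class_weights, ...)
    }
  }
  plate_spec(wells, seed = seed)
}

# Row-wise 96-well labels A01, A02, ...; spills to row B etc.
well_labels_rowwise <- function(n, cols = 12L) {
  stopifnot(n >= 1L, n <= 16L * 24L)
  i <- seq_len(n) - 1L
  sprintf("%s%02d", LETTERS[i %/% cols + 1L], i %% cols + 1L)
}
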