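#' Run configuration
#'
#' Validated bundle of everything one profiling run needs. Values follow
#' the precedence CLI flags > YAML config file > these defaults.
#'
#' @param input path to one per-cell CSV file.
#' @param well_column,treatment_column,measurement_column CSV header names.
#' @param control_treatment control treatment label (e.g. `"DMSO"`), or
#'   `NULL` when selecting controls by `control_wells`.
#' @param control_wells explicit control well labels.
#' @param gating_mode `"adaptive"` (per-well valley adjustment for treated
#'   wells), `"fixed"` (control gates everywhere) or `"manual"`
#'   (user-supplied gates on the raw measurement axis).
#' @param manual_gates a [make_gates()] set, required for manual mode.
#' @param thresholds four interior cell-cycle boundaries.
#' @param sigma Gaussian smoothing width in bins.
#' @param adapt_clamp maximum adaptive boundary displacement.
#' @param bins histogram bin count.
#' @param delimiter CSV field separator.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param verbose print per-well peak/gate diagnostics.
#' @return object of class `run_config`.
#' @export
run_config <- function(input,
                       well_column = "Well",
                       treatment_column = "Treatment",
                       measurement_column = "IntegratedIntensity",
                       control_treatment = "DMSO",
                       control_wells = NULL,
                       gating_mode = c("adaptive", "fixed", "manual"),
                       manual_gates = NULL,
                       thresholds = c(0.75, 1.25, 1.75, 2.5),
                       sigma = 1.5,
                       adapt_clamp = 0.15,
                       bins = 64L,
                       delimiter = ",",
                       out_dir = NULL,
                       verbose = FALSE) {
  gating_mode <- match.arg(gating_mode)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    stop("thresholds not increasing: need 4 strictly increasing values",
         call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (adapt_clamp < 0) stop("`adapt_clamp` must be >= 0", call. = FALSE)
  if (bins < 3L) stop("`bins` must be at least 3", call. = FALSE)
  if (gating_mode == "manual" && !inherits(manual_gates, "gate_set")) {
    stop("manual gating mode needs `manual_gates` (see make_gates())",
         call. = FALSE)
  }
  structure(list(input = input, well_column = well_column,
                 treatment_column = treatment_column,
                 measurement_column = measurement_column,
                 control_treatment = control_treatment,
                 control_wells = control_wells,
                 gating_mode = gating_mode, manual_gates = manual_gates,
                 thresholds = thresholds, sigma = sigma,
                 adapt_clamp = adapt_clamp, bins = as.integer(bins),
                 delimiter = delimiter, out_dir = out_dir,
                 verbose = verbose),
            class = "run_config")
}

#' Load a run configuration from YAML with overrides
#'
#' Reads a YAML mapping whose keys are [run_config()] argument names and
#' merges explicit overrides on top (flag > file > default precedence).
#'
#' @param path YAML config file.
#' @param ... overrides passed to [run_config()].
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s",
                 paste(sQuote(unknown), collapse = ", ")), call. = FALSE)
  }
  do.call(run_config, cfg)
}

#' Run the full per-well profiling workflow
#'
#' End-to-end pipeline for one plate: read the per-cell table, aggregate by
#' well, pool the control wells, derive plate-wide histogram edges from the
#' pooled control, then either run the DNA-content cell-cycle analysis
#' (log2 transform, smoothing, 2N/4N peak detection, normalization,
#' five-class gating — adaptive or fixed) or apply manual gates on the raw
#' measurement axis. Writes `profiles.csv` under `out_dir` when given.
#'
#' In adaptive mode only wells whose treatment differs from the control
#' selector are adapted; control wells (and the pooled control record)
#' always use the control gates, so on a control-only plate adaptive and
#' fixed gating coincide exactly.
#'
#' @param config a [run_config()].
#' @return list with `records` (per-well records as used by
#'   [write_profiles()] and [plate_grid_figure()]), `table` (the written
#'   data.frame), `peaks` (reference peaks, cell-cycle modes only),
#'   `gates` (control gate set), `gates_by_well` (gates actually applied),
#'   `bin_edges` and `profile_path`.
#' @export
run_profile <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ct <- read_measurements(config$input, config$well_column,
                          config$treatment_column,
                          config$measurement_column,
                          delimiter = config$delimiter)
  pops <- group_by_well(ct)
  ctrl <- pool_controls(pops, treatment = config$control_treatment,
                        wells = config$control_wells)
  if (config$gating_mode == "manual") {
    out <- profile_manual(pops, ctrl, config)
  } else {
    out <- profile_cellcycle(pops, ctrl, config)
  }
  out$profile_path <- NULL
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                                recursive = TRUE)
    path <- file.path(config$out_dir, "profiles.csv")
    out$table <- write_profiles(path, out$records)
    out$profile_path <- path
  } else {
    tmp <- tempfile(fileext = ".csv")
    out$table <- write_profiles(tmp, out$records)
    unlink(tmp)
  }
  out
}

# DNA-content cell-cycle branch: control-anchored normalization and
# five-class gating, fixed or per-well adaptive.
profile_cellcycle <- function(pops, ctrl, config) {
  l2_ctrl <- to_log2_dna(ctrl$values)
  edges_log2 <- dna_bin_edges(l2_ctrl, bins = config$bins)
  ctrl_hist <- smooth_histogram(build_histogram(l2_ctrl, edges_log2),
                                sigma_bins = config$sigma)
  peaks <- detect_reference_peaks(ctrl_hist, detected_on = ctrl$well_label)
  message(sprintf("reference peaks: 2N at %.4g, 4N at %.4g (%s)",
                  peaks$p2N, peaks$p4N, peaks$detected_on))
  nedges <- normalized_edges(edges_log2, peaks)
  gates0 <- default_gates(config$thresholds)
  is_control <- function(p) {
    if (!is.null(config$control_treatment)) {
      p$treatment_label == config$control_treatment
    } else {
      p$well_label %in% config$control_wells
    }
  }
  all_pops <- c(pops, stats::setNames(list(ctrl), ctrl$well_label))
  records <- list()
  gates_by_well <- list()
  for (p in all_pops) {
    l2 <- to_log2_dna(p$values)
    nv <- normalize_dna_content(2^as.numeric(l2), peaks)
    wh <- smooth_histogram(build_histogram(nv, nedges),
                           sigma_bins = config$sigma)
    gates_w <- if (config$gating_mode == "adaptive" && !is_control(p)) {
      adapt_gates(wh, gates0, clamp = config$adapt_clamp)
    } else {
      gates0
    }
    prof <- classify_cells(nv, gates_w, well_label = p$well_label)
    if (prof$zero_cells) {
      message(sprintf("well %s has zero cells", p$well_label))
    }
    if (config$verbose) {
      message(sprintf("%s [%s]: boundaries %s", p$well_label,
                      p$treatment_label,
                      paste(sprintf("%.3f", gates_w$upper[-nrow(gates_w)]),
                            collapse = " ")))
    }
    gates_by_well[[p$well_label]] <- gates_w
    records[[length(records) + 1L]] <- list(
      well = p$well_label, treatment = p$treatment_label,
      cell_count = prof$cell_count, hist = wh,
      class_counts = prof$class_counts,
      class_fractions = prof$class_fractions)
  }
  list(records = records, peaks = peaks, gates = gates0,
       gates_by_well = gates_by_well, bin_edges = nedges)
}

# Manual-gating branch: arbitrary named gates on the raw measurement axis;
# values falling between gates are tallied in an explicit "ungated" class.
profile_manual <- function(pops, ctrl, config) {
  gates <- config$manual_gates
  all_vals <- unlist(lapply(pops, function(p) p$values), use.names = FALSE)
  edges <- seq(min(all_vals), max(all_vals), length.out = config$bins + 1L)
  if (edges[1] == edges[length(edges)]) {
    stop("measurement column is constant; nothing to histogram",
         call. = FALSE)
  }
  all_pops <- c(pops, stats::setNames(list(ctrl), ctrl$well_label))
  records <- list()
  for (p in all_pops) {
    wh <- smooth_histogram(build_histogram(p$values, edges),
                           sigma_bins = config$sigma)
    res <- apply_gates(p$values, gates)
    counts <- c(res$counts, ungated = res$ungated_count)
    fracs <- if (res$n > 0L) counts / res$n else counts * 0
    records[[length(records) + 1L]] <- list(
      well = p$well_label, treatment = p$treatment_label,
      cell_count = res$n, hist = wh,
      class_counts = counts, class_fractions = fracs)
  }
  list(records = records, peaks = NULL, gates = gates,
       gates_by_well = NULL, bin_edges = edges)
}
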