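#' Log2-transform DNA-stain intensities
#'
#' Relative per-cell DNA content is analyzed as log2 of the integrated
#' intensity of a DNA stain (DAPI, Hoechst, PI), so a diploid-to-tetraploid
#' doubling is one unit apart. Non-positive intensities have no logarithm:
#' when they are at most 1% of the cells they are excluded with a warning
#' (and counted in the `n_excluded` attribute), a larger share signals
#' corrupt input and is an error.
#'
#' @param values numeric vector of intensities.
#' @return numeric vector of log2 intensities, with attribute `n_excluded`.
#' @export
to_log2_dna <- function(values) {
  values <- as.numeric(values)
  bad <- !is.finite(values) | values <= 0
  n_bad <- sum(bad)
  if (n_bad > 0L) {
    if (n_bad / length(values) > 0.01) {
      stop(sprintf("%d of %d cells have non-positive DNA intensity (> 1%%); input looks corrupt",
                   n_bad, length(values)), call. = FALSE)
    }
    warning(sprintf("excluded %d cell(s) with non-positive DNA intensity",
                    n_bad), call. = FALSE)
  }
  out <- log2(values[!bad])
  attr(out, "n_excluded") <- as.integer(n_bad)
  out
}

#' Plate-wide histogram edges for DNA content
#'
#' Equal-width bins in log2-intensity space spanning
#' `[p1 - 3*IQR, p99 + 3*IQR]` of the pooled control. The same edges are
#' reused for every well on the plate so the saved histogram vectors are
#' comparable across wells.
#'
#' @param log2_values pooled-control log2 intensities.
#' @param bins number of bins (default 64).
#' @return numeric vector of `bins + 1` edges.
#' @export
dna_bin_edges <- function(log2_values, bins = 64L) {
  stopifnot(length(log2_values) > 1L)
  q <- stats::quantile(log2_values, c(0.01, 0.25, 0.75, 0.99), names = FALSE,
                       type = 7)
  pad <- 3 * (q[3] - q[2])
  if (pad <= 0) pad <- max(0.05 * (q[4] - q[1]), 1e-6)
  seq(q[1] - pad, q[4] + pad, length.out = bins + 1L)
}

#' Reference 2N/4N peaks
#'
#' @param p2N,p4N peak locations in intensity units, `p4N > p2N > 0`.
#' @param detected_on label of the population the peaks were detected on.
#' @return object of class `reference_peaks`.
#' @export
reference_peaks <- function(p2N, p4N, detected_on = POOLED_CONTROL_LABEL) {
  if (!(is.finite(p2N) && is.finite(p4N) && p2N > 0 && p4N > p2N)) {
    stop("invalid reference peaks: need p4N > p2N > 0", call. = FALSE)
  }
  structure(list(p2N = p2N, p4N = p4N, detected_on = detected_on),
            class = "reference_peaks")
}

#' @export
print.reference_peaks <- function(x, ...) {
  cat(sprintf("<reference_peaks> 2N at %g, 4N at %g (ratio %.3f), detected on %s\n",
              x$p2N, x$p4N, x$p4N / x$p2N, x$detected_on))
  invisible(x)
}

#' Detect the 2N and 4N reference peaks on a control histogram
#'
#' On an unperturbed population the DNA-content histogram is bimodal: the
#' taller 2N (G1) peak to the left and the smaller 4N (G2/M) peak to the
#' right. The 2N center is taken as the highest smoothed local maximum and
#' the 4N center as the highest maximum to its right — taking simply the
#' second-highest maximum would mistake a tall sub-G1 debris peak for 4N.
#'
#' @param control_hist a [smooth_histogram()]-ed histogram of the pooled
#'   control's log2 intensities.
#' @param detected_on label recorded in the result.
#' @return a [reference_peaks()] with locations back-transformed to
#'   intensity units.
#' @export
detect_reference_peaks <- function(control_hist,
                                   detected_on = POOLED_CONTROL_LABEL) {
  stopifnot(inherits(control_hist, "hist_vector"))
  if (is.null(control_hist$smoothed)) {
    stop("control histogram must be smoothed before peak detection",
         call. = FALSE)
  }
  pk <- find_peaks(control_hist, use_smoothed = TRUE)
  if (nrow(pk) < 2L) {
    stop("reference detection failed: control histogram has fewer than 2 local maxima; enter gates manually",
         call. = FALSE)
  }
  loc2 <- pk$location[1L]
  right <- pk[pk$location > loc2, , drop = FALSE]
  if (nrow(right) == 0L) {
    stop("reference detection failed: no peak to the right of the 2N peak; enter gates manually",
         call. = FALSE)
  }
  loc4 <- right$location[1L]
  reference_peaks(2^loc2, 2^loc4, detected_on = detected_on)
}

#' Normalize DNA content to the 2N/4N anchors
#'
#' Maps intensities so the detected 2N peak sits at exactly 1 and the 4N
#' peak at exactly 2: with `u(x) = (log2 x - log2 p2N) / (log2 p4N - log2 p2N)`
#' the normalized content is `2^u`. The map is strictly increasing, holds
#' both anchors even when staining is non-proportional (`p4N != 2 * p2N`),
#' and reduces to `x / p2N` when `p4N = 2 * p2N`.
#'
#' @param values positive intensities (apply [to_log2_dna()]'s exclusion
#'   policy upstream).
#' @param peaks a [reference_peaks()].
#' @return numeric vector of dimensionless normalized DNA content.
#' @export
normalize_dna_content <- function(values, peaks) {
  stopifnot(inherits(peaks, "reference_peaks"))
  values <- as.numeric(values)
  if (any(!is.finite(values) | values <= 0)) {
    stop("normalize_dna_content() needs strictly positive finite intensities",
         call. = FALSE)
  }
  u <- (log2(values) - log2(peaks$p2N)) / (log2(peaks$p4N) - log2(peaks$p2N))
  2^u
}

# Transform log2-axis histogram edges onto the normalized-DNA axis.
normalized_edges <- function(log2_edges, peaks) {
  u <- (log2_edges - log2(peaks$p2N)) / (log2(peaks$p4N) - log2(peaks$p2N))
  2^u
}

CELL_CYCLE_CLASSES <- c("<2N", "2N", "S", "4N", ">4N")

#' Default five-class cell-cycle gates
#'
#' Classes `<2N`, `2N`, `S`, `4N`, `>4N` on the normalized DNA axis, with
#' thresholds at 0.75, 1.25, 1.75 and 2.5. Intervals are half-open
#' `[lower, upper)`: a value exactly at a threshold joins the upper class.
#'
#' @param thresholds the four interior boundaries, strictly increasing.
#' @return a [make_gates()] gate set covering `[0, Inf)` on axis
#'   `"normalized_dna"`.
#' @export
default_gates <- function(thresholds = c(0.75, 1.25, 1.75, 2.5)) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0) ||
      thresholds[1] <= 0) {
    stop("thresholds must be 4 strictly increasing positive numbers",
         call. = FALSE)
  }
  make_gates(data.frame(name = CELL_CYCLE_CLASSES,
                        lower = c(0, thresholds),
                        upper = c(thresholds, Inf)),
             axis = "normalized_dna")
}

#' Adapt cell-cycle gate boundaries to one well's histogram shape
#'
#' Treatments can shift where sub-populations separate (through changes in
#' cell size or stain uptake) without changing which sub-population a cell
#' belongs to. Each interior boundary is therefore moved to the valley of
#' the well's own smoothed histogram: for every one of the five classes the
#' highest smoothed local maximum inside the class interval is located, and
#' a boundary flanked by peaks in both adjacent classes is moved to the
#' minimum of the smoothed histogram between those two peaks (leftmost bin
#' center on ties). Every adjusted boundary is clamped to within
#' `clamp` of its reference value, which keeps the gates ordered and tied to
#' the limits set by the control's 2N and 4N peaks; a boundary with a
#' missing flanking peak keeps its reference value. When the histogram has
#' no peaks at all the reference gates are returned unchanged.
#'
#' @param well_hist smoothed [hist_vector()] of the well on the normalized
#'   DNA axis.
#' @param control_gates reference gate set (usually [default_gates()]).
#' @param clamp maximum displacement of a boundary from its reference, in
#'   normalized DNA units (default 0.15).
#' @return a gate set with the same class names.
#' @export
adapt_gates <- function(well_hist, control_gates = default_gates(),
                        clamp = 0.15) {
  stopifnot(inherits(well_hist, "hist_vector"),
            inherits(control_gates, "gate_set"))
  if (is.null(well_hist$smoothed)) {
    stop("well histogram must be smoothed before gate adaptation",
         call. = FALSE)
  }
  pk <- find_peaks(well_hist, use_smoothed = TRUE)
  if (nrow(pk) == 0L) return(control_gates)
  nclass <- nrow(control_gates)
  # highest peak per class region (peaks are height-sorted: first hit wins)
  region_bin <- rep(NA_integer_, nclass)
  for (i in seq_len(nclass)) {
    hit <- pk$location >= control_gates$lower[i] &
      pk$location < control_gates$upper[i]
    if (any(hit)) region_bin[i] <- pk$bin_index[which(hit)[1L]]
  }
  centers <- bin_centers(well_hist)
  bounds <- control_gates$upper[-nclass]
  for (k in seq_len(nclass - 1L)) {
    a <- region_bin[k]
    b <- region_bin[k + 1L]
    if (is.na(a) || is.na(b)) next
    seg <- well_hist$smoothed[a:b]
    valley <- centers[a + which.min(seg) - 1L]
    bounds[k] <- min(max(valley, control_gates$upper[k] - clamp),
                     control_gates$upper[k] + clamp)
  }
  out <- tryCatch(
    make_gates(data.frame(name = control_gates$name,
                          lower = c(control_gates$lower[1L], bounds),
                          upper = c(bounds, control_gates$upper[nclass])),
               axis = attr(control_gates, "axis")),
    error = function(e) NULL)
  if (is.null(out)) {
    warning("adapted boundaries were not strictly ordered; keeping control gates",
            call. = FALSE)
    return(control_gates)
  }
  out
}

#' Classify cells into cell-cycle classes
#'
#' Assigns every normalized DNA-content value to exactly one class of a
#' gate set that covers the whole positive axis (as [default_gates()] and
#' [adapt_gates()] outputs do). Classification always uses the raw
#' per-cell values against the gate boundaries, never the smoothed
#' histogram.
#'
#' @param normalized_values normalized DNA content (positive reals).
#' @param gates covering, contiguous gate set.
#' @param well_label label stored in the profile.
#' @return object of class `cell_cycle_profile`: list with `well_label`,
#'   `gates`, `class_counts`, `class_fractions`, `cell_count` and
#'   `zero_cells`. With zero cells, fractions are reported as 0 and
#'   `zero_cells` is `TRUE`.
#' @export
classify_cells <- function(normalized_values, gates, well_label = NA_character_) {
  stopifnot(inherits(gates, "gate_set"))
  ng <- nrow(gates)
  contiguous <- ng == 1L ||
    isTRUE(all.equal(gates$lower[-1L], gates$upper[-ng]))
  if (!contiguous || gates$lower[1L] > 0 || is.finite(gates$upper[ng])) {
    stop("cell-cycle gates must be contiguous and cover (0, Inf)",
         call. = FALSE)
  }
  res <- apply_gates(normalized_values, gates)
  if (res$ungated_count > 0L) {
    stop(sprintf("internal inconsistency: %d value(s) fell outside covering gates",
                 res$ungated_count), call. = FALSE)
  }
  structure(
    list(well_label = well_label,
         gates = gates,
         class_counts = res$counts,
         class_fractions = res$fractions,
         cell_count = res$n,
         zero_cells = res$n == 0L),
    class = "cell_cycle_profile"
  )
}

#' @export
print.cell_cycle_profile <- function(x, ...) {
  cat(sprintf("<cell_cycle_profile> %s: %d cells%s\n", x$well_label,
              x$cell_count, if (x$zero_cells) " (zero-cell well)" else ""))
  print(round(100 * x$class_fractions, 1))
  invisible(x)
}
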