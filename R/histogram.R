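#' Histogram vector
#'
#' The per-well reduced representation: bin edges plus raw counts, optionally
#' carrying a Gaussian-smoothed copy of the counts used for peak and valley
#' detection. Counts live in the bins `[edge_i, edge_{i+1})`; the last bin is
#' closed on both sides so a value exactly at the top edge is kept.
#'
#' @param bin_edges numeric vector of `B + 1` strictly increasing bin edges,
#'   in measurement units.
#' @param counts numeric vector of `B` non-negative per-bin counts.
#' @param n_outside number of values that fell outside `[min(edges), max(edges)]`
#'   when the histogram was built (0 for hand-constructed vectors).
#'
#' @return An object of class `hist_vector`: a list with elements
#'   `bin_edges`, `counts`, `smoothed` (NULL until [smooth_histogram()] is
#'   called), `sigma_bins` and `n_outside`.
#' @seealso [build_histogram()], [smooth_histogram()], [find_peaks()]
#' @export
hist_vector <- function(bin_edges, counts, n_outside = 0L) {
  bin_edges <- as.numeric(bin_edges)
  counts <- as.numeric(counts)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing with at least 2 entries",
         call. = FALSE)
  }
  if (length(counts) != length(bin_edges) - 1L) {
    stop("`counts` must have one entry per bin (length(bin_edges) - 1)",
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(bin_edges = bin_edges, counts = counts, smoothed = NULL,
         sigma_bins = NULL, n_outside = as.integer(n_outside)),
    class = "hist_vector"
  )
}

#' @export
print.hist_vector <- function(x, ...) {
  cat(sprintf("<hist_vector> %d bins on [%g, %g], mass %g%s%s\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              sum(x$counts),
              if (x$n_outside > 0) sprintf(", %d outside", x$n_outside) else "",
              if (!is.null(x$smoothed))
                sprintf(", smoothed (sigma = %g bins)", x$sigma_bins) else ""))
  invisible(x)
}

#' Bin centers of a histogram vector
#'
#' Arithmetic midpoints of consecutive bin edges, on the histogram's own axis.
#'
#' @param hist a [hist_vector()].
#' @return numeric vector of length `B`.
#' @export
bin_centers <- function(hist) {
  stopifnot(inherits(hist, "hist_vector"))
  e <- hist$bin_edges
  (e[-length(e)] + e[-1L]) / 2
}

#' Build a histogram vector from a measurement vector
#'
#' Bins are half-open `[edge_i, edge_{i+1})` except the last, which also
#' includes its upper edge. Values outside the edge range are excluded from
#' the counts and tallied in `n_outside`, so
#' `sum(counts) + n_outside == length(values)` always holds.
#'
#' @param values non-empty numeric vector of finite measurements.
#' @param bin_edges explicit strictly increasing edges; overrides `bins`/`range`.
#' @param bins number of equal-width bins when `bin_edges` is not given.
#' @param range length-2 numeric range for equal-width binning; defaults to
#'   `range(values)`.
#'
#' @return a [hist_vector()].
#' @examples
#' build_histogram(c(1, 1, 1, 2), bin_edges = c(0.5, 1.5, 2.5))$counts  # 3 1
#' @export
build_histogram <- function(values, bin_edges = NULL, bins = 64L,
                            range = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("cannot build a histogram from an empty value vector", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite; filter the input first", call. = FALSE)
  }
  if (is.null(bin_edges)) {
    if (is.null(range)) range <- base::range(values)
    if (!is.numeric(range) || length(range) != 2L || range[2] <= range[1]) {
      stop("`range` must be two increasing numbers", call. = FALSE)
    }
    bin_edges <- seq(range[1], range[2], length.out = bins + 1L)
  }
  if (any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= nb
  counts <- tabulate(idx[inside], nbins = nb)
  hist_vector(bin_edges, counts, n_outside = sum(!inside))
}

# Edge-repeating reflection of out-of-range indices into 1..n
# (... 2 1 | 1 2 ... n | n n-1 ...), tiling for arbitrarily wide kernels.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- (i - 1L) %% p
  as.integer(ifelse(j < n, j + 1L, p - j))
}

# Discrete Gaussian smoothing with kernel truncated at 4*sigma and
# reflect-padded boundaries. Operates on a bare numeric vector.
gaussian_smooth <- function(y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma_bins` must be a single positive number", call. = FALSE)
  }
  n <- length(y)
  r <- as.integer(ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  padded <- y[reflect_index(seq.int(1L - r, n + r), n)]
  sm <- stats::filter(padded, k, method = "convolution", sides = 2L)
  as.numeric(sm[seq.int(r + 1L, r + n)])
}

#' Gaussian-smooth a histogram vector
#'
#' Fills the `smoothed` field by discrete convolution with a normalized
#' Gaussian kernel of standard deviation `sigma_bins`, expressed in bin
#' units. The kernel is truncated at 4 sigma and boundaries are
#' reflect-padded, which keeps a constant signal fixed and preserves total
#' mass to well under 0.5%. Raw counts are left untouched: smoothing exists
#' for peak/valley detection and display, never for classifying cells.
#'
#' @param hist a [hist_vector()] with at least 3 bins.
#' @param sigma_bins kernel standard deviation in bins (default 1.5).
#' @return the input `hist_vector` with `smoothed` and `sigma_bins` set.
#' @export
smooth_histogram <- function(hist, sigma_bins = 1.5) {
  stopifnot(inherits(hist, "hist_vector"))
  if (length(hist$counts) < 3L) {
    stop("smoothing needs a histogram with at least 3 bins", call. = FALSE)
  }
  hist$smoothed <- gaussian_smooth(hist$counts, sigma_bins)
  hist$sigma_bins <- sigma_bins
  hist
}

#' Find local maxima of a histogram
#'
#' A peak is a bin strictly greater than both neighbors; a plateau of equal
#' bins flanked by lower values reports its leftmost bin; the first and last
#' bin qualify when greater than their single neighbor. Peaks of
#' non-positive height are discarded. Results are sorted by descending
#' height, ties broken by the lower bin index.
#'
#' @param hist a [hist_vector()].
#' @param use_smoothed search the smoothed counts instead of the raw counts
#'   (requires [smooth_histogram()] to have run).
#' @return data.frame with columns `bin_index` (1-based), `location`
#'   (bin center) and `height`; zero rows when no peak exists.
#' @export
find_peaks <- function(hist, use_smoothed = FALSE) {
  stopifnot(inherits(hist, "hist_vector"))
  y <- if (use_smoothed) {
    if (is.null(hist$smoothed)) {
      stop("histogram has no smoothed counts; call smooth_histogram() first",
           call. = FALSE)
    }
    hist$smoothed
  } else {
    hist$counts
  }
  runs <- rle(y)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  vals <- runs$values
  m <- length(vals)
  left <- c(-Inf, vals[-m])
  right <- c(vals[-1L], -Inf)
  is_peak <- vals > left & vals > right & vals > 0
  idx <- starts[is_peak]
  out <- data.frame(bin_index = idx,
                    location = bin_centers(hist)[idx],
                    height = vals[is_peak])
  out[order(-out$height, out$bin_index), , drop = FALSE]
}
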