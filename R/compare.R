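#' Sub-population fraction vector
#'
#' A labeled vector of class fractions on the simplex (entries in `[0, 1]`
#' summing to 1 within 1e-6), the unit compared across wells, treatments or
#' measurement modalities.
#'
#' @param label text label (well, treatment, modality).
#' @param fractions numeric fractions.
#' @param class_names class names, one per fraction; defaults to
#'   `names(fractions)`.
#' @return object of class `fraction_vector`.
#' @export
fraction_vector <- function(label, fractions, class_names = names(fractions)) {
  fractions <- as.numeric(fractions)
  if (is.null(class_names) || length(class_names) != length(fractions)) {
    stop("`class_names` must name every fraction", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < -1e-9) ||
      any(fractions > 1 + 1e-9) || abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must lie in [0, 1] and sum to 1 (within 1e-6)",
         call. = FALSE)
  }
  structure(list(label = as.character(label), fractions = fractions,
                 class_names = as.character(class_names)),
            class = "fraction_vector")
}

#' Pearson correlation of two fraction vectors
#'
#' The product-moment correlation of two sub-population distribution
#' vectors, the standard summary for comparing class profiles across
#' modalities (e.g. image-based analysis versus flow cytometry). Computed
#' on fractions, not raw counts, so populations of different sizes are
#' comparable. A constant vector has zero variance and no defined
#' correlation.
#'
#' @param a,b [fraction_vector()]s with identical `class_names` in the same
#'   order.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  stopifnot(inherits(a, "fraction_vector"), inherits(b, "fraction_vector"))
  if (!identical(a$class_names, b$class_names)) {
    stop("fraction vectors have different class names or order",
         call. = FALSE)
  }
  if (stats::sd(a$fractions) == 0 || stats::sd(b$fractions) == 0) {
    stop(sprintf("correlation undefined: vector '%s' is constant (zero variance)",
                 if (stats::sd(a$fractions) == 0) a$label else b$label),
         call. = FALSE)
  }
  stats::cor(a$fractions, b$fractions)
}

#' Pairwise correlation matrix of fraction vectors
#'
#' Symmetric matrix with unit diagonal; a pair whose correlation is
#' undefined (a constant vector) is recorded as `NA`.
#'
#' @param vectors list of at least two [fraction_vector()]s sharing
#'   `class_names`.
#' @return square numeric matrix with the vectors' labels as dimnames.
#' @export
correlation_matrix <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 2L)
  labels <- vapply(vectors, function(v) v$label, character(1))
  n <- length(vectors)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- tryCatch(pearson_correlation(vectors[[i]], vectors[[j]]),
                    error = function(e) NA_real_)
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  m
}

#' Fraction vectors from a profile table
#'
#' Extracts the `frac_` columns of a [read_profiles()] table into a list of
#' [fraction_vector()]s, one per row, labeled by well. Rows with zero cells
#' (all fractions 0) are skipped with a message.
#'
#' @param profiles data.frame from [read_profiles()].
#' @return list of `fraction_vector`.
#' @export
profile_fraction_vectors <- function(profiles) {
  fcols <- attr(profiles, "frac_columns")
  classes <- attr(profiles, "class_names")
  if (is.null(fcols) || length(fcols) == 0L) {
    stop("table carries no frac_ columns; was it written by write_profiles()?",
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    f <- as.numeric(profiles[i, fcols])
    if (sum(f) == 0) {
      message(sprintf("skipping zero-cell well '%s'", profiles$well[i]))
      next
    }
    out[[length(out) + 1L]] <-
      fraction_vector(profiles$well[i], f / sum(f), classes)
  }
  out
}
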