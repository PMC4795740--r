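#' Parse multi-well plate labels
#'
#' Accepts one row letter (A-P, case-insensitive) followed by a 1-2 digit
#' column number, covering 96- and 384-well plates. Anything else maps to
#' `NA` and is reported in a single warning.
#'
#' @param labels character vector of well labels.
#' @return data.frame with columns `label`, `row` (1-based, A = 1) and
#'   `col` (1-based).
#' @export
parse_well_label <- function(labels) {
  labels <- as.character(labels)
  m <- regmatches(labels, regexec("^([A-Pa-p])([0-9]{1,2})$", labels))
  row <- vapply(m, function(x) {
    if (length(x) == 3L) match(toupper(x[2]), LETTERS) else NA_integer_
  }, integer(1))
  col <- vapply(m, function(x) {
    if (length(x) == 3L) as.integer(x[3]) else NA_integer_
  }, integer(1))
  col[!is.na(col) & col == 0L] <- NA_integer_
  row[is.na(col)] <- NA_integer_
  bad <- labels[is.na(row)]
  if (length(bad) > 0L) {
    warning(sprintf("unparseable well label(s) skipped: %s",
                    paste(sQuote(unique(bad)), collapse = ", ")),
            call. = FALSE)
  }
  data.frame(label = labels, row = row, col = col, stringsAsFactors = FALSE)
}

#' Plate layout for a set of well labels
#'
#' Chooses 8 x 12 when all parsed coordinates fit a 96-well plate and
#' 16 x 24 otherwise.
#'
#' @param labels character vector of well labels.
#' @return list with `rows`, `cols` and the parsed `map` data.frame.
#' @export
plate_layout <- function(labels) {
  map <- parse_well_label(labels)
  ok <- !is.na(map$row)
  if (!any(ok)) stop("no parseable well labels", call. = FALSE)
  small <- all(map$row[ok] <= 8L) && all(map$col[ok] <= 12L)
  list(rows = if (small) 8L else 16L,
       cols = if (small) 12L else 24L,
       map = map)
}

#' Full-plate histogram grid figure
#'
#' Small-multiples view of a whole plate: one panel per occupied well at
#' its plate position, raw counts (blue steps) overlaid with the smoothed
#' curve (red), gate boundaries as dashed verticals, the treatment label
#' above each panel and the per-class percentages (1 decimal) printed
#' beneath the x axis. Panels share the y scale by default so relative
#' cell counts are comparable across the plate.
#'
#' @param records list of per-well records as passed to [write_profiles()]
#'   (fields `well`, `treatment`, `cell_count`, `hist`, `class_counts`,
#'   `class_fractions`); all histograms must share bin edges. Records with
#'   unparseable well labels are skipped with a warning.
#' @param gates optional gate set whose boundaries are drawn.
#' @param file optional output path; extension selects the device
#'   (`.png`, `.pdf`, `.svg`).
#' @param shared_y share the y scale across panels (default) or autoscale
#'   each well.
#' @param width,height figure size in inches passed to [ggplot2::ggsave()].
#' @return the ggplot object, invisibly.
#' @export
plate_grid_figure <- function(records, gates = NULL, file = NULL,
                              shared_y = TRUE, width = NULL, height = NULL) {
  if (length(records) == 0L) stop("nothing to plot: no well records",
                                  call. = FALSE)
  labels <- vapply(records, function(r) r$well, character(1))
  layout <- plate_layout(labels)
  map <- layout$map
  keep <- which(!is.na(map$row))
  if (length(keep) == 0L) stop("nothing to plot: no parseable well labels",
                               call. = FALSE)
  curve <- list()
  ann <- list()
  for (i in keep) {
    r <- records[[i]]
    cen <- bin_centers(r$hist)
    rowf <- LETTERS[map$row[i]]
    colf <- map$col[i]
    curve[[length(curve) + 1L]] <- data.frame(
      row = rowf, col = colf, x = cen, y = r$hist$counts, kind = "raw")
    if (!is.null(r$hist$smoothed)) {
      curve[[length(curve) + 1L]] <- data.frame(
        row = rowf, col = colf, x = cen, y = r$hist$smoothed, kind = "smoothed")
    }
    pct <- 100 * r$class_fractions
    ann[[length(ann) + 1L]] <- data.frame(
      row = rowf, col = colf,
      treatment = r$treatment,
      pct_text = paste(sprintf("%.1f", pct), collapse = " "),
      x = mean(range(cen)))
  }
  curve <- do.call(rbind, curve)
  ann <- do.call(rbind, ann)
  rows_present <- LETTERS[sort(unique(map$row[keep]))]
  cols_present <- sort(unique(map$col[keep]))
  curve$row <- factor(curve$row, levels = rows_present)
  curve$col <- factor(curve$col, levels = cols_present)
  ann$row <- factor(ann$row, levels = rows_present)
  ann$col <- factor(ann$col, levels = cols_present)

  p <- ggplot2::ggplot(curve, ggplot2::aes(x = x, y = y, color = kind)) +
    ggplot2::geom_step(data = curve[curve$kind == "raw", ], linewidth = 0.3) +
    ggplot2::geom_line(data = curve[curve$kind == "smoothed", ],
                       linewidth = 0.4) +
    ggplot2::scale_color_manual(values = c(raw = "#2166ac",
                                           smoothed = "#b2182b"),
                                name = NULL) +
    ggplot2::geom_text(data = ann, ggplot2::aes(x = x, y = Inf, label = treatment),
                       inherit.aes = FALSE, vjust = 1.2, size = 2.2) +
    ggplot2::geom_text(data = ann, ggplot2::aes(x = x, y = -Inf, label = pct_text),
                       inherit.aes = FALSE, vjust = -0.3, size = 1.8) +
    ggplot2::facet_grid(row ~ col,
                        scales = if (shared_y) "fixed" else "free_y") +
    ggplot2::labs(x = NULL, y = "cells / bin") +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::theme(legend.position = "bottom",
                   panel.grid.minor = ggplot2::element_blank())
  if (!is.null(gates)) {
    b <- gates$upper[is.finite(gates$upper)]
    p <- p + ggplot2::geom_vline(xintercept = b, linetype = "dashed",
                                 linewidth = 0.2, color = "grey40")
  }
  if (!is.null(file)) {
    if (is.null(width)) width <- max(6, 1.1 * length(cols_present))
    if (is.null(height)) height <- max(4, 1.1 * length(rows_present))
    ggplot2::ggsave(file, p, width = width, height = height, limitsize = FALSE)
  }
  invisible(p)
}
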