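#' Read a per-cell measurement table
#'
#' Parses one CSV export with one row per cell (CellProfiler-style
#' "per-object" tables, or any text table with a header row), keeping the
#' well label, the treatment label and a single numeric measurement column.
#' Each file is treated as an independent experiment; call this once per
#' file and never merge plates that happen to share well labels.
#'
#' Rows whose measurement is non-numeric or non-finite, or whose well label
#' is empty, are dropped from analysis but tallied in `n_dropped` and
#' reported with a message.
#'
#' @param path path to the CSV file.
#' @param well_column,treatment_column,measurement_column header names of the
#'   well label, treatment label and numeric measurement columns.
#' @param delimiter field separator; `","` by default, use `";"` or `"\t"`
#'   for semicolon/tab exports.
#'
#' @return An object of class `cell_table`: a list with `rows` (data.frame
#'   with columns `well`, `treatment`, `value`), `source_file`,
#'   `column_names` (full CSV header) and `n_dropped`.
#' @export
read_measurements <- function(path, well_column, treatment_column,
                              measurement_column, delimiter = ",") {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, sep = delimiter, check.names = FALSE,
                        stringsAsFactors = FALSE)
  wanted <- c(well_column, treatment_column, measurement_column)
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf(
      "column(s) %s not found in '%s'; available columns: %s",
      paste(sQuote(missing_cols), collapse = ", "), path,
      paste(sQuote(names(df)), collapse = ", ")), call. = FALSE)
  }
  well <- as.character(df[[well_column]])
  treatment <- as.character(df[[treatment_column]])
  value <- suppressWarnings(as.numeric(df[[measurement_column]]))
  keep <- is.finite(value) & !is.na(well) & nzchar(well)
  n_dropped <- sum(!keep)
  if (sum(keep) == 0L) {
    stop(sprintf("no parseable rows in '%s' (all %d rows dropped)",
                 path, nrow(df)), call. = FALSE)
  }
  if (n_dropped > 0L) {
    message(sprintf("%s: dropped %d of %d rows (non-finite measurement or empty well label)",
                    basename(path), n_dropped, nrow(df)))
  }
  structure(
    list(rows = data.frame(well = well[keep], treatment = treatment[keep],
                           value = value[keep], stringsAsFactors = FALSE),
         source_file = path,
         column_names = names(df),
         n_dropped = as.integer(n_dropped)),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells in %d wells from '%s' (%d rows dropped)\n",
              nrow(x$rows), length(unique(x$rows$well)),
              basename(x$source_file), x$n_dropped))
  invisible(x)
}

#' Well population
#'
#' One well's (or the pooled controls') measurement vector plus metadata.
#'
#' @param well_label,treatment_label character scalars.
#' @param values finite numeric measurement vector; `cell_count` is its length.
#' @return object of class `well_population`.
#' @export
well_population <- function(well_label, treatment_label, values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("well population values must all be finite", call. = FALSE)
  }
  structure(
    list(well_label = as.character(well_label),
         treatment_label = as.character(treatment_label),
         values = values,
         cell_count = length(values)),
    class = "well_population"
  )
}

#' @export
print.well_population <- function(x, ...) {
  cat(sprintf("<well_population> %s (%s): %d cells\n",
              x$well_label, x$treatment_label, x$cell_count))
  invisible(x)
}

#' Aggregate cells by well
#'
#' Groups the rows of a [read_measurements()] table by well label. Every
#' distinct well yields one [well_population()]; the union of all values is
#' exactly the table's values. A well whose rows carry more than one
#' treatment label is a data-integrity error, since well-to-treatment must
#' be a function for pooling and reporting.
#'
#' @param table a `cell_table`.
#' @return named list of `well_population`, ordered by well label.
#' @export
group_by_well <- function(table) {
  stopifnot(inherits(table, "cell_table"))
  if (nrow(table$rows) == 0L) {
    stop("cell table has no rows to group", call. = FALSE)
  }
  rows <- table$rows
  pieces <- split(rows, rows$well)
  pieces <- pieces[order(names(pieces))]
  lapply(pieces, function(p) {
    trt <- unique(p$treatment)
    if (length(trt) != 1L) {
      stop(sprintf("well '%s' carries conflicting treatment labels: %s",
                   p$well[1L], paste(sQuote(trt), collapse = ", ")),
           call. = FALSE)
    }
    well_population(p$well[1L], trt, p$value)
  })
}

#' Reserved label of the pooled-control record
#' @export
POOLED_CONTROL_LABEL <- "POOLED_CONTROL"

#' Pool control wells into a single reference population
#'
#' Concatenates the values of all wells matched either by treatment label or
#' by an explicit well list, and stores them as a separate record under the
#' reserved well label `"POOLED_CONTROL"`. Pooling is order-invariant up to
#' the multiset of values.
#'
#' @param populations list of [well_population()] (from [group_by_well()]).
#' @param treatment control treatment label to match (e.g. `"DMSO"`).
#' @param wells explicit character vector of control well labels; used when
#'   `treatment` is `NULL`.
#' @return a `well_population` with `well_label = "POOLED_CONTROL"`.
#' @export
pool_controls <- function(populations, treatment = NULL, wells = NULL) {
  stopifnot(is.list(populations), length(populations) > 0L)
  if (is.null(treatment) && is.null(wells)) {
    stop("supply a control `treatment` label or an explicit `wells` list",
         call. = FALSE)
  }
  sel <- if (!is.null(treatment)) {
    vapply(populations, function(p) p$treatment_label == treatment, logical(1))
  } else {
    vapply(populations, function(p) p$well_label %in% wells, logical(1))
  }
  if (!any(sel)) {
    desc <- if (!is.null(treatment)) sprintf("treatment '%s'", treatment)
            else sprintf("wells %s", paste(sQuote(wells), collapse = ", "))
    stop(sprintf("control selector matched no wells (%s); available treatments: %s",
                 desc,
                 paste(sQuote(unique(vapply(populations,
                                            function(p) p$treatment_label,
                                            character(1)))), collapse = ", ")),
         call. = FALSE)
  }
  matched <- populations[sel]
  trt <- unique(vapply(matched, function(p) p$treatment_label, character(1)))
  well_population(
    POOLED_CONTROL_LABEL,
    if (length(trt) == 1L) trt else "POOLED",
    unlist(lapply(matched, function(p) p$values), use.names = FALSE)
  )
}

fmt_edge <- function(x) formatC(x, format = "g", digits = 6)

#' Write the per-well profile table
#'
#' One row per well (plus one for the pooled control), with columns
#' `well`, `treatment`, `cell_count`, one column per histogram bin named
#' `bin_<edge_low>_<edge_high>`, then one `count_<class>` and one
#' `frac_<class>` column per gate class. Fractions are written with 6
#' decimals so the file round-trips.
#'
#' @param path output CSV path.
#' @param records list of per-well records; each a list with elements
#'   `well`, `treatment`, `cell_count`, `hist` (a [hist_vector()]),
#'   `class_counts` (named integer vector) and `class_fractions` (named
#'   numeric vector with the same names).
#' @return the written data.frame, invisibly.
#' @export
write_profiles <- function(path, records) {
  stopifnot(is.list(records), length(records) > 0L)
  edges <- records[[1L]]$hist$bin_edges
  same <- vapply(records, function(r) {
    length(r$hist$bin_edges) == length(edges) &&
      isTRUE(all.equal(r$hist$bin_edges, edges))
  }, logical(1))
  if (!all(same)) {
    stop("records carry heterogeneous histogram bin edges; all wells of a plate must share edges",
         call. = FALSE)
  }
  classes <- names(records[[1L]]$class_counts)
  nb <- length(edges) - 1L
  bin_names <- paste0("bin_", fmt_edge(edges[-length(edges)]), "_",
                      fmt_edge(edges[-1L]))
  rows <- lapply(records, function(r) {
    stopifnot(identical(names(r$class_counts), classes),
              identical(names(r$class_fractions), classes))
    c(list(well = r$well, treatment = r$treatment,
           cell_count = as.integer(r$cell_count)),
      as.list(stats::setNames(r$hist$counts, bin_names)),
      as.list(stats::setNames(as.integer(r$class_counts),
                              paste0("count_", classes))),
      as.list(stats::setNames(round(r$class_fractions, 6),
                              paste0("frac_", classes))))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  rownames(df) <- NULL
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write profile table to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(df)
}

#' Read back a per-well profile table
#'
#' Inverse of [write_profiles()] for downstream use: returns the data.frame
#' with attributes `bin_columns`, `count_columns`, `frac_columns` and
#' `class_names` identifying the column groups.
#'
#' @param path profile CSV written by [write_profiles()].
#' @return data.frame with helper attributes.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("profile file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "bin_columns") <- grep("^bin_", names(df), value = TRUE)
  attr(df, "count_columns") <- grep("^count_", names(df), value = TRUE)
  attr(df, "frac_columns") <- grep("^frac_", names(df), value = TRUE)
  attr(df, "class_names") <- sub("^frac_", "", attr(df, "frac_columns"))
  df
}
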