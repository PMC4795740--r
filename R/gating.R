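#' Build a validated gate set
#'
#' A gate set is an ordered list of named, pairwise-disjoint half-open
#' intervals `[lower, upper)` on one measurement axis. Gaps between gates
#' are allowed (values falling in a gap are tallied as "ungated" by
#' [apply_gates()]); overlaps and duplicate names are configuration errors.
#'
#' @param spec a data.frame with columns `name`, `lower`, `upper`, or a list
#'   of length-3 lists/vectors in that order. `-Inf`/`Inf` bounds are
#'   allowed.
#' @param axis measurement-axis label, e.g. a column name or
#'   `"normalized_dna"`.
#' @return object of class `gate_set`: a data.frame sorted by lower bound
#'   with attribute `axis`.
#' @examples
#' make_gates(data.frame(name = c("neg", "pos"), lower = c(-Inf, 2),
#'                       upper = c(2, Inf)))
#' @export
make_gates <- function(spec, axis = "measurement") {
  if (is.data.frame(spec)) {
    df <- data.frame(name = as.character(spec$name),
                     lower = as.numeric(spec$lower),
                     upper = as.numeric(spec$upper),
                     stringsAsFactors = FALSE)
  } else if (is.list(spec) && length(spec) > 0L) {
    df <- do.call(rbind, lapply(spec, function(g) {
      g <- as.list(g)
      if (is.null(names(g)) || !all(c("name", "lower", "upper") %in% names(g))) {
        names(g) <- c("name", "lower", "upper")
      }
      data.frame(name = as.character(g$name), lower = as.numeric(g$lower),
                 upper = as.numeric(g$upper), stringsAsFactors = FALSE)
    }))
  } else {
    stop("gate spec must be a non-empty data.frame or list", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("gate spec is empty", call. = FALSE)
  if (anyDuplicated(df$name)) {
    stop(sprintf("duplicate gate names: %s",
                 paste(sQuote(unique(df$name[duplicated(df$name)])),
                       collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(df$lower)) || any(is.na(df$upper)) ||
      any(df$lower >= df$upper)) {
    stop("every gate needs lower < upper (use -Inf/Inf for open bounds)",
         call. = FALSE)
  }
  df <- df[order(df$lower, df$upper), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L) {
    bad <- which(df$lower[-1L] < df$upper[-nrow(df)])
    if (length(bad) > 0L) {
      i <- bad[1L]
      stop(sprintf("gates '%s' and '%s' overlap ([%g, %g) vs [%g, %g))",
                   df$name[i], df$name[i + 1L], df$lower[i], df$upper[i],
                   df$lower[i + 1L], df$upper[i + 1L]), call. = FALSE)
    }
  }
  structure(df, axis = axis, class = c("gate_set", "data.frame"))
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("<gate_set> %d gates on axis '%s'\n", nrow(x), attr(x, "axis")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a gate set from a YAML file
#'
#' Expects a YAML list of mappings with keys `name`, `lower`, `upper`;
#' the strings `"inf"` / `"-inf"` (any case, ASCII or minus sign) are
#' accepted as unbounded ends.
#'
#' @param path YAML file path.
#' @param axis passed through to [make_gates()].
#' @return a `gate_set`.
#' @export
gates_from_yaml <- function(path, axis = "measurement") {
  raw <- yaml::read_yaml(path)
  as_bound <- function(x) {
    if (is.character(x)) {
      x <- gsub("−", "-", trimws(tolower(x)))
      if (x %in% c("inf", "+inf")) return(Inf)
      if (x == "-inf") return(-Inf)
      return(as.numeric(x))
    }
    as.numeric(x)
  }
  spec <- lapply(raw, function(g) list(name = g$name,
                                       lower = as_bound(g$lower),
                                       upper = as_bound(g$upper)))
  make_gates(spec, axis = axis)
}

# Gate index per value: 0 = ungated. Gates are disjoint so a loop over gates
# assigns each value at most once.
gate_index <- function(values, gates) {
  idx <- integer(length(values))
  for (g in seq_len(nrow(gates))) {
    hit <- values >= gates$lower[g] & values < gates$upper[g]
    idx[hit] <- g
  }
  idx
}

#' Count values per gate
#'
#' Assigns each value to at most one gate (`[lower, upper)`); values in no
#' gate are counted as ungated, so gate counts plus the ungated count always
#' equal the number of values. Fractions are relative to the total number of
#' values.
#'
#' @param values numeric vector.
#' @param gates a [make_gates()] gate set.
#' @return list with `counts` (named integer), `fractions` (named numeric),
#'   `ungated_count` and `n`.
#' @export
apply_gates <- function(values, gates) {
  stopifnot(inherits(gates, "gate_set"))
  values <- as.numeric(values)
  idx <- gate_index(values, gates)
  counts <- tabulate(idx[idx > 0L], nbins = nrow(gates))
  names(counts) <- gates$name
  n <- length(values)
  fractions <- if (n > 0L) counts / n else stats::setNames(rep(0, nrow(gates)),
                                                           gates$name)
  list(counts = counts,
       fractions = stats::setNames(as.numeric(fractions), gates$name),
       ungated_count = sum(idx == 0L),
       n = n)
}
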