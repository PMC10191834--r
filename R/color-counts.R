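#' Color-count table
#'
#' Container for the outcome of a multicolor co-transduction experiment:
#' the number of cells expressing exactly 0, 1, ..., k distinct
#' fluorescent reporters. These are the counts `r_0 ... r_k` that the
#' lambda estimator inverts.
#'
#' @param counts Integer vector of length `k + 1`; element `i + 1` is the
#'   number of cells expressing exactly `i` distinct reporters.
#' @param k Number of reporters (colors); defaults to `length(counts) - 1`.
#'   Must be at least 2.
#' @param label Free-text label (dose, brain area, ...).
#' @param dose Optional positive dose (e.g. vector genomes per dish),
#'   used by dose-series extrapolation.
#' @return An object of class `color_count_table` with fields `counts`,
#'   `k`, `label`, `dose` and derived total `n_cells`.
#' @examples
#' tab <- color_count_table(c(14, 77, 184, 1475), label = "1e10 vg/dish")
#' estimate_lambda(tab)
#' @export
color_count_table <- function(counts, k = length(counts) - 1L,
                              label = NA_character_, dose = NA_real_) {
  if (!is_count_vector(counts)) {
    stop_invalid("`counts` must be non-negative integers")
  }
  k <- as.integer(k)
  if (k < 2L) stop_invalid("`k` must be >= 2")
  if (length(counts) != k + 1L) {
    stop_invalid("`counts` must have length k + 1 = ", k + 1L)
  }
  if (!is.na(dose) && dose <= 0) stop_invalid("`dose` must be positive")
  structure(
    list(counts = as.numeric(round(counts)), k = k,
         label = as.character(label), dose = as.numeric(dose),
         n_cells = sum(counts)),
    class = "color_count_table"
  )
}

#' @export
print.color_count_table <- function(x, ...) {
  cat("Color-count table", if (!is.na(x$label)) paste0(" [", x$label, "]"),
      "\n", sep = "")
  if (!is.na(x$dose)) cat("  dose:", format(x$dose, scientific = TRUE), "\n")
  cls <- paste0(seq_len(x$k + 1L) - 1L, "-color")
  pct <- color_count_percentages(x)
  cat(paste0("  ", format(cls, width = 8), " ",
             format(x$counts, width = 6), "  (", sprintf("%.2f", pct), "%)",
             collapse = "\n"), "\n")
  cat("  total  ", sum(x$counts), "cells\n")
  invisible(x)
}

#' Percentage breakdown of a color-count table
#'
#' Class percentages at 2 decimals with half-up rounding, matching the
#' usual presentation of co-transduction tables.
#'
#' @param table A [color_count_table()].
#' @return Numeric vector of percentages over classes `0..k`.
#' @export
color_count_percentages <- function(table) {
  stopifnot(inherits(table, "color_count_table"))
  n <- sum(table$counts)
  if (n == 0) stop_degenerate("empty table: no cells")
  round_half_up(100 * table$counts / n, 2L)
}

#' Dose series of color-count tables
#'
#' Ordered collection of tables observed at strictly increasing doses,
#' the input to dose-extrapolation lower bounds.
#'
#' @param tables List of [color_count_table()] objects, each with a
#'   finite positive `dose`.
#' @return An object of class `dose_series`.
#' @export
dose_series <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L) {
    stop_invalid("a dose series needs at least 2 tables")
  }
  ok <- vapply(tables, inherits, logical(1), "color_count_table")
  if (!all(ok)) stop_invalid("all entries must be color_count_table objects")
  doses <- vapply(tables, function(t) t$dose, numeric(1))
  if (anyNA(doses) || any(doses <= 0)) {
    stop_invalid("every table in a dose series needs a positive dose")
  }
  o <- order(doses)
  doses <- doses[o]
  if (any(diff(doses) <= 0)) stop_invalid("doses must be strictly increasing")
  ks <- vapply(tables, function(t) t$k, integer(1))
  if (length(unique(ks)) != 1L) stop_invalid("tables disagree on k")
  structure(list(tables = tables[o], doses = doses, k = ks[1]),
            class = "dose_series")
}

#' Read color-count tables from CSV
#'
#' Expects a header `label,dose,r0,r1,...,rk` (extra `r` columns give
#' higher `k`). Additional columns are carried through untouched in the
#' returned data frame attribute but ignored for estimation.
#'
#' @param path CSV file path.
#' @return A list of [color_count_table()] objects, one per row.
#' @export
read_color_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rcols <- grep("^r[0-9]+$", names(df), value = TRUE)
  if (length(rcols) < 3L) {
    stop_invalid("counts CSV needs columns r0..rk with k >= 2")
  }
  rcols <- rcols[order(as.integer(sub("^r", "", rcols)))]
  lab <- if ("label" %in% names(df)) as.character(df$label) else
    rep(NA_character_, nrow(df))
  dose <- if ("dose" %in% names(df)) as.numeric(df$dose) else
    rep(NA_real_, nrow(df))
  out <- lapply(seq_len(nrow(df)), function(i) {
    color_count_table(as.numeric(df[i, rcols]), label = lab[i], dose = dose[i])
  })
  attr(out, "extra") <- df[setdiff(names(df), c("label", "dose", rcols))]
  out
}

#' Write color-count tables to CSV
#'
#' @param tables A single [color_count_table()] or a list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_color_counts <- function(tables, path) {
  if (inherits(tables, "color_count_table")) tables <- list(tables)
  k <- tables[[1]]$k
  rows <- lapply(tables, function(t) {
    stopifnot(t$k == k)
    cnt <- as.list(t$counts)
    names(cnt) <- paste0("r", 0:k)
    c(list(label = t$label, dose = t$dose), cnt)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
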