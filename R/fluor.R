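# Per-cell fluorescence correction, color calling, tabulation, and
# mixture composition.
#
# Measurement tables are long-format data frames with columns
#   cell_id, channel, integrated_density, roi_area, background_mean
# (one row per cell x channel).

default_channels <- function(k = 3L) {
  base <- c("EGFP", "mCherry", "mTurq2")
  if (k <= 3L) base[seq_len(k)] else c(base, paste0("ch", 4:k))
}

validate_measurements <- function(measurements) {
  need <- c("cell_id", "channel", "integrated_density", "roi_area",
            "background_mean")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    stop_invalid("measurement table needs columns: ",
                 paste(need, collapse = ", "))
  }
  if (any(!is.finite(measurements$roi_area)) ||
      any(measurements$roi_area <= 0)) {
    stop_invalid("roi_area must be finite and > 0")
  }
  if (any(measurements$background_mean < 0)) {
    stop_invalid("background_mean must be >= 0")
  }
  # every cell must carry the same channel set
  tab <- table(measurements$cell_id, measurements$channel)
  if (any(tab != 1L)) {
    stop_invalid("each cell needs exactly one row per channel")
  }
  invisible(measurements)
}

#' Corrected total cell fluorescence (CTCF)
#'
#' Background-corrected integrated fluorescence of a cell ROI:
#' `integrated_density - roi_area * background_mean`. May be negative
#' when the background estimate exceeds the signal.
#'
#' @param integrated_density Summed pixel intensity over the ROI (a.u.).
#' @param roi_area ROI area in pixels^2; must be positive.
#' @param background_mean Mean background intensity per pixel (a.u.).
#' @return CTCF in arbitrary units; vectorized over its arguments.
#' @examples
#' ctcf(1000, 50, 4) # 800
#' @export
ctcf <- function(integrated_density, roi_area, background_mean) {
  if (any(!is.finite(integrated_density)) || any(!is.finite(roi_area)) ||
      any(!is.finite(background_mean))) {
    stop_invalid("all CTCF inputs must be finite")
  }
  if (any(roi_area <= 0)) stop_invalid("roi_area must be > 0")
  integrated_density - roi_area * background_mean
}

# CTCF per row of a long measurement table, plus wide reshape.
ctcf_wide <- function(measurements) {
  validate_measurements(measurements)
  measurements$ctcf <- ctcf(measurements$integrated_density,
                            measurements$roi_area,
                            measurements$background_mean)
  channels <- unique(as.character(measurements$channel))
  ids <- unique(measurements$cell_id)
  wide <- matrix(NA_real_, nrow = length(ids), ncol = length(channels),
                 dimnames = list(NULL, channels))
  idx_i <- match(measurements$cell_id, ids)
  idx_j <- match(as.character(measurements$channel), channels)
  wide[cbind(idx_i, idx_j)] <- measurements$ctcf
  list(cell_id = ids, ctcf = wide, channels = channels)
}

#' Calibrate per-channel expression thresholds
#'
#' Sets each channel's threshold to `mean + z * sd` of CTCF values from
#' negative-control (non-transduced) cells, operationalizing
#' normalization against the background intensity of non-fluorescent
#' cells.
#'
#' @param negative_control_ctcf Named list of numeric CTCF vectors, one
#'   per channel, each with at least 2 values; or a long measurement
#'   table of control cells.
#' @param z Number of control standard deviations above the control
#'   mean (default 3).
#' @return A `threshold_policy`: named numeric vector of thresholds with
#'   provenance attributes.
#' @export
calibrate_threshold <- function(negative_control_ctcf, z = 3) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z < 0) {
    stop_invalid("`z` must be a single finite value >= 0")
  }
  if (is.data.frame(negative_control_ctcf)) {
    w <- ctcf_wide(negative_control_ctcf)
    negative_control_ctcf <- lapply(seq_along(w$channels),
                                    function(j) w$ctcf[, j])
    names(negative_control_ctcf) <- w$channels
  }
  if (!is.list(negative_control_ctcf) ||
      is.null(names(negative_control_ctcf))) {
    stop_invalid("controls must be a named list of per-channel CTCF values")
  }
  lens <- lengths(negative_control_ctcf)
  if (any(lens < 2L)) {
    stop_invalid("need >= 2 control values per channel")
  }
  thr <- vapply(negative_control_ctcf,
                function(v) mean(v) + z * stats::sd(v), numeric(1))
  structure(thr, class = "threshold_policy", provenance = "z_score", z = z)
}

#' Fixed thresholds
#'
#' @param thresholds Named numeric vector of per-channel CTCF cutoffs.
#' @return A `threshold_policy` with provenance `"fixed"`.
#' @export
fixed_threshold <- function(thresholds) {
  if (!is.numeric(thresholds) || is.null(names(thresholds)) ||
      any(!is.finite(thresholds))) {
    stop_invalid("`thresholds` must be a named finite numeric vector")
  }
  structure(thresholds, class = "threshold_policy", provenance = "fixed")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("Threshold policy (", attr(x, "provenance"), ")\n", sep = "")
  for (ch in names(x)) cat(sprintf("  %-10s %.4g\n", ch, unclass(x)[ch]))
  invisible(x)
}

#' Call expressed colors per cell
#'
#' A channel is called expressed when its CTCF strictly exceeds the
#' channel threshold (ties are negative, a deliberately conservative
#' rule).
#'
#' @param measurements Long-format measurement table.
#' @param policy A `threshold_policy` covering every channel present.
#' @return Data frame with `cell_id`, one logical column per channel,
#'   and `n_colors`.
#' @export
classify_cells <- function(measurements, policy) {
  if (!inherits(policy, "threshold_policy")) {
    stop_invalid("`policy` must be a threshold_policy")
  }
  w <- ctcf_wide(measurements)
  missing_ch <- setdiff(w$channels, names(policy))
  if (length(missing_ch)) {
    stop_invalid("policy lacks thresholds for: ",
                 paste(missing_ch, collapse = ", "))
  }
  thr <- unclass(policy)[w$channels]
  flags <- sweep(w$ctcf, 2L, thr, `>`)
  out <- data.frame(cell_id = w$cell_id)
  for (j in seq_along(w$channels)) out[[w$channels[j]]] <- flags[, j]
  out$n_colors <- rowSums(flags)
  out
}

#' Tabulate color calls into a color-count table
#'
#' @param calls Output of [classify_cells()] (needs an `n_colors`
#'   column).
#' @param label,dose Passed to [color_count_table()].
#' @param k Number of colors; defaults to the number of channel columns.
#' @return A [color_count_table()].
#' @export
tabulate_counts <- function(calls, label = NA_character_, dose = NA_real_,
                            k = NULL) {
  if (!is.data.frame(calls) || !"n_colors" %in% names(calls) ||
      nrow(calls) == 0L) {
    stop_invalid("`calls` must be a non-empty data frame with n_colors")
  }
  if (is.null(k)) {
    k <- sum(vapply(calls, is.logical, logical(1)))
    if (k < 2L) k <- max(calls$n_colors, 2L)
  }
  counts <- tabulate(calls$n_colors + 1L, nbins = k + 1L)
  color_count_table(counts, k = k, label = label, dose = dose)
}

#' Per-cell color mixture composition
#'
#' Fraction of each cell's total positive CTCF attributable to each
#' channel. Negative CTCF values are clamped to zero before
#' normalization; cells whose clamped total is zero have no defined
#' composition and are dropped (their ids are recorded in the
#' `"dropped"` attribute).
#'
#' @param measurements Long-format measurement table.
#' @return Data frame with `cell_id` and one fraction column per
#'   channel, each row summing to 1.
#' @export
mixture_fractions <- function(measurements) {
  w <- ctcf_wide(measurements)
  clamped <- pmax(w$ctcf, 0)
  tot <- rowSums(clamped)
  keep <- tot > 0
  if (!any(keep)) {
    stop_degenerate("no cell has positive total CTCF; composition undefined")
  }
  fr <- clamped[keep, , drop = FALSE] / tot[keep]
  out <- data.frame(cell_id = w$cell_id[keep])
  for (j in seq_along(w$channels)) out[[w$channels[j]]] <- fr[, j]
  attr(out, "dropped") <- w$cell_id[!keep]
  out
}

#' Read / write long-format measurement tables
#'
#' CSV schema: `cell_id,channel,integrated_density,roi_area,background_mean`.
#'
#' @param path CSV path.
#' @return `read_measurements()` returns the validated data frame.
#' @export
read_measurements <- function(path) {
  validate_measurements(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_measurements
#' @param measurements Measurement table to write.
#' @export
write_measurements <- function(measurements, path) {
  validate_measurements(measurements)
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
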