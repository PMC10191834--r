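# Ternary composition coordinates and boundary-reflected densities of
# color-mixture percentages.

#' Barycentric ternary coordinates
#'
#' Maps composition fractions (a, b, c) summing to 1 onto the reference
#' triangle with vertices (0,0), (1,0), (1/2, sqrt(3)/2):
#' `x = b + c/2`, `y = (sqrt(3)/2) c`. Single-color cells land on
#' vertices, two-color cells on edges, three-color mixtures inside.
#'
#' @param fractions Numeric vector of length 3, or a composition data
#'   frame from [mixture_fractions()] (cell_id + 3 fraction columns).
#' @param tol Tolerance on `sum(fractions) == 1`.
#' @return Data frame with columns `x`, `y` (and `cell_id` when given a
#'   composition table).
#' @export
ternary_coordinates <- function(fractions, tol = 1e-8) {
  if (is.data.frame(fractions)) {
    chans <- setdiff(names(fractions), "cell_id")
    if (length(chans) != 3L) {
      stop_invalid("ternary coordinates need exactly 3 channels")
    }
    mat <- as.matrix(fractions[chans])
    ids <- fractions$cell_id
  } else {
    if (length(fractions) != 3L) stop_invalid("need 3 fractions")
    mat <- matrix(fractions, nrow = 1)
    ids <- NULL
  }
  if (any(mat < -tol) || any(abs(rowSums(mat) - 1) > tol)) {
    stop_invalid("fractions must be non-negative and sum to 1")
  }
  out <- data.frame(x = mat[, 2] + mat[, 3] / 2,
                    y = sqrt(3) / 2 * mat[, 3])
  if (!is.null(ids)) out <- cbind(data.frame(cell_id = ids), out)
  out
}

#' Boundary-reflected kernel density of mixture percentages
#'
#' Gaussian kernel density on the compact support [0, 100] with mass
#' reflected at both boundaries, so the curve integrates to 1 without
#' the edge bias of an unbounded estimator.
#'
#' @param percentages Numeric values in `[0, 100]`, at least 2.
#' @param bandwidth Kernel SD in percentage points, or `"auto"` for
#'   Silverman's rule ([stats::bw.nrd0()]).
#' @param n_grid Number of evaluation points over `[0, 100]`.
#' @param label Optional channel label carried on the result.
#' @return A `density_curve`: data frame with `grid`, `density`, and
#'   attributes `bandwidth`, `label`, `mode` (grid argmax).
#' @export
density_estimate <- function(percentages, bandwidth = "auto",
                             n_grid = 512L, label = NA_character_) {
  x <- as.numeric(percentages)
  if (length(x) < 2L) stop_invalid("need at least 2 values")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100)) {
    stop_invalid("percentages must lie in [0, 100]")
  }
  if (identical(bandwidth, "auto")) {
    bandwidth <- stats::bw.nrd0(x)
    if (bandwidth <= 0) bandwidth <- 1
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop_invalid("`bandwidth` must be positive")
  }
  # refine the grid until it resolves the kernel (spacing <= h / 2),
  # so the curve's Riemann sum conserves mass
  n_grid <- max(n_grid, ceiling(200 / bandwidth) + 1L)
  grid <- seq(0, 100, length.out = n_grid)
  # reflect sample at 0 and 100, then restrict to the support
  dens <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = x, sd = bandwidth) +
           stats::dnorm(g, mean = -x, sd = bandwidth) +
           stats::dnorm(g, mean = 200 - x, sd = bandwidth))
  }, numeric(1))
  out <- data.frame(grid = grid, density = dens)
  structure(out, class = c("density_curve", "data.frame"),
            bandwidth = bandwidth, label = label,
            mode = grid[which.max(dens)])
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf(
    "Density curve%s: %d grid points, bandwidth %.3g, mode at %.2f%%\n",
    if (!is.na(attr(x, "label"))) paste0(" [", attr(x, "label"), "]") else "",
    nrow(x), attr(x, "bandwidth"), attr(x, "mode")))
  invisible(x)
}

#' Mode of a density curve
#'
#' @param curve A `density_curve`.
#' @return Grid location (%) of the density maximum.
#' @export
density_mode <- function(curve) {
  stopifnot(inherits(curve, "density_curve"))
  attr(curve, "mode")
}

#' Plot ternary compositions
#'
#' Scatter of per-cell compositions inside the reference triangle,
#' written to a PNG or SVG file.
#'
#' @param fractions Composition table (see [ternary_coordinates()]).
#' @param path Output file; extension selects the device (.png/.svg).
#' @param point_cex Marker size.
#' @return The path, invisibly.
#' @export
plot_ternary <- function(fractions, path, point_cex = 0.3) {
  pts <- ternary_coordinates(fractions)
  if (nrow(pts) == 0L) stop_invalid("no points to plot")
  labels <- if (is.data.frame(fractions)) {
    setdiff(names(fractions), "cell_id")
  } else c("a", "b", "c")
  open_device(path, width = 5, height = 4.6)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot(NA, xlim = c(-0.08, 1.08), ylim = c(-0.08, 0.95),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  tri <- cbind(c(0, 1, 0.5, 0), c(0, 0, sqrt(3) / 2, 0))
  graphics::lines(tri, col = "grey30")
  graphics::points(pts$x, pts$y, pch = 16, cex = point_cex,
                   col = grDevices::adjustcolor("blue", 0.4))
  vert <- rbind(c(0, -0.05), c(1, -0.05), c(0.5, sqrt(3) / 2 + 0.05))
  graphics::text(vert[, 1], vert[, 2], labels, cex = 0.9)
  invisible(path)
}

#' Plot density curves
#'
#' @param curves A `density_curve` or list of them.
#' @param path Output file (.png/.svg).
#' @return The path, invisibly.
#' @export
plot_density_curves <- function(curves, path) {
  if (inherits(curves, "density_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop_invalid("no curves to plot")
  open_device(path, width = 5.5, height = 4)
  on.exit(grDevices::dev.off())
  ymax <- max(vapply(curves, function(c) max(c$density), numeric(1)))
  graphics::plot(NA, xlim = c(0, 100), ylim = c(0, ymax * 1.05),
                 xlab = "color mixture (%)", ylab = "probability density")
  cols <- grDevices::hcl.colors(max(3L, length(curves)), "Dark 3")
  for (i in seq_along(curves)) {
    graphics::lines(curves[[i]]$grid, curves[[i]]$density, col = cols[i],
                    lwd = 2)
  }
  labs <- vapply(curves, function(c) {
    l <- attr(c, "label"); if (is.na(l)) "channel" else l
  }, character(1))
  graphics::legend("topright", legend = labs, col = cols[seq_along(curves)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(path)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_invalid("directory does not exist: ", dir)
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height),
         stop_invalid("unsupported figure format: .", ext))
}

#' Export density curves as CSV
#'
#' Schema: `grid,density,channel`.
#'
#' @inheritParams plot_density_curves
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_density_curves <- function(curves, path) {
  if (inherits(curves, "density_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(c) {
    data.frame(grid = c$grid, density = c$density,
               channel = attr(c, "label"))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
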