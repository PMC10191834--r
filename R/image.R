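# Synthetic multi-channel image rendering and ROI quantification.
#
# Images are numeric arrays [height, width, channel]; masks are integer
# matrices labeling pixels by cell id (0 = background). This stands in
# for confocal acquisition so the quantification path can be exercised
# end to end.

# Zero-padded separable Gaussian blur of a matrix.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  conv1 <- function(m, along_rows) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(g)) {
      off <- i - r - 1L
      if (along_rows) {
        src <- seq_len(nrow(m)) + off
        ok <- src >= 1L & src <= nrow(m)
        out[ok, ] <- out[ok, ] + g[i] * m[src[ok], , drop = FALSE]
      } else {
        src <- seq_len(ncol(m)) + off
        ok <- src >= 1L & src <= ncol(m)
        out[, ok] <- out[, ok] + g[i] * m[, src[ok], drop = FALSE]
      }
    }
    out
  }
  conv1(conv1(mat, TRUE), FALSE)
}

#' Render a synthetic multi-channel image
#'
#' Places each cell as a uniform disk (rejection-sampled to avoid
#' overlap), spreads its per-channel intensity over the disk, convolves
#' with a Gaussian point-spread function, adds a per-pixel truncated
#' normal background field, and optionally applies Poisson shot noise.
#'
#' @param truth Ground-truth table from [simulate_cells()] /
#'   [simulate_genome_counts()].
#' @param config A [simulation_config()] with a non-NULL `image` block.
#' @param seed Seed for placement/noise; defaults to `config$seed + 2`.
#' @return List with `image` (array height x width x k), `mask` (integer
#'   matrix of cell ids), and `placement` (data frame cell_id, row, col,
#'   radius, and per-channel rendered intensities `I_<channel>`).
#' @export
render_image <- function(truth, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$image)) stop_invalid("config has no image options")
  opt <- config$image
  k <- config$k
  n <- nrow(truth)
  h <- opt$canvas[1]; w <- opt$canvas[2]
  m <- as.matrix(truth[paste0("m_", config$channels)])
  with_seed(seed, {
    # per-cell per-channel rendered intensity (same noise law as tables)
    noise <- matrix(stats::rlnorm(n * k, 0, config$noise_sigma), n, k)
    intensity <- sweep(m * noise, 2L, config$brightness, `*`)
    radius <- stats::runif(n, opt$radius_range[1], opt$radius_range[2])
    # non-overlapping placement by rejection sampling
    pos <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(opt$max_tries)) {
        r_i <- radius[i]
        cand <- c(stats::runif(1, 1 + r_i, h - r_i),
                  stats::runif(1, 1 + r_i, w - r_i))
        if (i == 1L) { ok <- TRUE } else {
          prev <- seq_len(i - 1L)
          d2 <- (pos[prev, 1] - cand[1])^2 + (pos[prev, 2] - cand[2])^2
          ok <- all(d2 > (radius[prev] + r_i + 1)^2)
        }
        if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) {
        stop_degenerate("could not place cell ", i, " after ", opt$max_tries,
                        " tries; use a larger canvas or fewer cells")
      }
    }
    mask <- matrix(0L, h, w)
    signal <- array(0, dim = c(h, w, k))
    for (i in seq_len(n)) {
      rr <- max(1L, floor(pos[i, 1] - radius[i])):min(h, ceiling(pos[i, 1] + radius[i]))
      cc <- max(1L, floor(pos[i, 2] - radius[i])):min(w, ceiling(pos[i, 2] + radius[i]))
      d2 <- outer((rr - pos[i, 1])^2, (cc - pos[i, 2])^2, `+`)
      inside <- d2 <= radius[i]^2
      npix <- sum(inside)
      if (npix == 0L) stop_degenerate("cell ", i, " rasterized to zero pixels")
      mask[rr, cc][inside] <- truth$cell_id[i]
      for (ch in seq_len(k)) {
        layer <- signal[rr, cc, ch]
        layer[inside] <- layer[inside] + intensity[i, ch] / npix
        signal[rr, cc, ch] <- layer
      }
    }
    if (opt$psf_sigma > 0) {
      for (ch in seq_len(k)) {
        signal[, , ch] <- gaussian_blur(signal[, , ch], opt$psf_sigma)
      }
    }
    img <- signal
    for (ch in seq_len(k)) {
      bg <- matrix(rtruncnorm0(h * w, config$background_mean,
                               config$background_sd), h, w)
      img[, , ch] <- img[, , ch] + bg
    }
    if (isTRUE(opt$shot_noise)) {
      img[] <- stats::rpois(length(img), lambda = pmax(img, 0))
    }
    placement <- data.frame(cell_id = truth$cell_id,
                            row = pos[, 1], col = pos[, 2], radius = radius)
    for (ch in seq_len(k)) {
      placement[[paste0("I_", config$channels[ch])]] <- intensity[, ch]
    }
    list(image = img, mask = mask, placement = placement)
  })
}

#' Quantify cells from an image and a labeled mask
#'
#' Per cell and channel: `integrated_density` is the pixel sum over the
#' cell's mask region, `roi_area` its pixel count, and `background_mean`
#' the per-channel mean over mask-zero pixels (the image-analysis
#' convention of reading background from non-fluorescent regions).
#'
#' @param image Numeric array height x width x k.
#' @param mask Integer matrix of matching height/width; 0 = background.
#' @param channels Channel names (default built-in reporter names).
#' @return Long-format measurement table (see [read_measurements()]).
#' @export
quantify_image <- function(image, mask,
                           channels = default_channels(dim(image)[3])) {
  d <- dim(image)
  if (length(d) != 3L) stop_invalid("`image` must be a 3-d array")
  if (!all(dim(mask) == d[1:2])) {
    stop_invalid("mask dimensions do not match image")
  }
  if (length(channels) != d[3]) stop_invalid("need one name per channel")
  bgpix <- mask == 0L
  if (!any(bgpix)) {
    stop_degenerate("mask has no background pixels; cannot estimate background")
  }
  ids <- sort(unique(mask[mask != 0L]))
  rows <- lapply(seq_len(d[3]), function(ch) {
    layer <- image[, , ch]
    sums <- as.numeric(tapply(layer[mask != 0L], mask[mask != 0L], sum))
    areas <- as.numeric(table(mask[mask != 0L]))
    data.frame(cell_id = ids, channel = channels[ch],
               integrated_density = sums, roi_area = areas,
               background_mean = mean(layer[bgpix]))
  })
  do.call(rbind, rows)
}

#' Plain-text image serialization
#'
#' Interchange format for synthetic images and masks (no binary TIFF
#' dependency): a header line `height width channels` followed by all
#' values in column-major order, one per line.
#'
#' @param image Numeric array (h x w x k) or matrix (mask).
#' @param path Output path.
#' @return The path (write) or the reconstructed array/matrix (read).
#' @export
write_image_text <- function(image, path) {
  d <- dim(image)
  if (length(d) == 2L) d <- c(d, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(d, collapse = " "), con)
  writeLines(format(as.vector(image), trim = TRUE, digits = 12,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_image_text
#' @export
read_image_text <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  d <- as.integer(strsplit(readLines(con, n = 1L), " ")[[1]])
  vals <- as.numeric(readLines(con))
  if (length(vals) != prod(d)) stop_invalid("corrupt image file: ", path)
  if (d[3] == 1L) matrix(vals, d[1], d[2]) else array(vals, dim = d)
}
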