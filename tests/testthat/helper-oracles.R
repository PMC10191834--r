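# Independent oracles and fixture builders used across the suite.

# Half-up rounding to the printed table precision.
round_half_up <- function(x, digits = 0L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# Truncated-enumeration oracle for the color-class distribution:
# enumerate per-color genome-count vectors (m_1, ..., m_k), each
# Poisson(lambda / k) truncated where the joint mass coverage exceeds
# 1 - 1e-12, and count colors with m_c >= 1. Independent of the
# binomial shortcut used by the implementation.
oracle_color_pmf <- function(lambda, k = 3L) {
  rate <- lambda / k
  m_max <- 0L
  while (stats::ppois(m_max, rate) < 1 - 1e-13) m_max <- m_max + 1L
  probs <- stats::dpois(0:m_max, rate)
  grid <- do.call(expand.grid, rep(list(0:m_max), k))
  w <- apply(grid, 1L, function(m) prod(probs[m + 1L]))
  ncol_expr <- rowSums(grid >= 1L)
  out <- vapply(0:k, function(i) sum(w[ncol_expr == i]), numeric(1))
  out / sum(w)  # renormalize away the truncated tail
}

# Long-format measurement table from a wide CTCF-like spec, with zero
# background so integrated_density is the CTCF directly.
make_measurements <- function(ctcf_matrix,
                              channels = colnames(ctcf_matrix),
                              roi_area = 50, background_mean = 0) {
  n <- nrow(ctcf_matrix)
  data.frame(
    cell_id = rep(seq_len(n), times = ncol(ctcf_matrix)),
    channel = rep(channels, each = n),
    integrated_density = as.vector(ctcf_matrix) +
      roi_area * background_mean,
    roi_area = roi_area,
    background_mean = background_mean
  )
}

table1_counts <- function() {
  list(low = c(14, 77, 184, 1475),
       mid = c(5, 9, 52, 1707),
       high = c(0, 0, 0, 1791))
}
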