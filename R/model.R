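# Poisson/binomial co-expression model.
#
# A cell exposed to an equimolar mix of k reporter vectors expresses,
# for each color independently, a Poisson(lambda / k) number of genomes
# of that color; a color is visible when at least one of its genomes
# expresses.  The number of distinct visible colors is then
# Binomial(k, p) with p = 1 - exp(-lambda / k).

#' Per-color expression probability
#'
#' Probability that a given reporter color is visible in a cell when the
#' mean number of expressed genomes per cell is `lambda` and the mix is
#' equimolar over `k` colors: `p = 1 - exp(-lambda / k)`.
#'
#' @param lambda Mean expressed genomes per cell, `>= 0`.
#' @param k Number of reporter colors, integer `>= 2`.
#' @return Probability in `[0, 1)`; strictly increasing in `lambda`.
#' @examples
#' expression_probability(3 * log(2), 3) # exactly 0.5
#' @export
expression_probability <- function(lambda, k = 3L) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda < 0)) {
    stop_invalid("`lambda` must be finite and >= 0")
  }
  k <- as.integer(k)
  if (k < 2L) stop_invalid("`k` must be >= 2")
  -expm1(-lambda / k)
}

#' Expression model
#'
#' Bundles `lambda`, the number of colors `k`, the derived per-color
#' expression probability, and the distribution of the number of
#' distinct colors a cell expresses.
#'
#' @inheritParams expression_probability
#' @return An object of class `expression_model` with fields `lambda`,
#'   `k`, `p`, and `class_probs` (probabilities of expressing exactly
#'   `0..k` colors).
#' @export
expression_model <- function(lambda, k = 3L) {
  p <- expression_probability(lambda, k)
  k <- as.integer(k)
  structure(
    list(lambda = lambda, k = k, p = p,
         class_probs = stats::dbinom(0:k, size = k, prob = p)),
    class = "expression_model"
  )
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf("Expression model: lambda = %.4g, k = %d, p = %.4g\n",
              x$lambda, x$k, x$p))
  cat("  P(exactly i colors):",
      paste(sprintf("%.4g", x$class_probs), collapse = ", "), "\n")
  invisible(x)
}

#' Distribution of the number of expressed colors
#'
#' Probability that a cell expresses exactly `0, 1, ..., k` distinct
#' colors: `Binomial(k, p)` with `p = 1 - exp(-lambda / k)`.
#'
#' @param lambda Mean expressed genomes per cell, or an
#'   [expression_model()] (in which case `k` is ignored).
#' @param k Number of reporter colors.
#' @return Numeric probability vector over classes `0..k`, summing to 1.
#' @export
color_count_pmf <- function(lambda, k = 3L) {
  if (inherits(lambda, "expression_model")) return(lambda$class_probs)
  expression_model(lambda, k)$class_probs
}

#' Expected color-count table
#'
#' Forward model: expected number of cells in each color class for a
#' given `lambda` and sample size.
#'
#' @inheritParams color_count_pmf
#' @param n_cells Number of cells, `>= 0`.
#' @return Numeric vector over classes `0..k`, summing to `n_cells`.
#' @export
expected_counts <- function(lambda, n_cells, k = 3L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0) {
    stop_invalid("`n_cells` must be a single non-negative number")
  }
  n_cells * color_count_pmf(lambda, k)
}

#' Asymptotic standard error of the lambda estimator
#'
#' Delta-method standard error of the plug-in estimator: the mean number
#' of expressed colors per cell has variance `k p (1 - p) / n`, and the
#' estimator's derivative with respect to that mean is `exp(lambda / k)`.
#'
#' @inheritParams expression_probability
#' @param n_cells Number of cells counted.
#' @return Approximate standard error of the lambda estimate.
#' @export
lambda_se <- function(lambda, n_cells, k = 3L) {
  p <- expression_probability(lambda, k)
  exp(lambda / k) * sqrt(k * p * (1 - p) / n_cells)
}
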