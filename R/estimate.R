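# Inversion estimator for lambda, bootstrap uncertainty, and lower
# bounds for saturated samples.

new_lambda_estimate <- function(lambda_hat, method, saturated,
                                ci_low = NA_real_, ci_high = NA_real_,
                                alpha = NA_real_, n_cells = NA_real_,
                                label = NA_character_, extra = list()) {
  structure(
    c(list(lambda_hat = lambda_hat, ci_low = ci_low, ci_high = ci_high,
           method = method, alpha = alpha, saturated = saturated,
           n_cells = n_cells, label = label), extra),
    class = "lambda_estimate"
  )
}

#' @export
print.lambda_estimate <- function(x, ...) {
  if (x$saturated && !is.finite(x$lambda_hat)) {
    cat("Lambda estimate: saturated (lambda -> Inf); use lambda_lower_bound()\n")
  } else {
    cat(sprintf("Lambda estimate: %.4g", x$lambda_hat))
    if (!is.na(x$ci_low)) {
      cat(sprintf("  [%.4g, %.4g]", x$ci_low, x$ci_high))
    }
    cat("\n")
  }
  cat("  method:", x$method)
  if (!is.na(x$alpha)) cat(sprintf("  (alpha = %g)", x$alpha))
  if (!is.na(x$n_cells)) cat("  n =", x$n_cells)
  cat("\n")
  invisible(x)
}

#' Estimate the mean number of expressed genomes per cell
#'
#' Inverts the binomial mean number of expressed colors: with
#' `S = sum(i * r_i)` over a color-count table with `N` cells and `k`
#' colors, the estimator is
#' \deqn{\hat\lambda = -k \, \ln\!\big(1 - S / (k N)\big).}
#' For `k = 3` this is the classic three-color co-infection estimator.
#'
#' When every cell expresses all `k` colors (`S = kN`) the point
#' estimator diverges; a saturated estimate (non-finite `lambda_hat`,
#' `saturated = TRUE`) is returned so callers can fall through to
#' [lambda_lower_bound()].
#'
#' @param counts A [color_count_table()], or a bare numeric vector of
#'   counts over classes `0..k` (fractional values are accepted here, so
#'   expected counts from the forward model can be inverted exactly).
#' @return A `lambda_estimate` with `method = "point"`.
#' @examples
#' estimate_lambda(c(14, 77, 184, 1475)) # ~7.9
#' @export
estimate_lambda <- function(counts) {
  if (inherits(counts, "color_count_table")) {
    r <- counts$counts
    k <- counts$k
    label <- counts$label
  } else {
    if (!is.numeric(counts) || length(counts) < 3L ||
        any(!is.finite(counts)) || any(counts < 0)) {
      stop_invalid("`counts` must be non-negative over classes 0..k, k >= 2")
    }
    r <- as.numeric(counts)
    k <- length(r) - 1L
    label <- NA_character_
  }
  n <- sum(r)
  if (n == 0) stop_degenerate("empty table: no cells to estimate from")
  s <- sum((0:k) * r)
  if (s == k * n) {
    return(new_lambda_estimate(Inf, method = "point", saturated = TRUE,
                               n_cells = n, label = label))
  }
  lam <- -k * log1p(-s / (k * n))
  new_lambda_estimate(lam, method = "point", saturated = FALSE,
                      n_cells = n, label = label)
}

#' Bootstrap confidence interval for lambda
#'
#' Percentile interval from multinomial resampling of the `N` counted
#' cells. Resamples that saturate (all cells express all colors) are
#' mapped to that resample's exact-binomial lower bound so the interval
#' remains defined; their frequency is reported as
#' `saturation_fraction`.
#'
#' @inheritParams estimate_lambda
#' @param n_boot Number of multinomial resamples.
#' @param level Confidence level of the percentile interval.
#' @param seed Integer seed (required; no hidden global RNG).
#' @param alpha_saturated Alpha used for the lower bound substituted for
#'   saturated resamples.
#' @return A `lambda_estimate` with `ci_low`/`ci_high` and a
#'   `saturation_fraction` field.
#' @export
bootstrap_ci <- function(counts, n_boot = 10000L, level = 0.95, seed,
                         alpha_saturated = 0.05) {
  if (!inherits(counts, "color_count_table")) {
    counts <- color_count_table(counts)
  }
  if (missing(seed)) stop_invalid("`seed` is required")
  if (level <= 0 || level >= 1) stop_invalid("`level` must be in (0, 1)")
  r <- counts$counts
  k <- counts$k
  n <- sum(r)
  if (n == 0) stop_degenerate("empty table")
  if (sum((0:k) * r) == k * n) {
    stop_degenerate("saturated table: use lambda_lower_bound()")
  }
  point <- estimate_lambda(counts)
  lams <- with_seed(seed, {
    res <- stats::rmultinom(n_boot, size = n, prob = r / n)
    s <- colSums(res * (0:k))
    out <- numeric(n_boot)
    sat <- s == k * n
    out[!sat] <- -k * log1p(-s[!sat] / (k * n))
    if (any(sat)) {
      out[sat] <- saturated_lower_bound(n, k, alpha_saturated)
    }
    attr(out, "sat_frac") <- mean(sat)
    out
  })
  qs <- stats::quantile(lams, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  new_lambda_estimate(point$lambda_hat, method = "point", saturated = FALSE,
                      ci_low = qs[1], ci_high = qs[2], alpha = 1 - level,
                      n_cells = n, label = counts$label,
                      extra = list(saturation_fraction = attr(lams, "sat_frac"),
                                   n_boot = n_boot, seed = seed))
}

# Closed form for the m = 0 exact binomial bound: all N cells k-colored;
# the bound solves P(no non-k-color cell) = (1 - f)^N = alpha with
# f = 1 - p^k, i.e. p = alpha^(1 / (kN)).
saturated_lower_bound <- function(n, k, alpha) {
  p <- alpha^(1 / (k * n))
  -k * log1p(-p)
}

# Monotone bisection on [lo, hi] for g increasing with g(lo) < 0 < g(hi).
bisect_root <- function(g, lo = 1e-6, hi = 200, tol = 1e-9) {
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo > 0 || ghi < 0) {
    stop_degenerate("root not bracketed in [", lo, ", ", hi, "]")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Lower bound on lambda for saturated samples
#'
#' When every counted cell expresses all `k` reporters the point
#' estimator is infinite; two defined lower-bound procedures are
#' provided.
#'
#' `"binomial"`: let `m = N - r_k` be the number of cells *not*
#' expressing all colors and `f(lambda) = 1 - p^k` the per-cell
#' probability of that event. The bound is the `lambda` solving
#' `P(Binomial(N, f(lambda)) <= m) = alpha` (for `m = 0` this reduces to
#' `(1 - f)^N = alpha`, the "rule of three" regime). It is the smallest
#' lambda not rejected at level `alpha` by the observed shortfall of
#' non-k-color cells.
#'
#' `"extrapolation"`: fit a line to (log dose, log two-color fraction)
#' over the lower-dose tables of `series`, predict the two-color
#' fraction at `target_dose`, and invert `f2 = 3 p^2 (1 - p)` on its
#' high-lambda branch (`p > 2/3`). Only defined for `k = 3`.
#'
#' @inheritParams estimate_lambda
#' @param alpha Significance level of the bound (default 0.05).
#' @param method `"binomial"` or `"extrapolation"`.
#' @param series A [dose_series()] of non-saturated lower-dose tables
#'   (extrapolation method only).
#' @param target_dose Dose at which the bound is wanted (extrapolation
#'   method only; defaults to `counts$dose`).
#' @return A `lambda_estimate` with method tag
#'   `"lower_bound_binomial"` or `"lower_bound_extrapolation"`.
#' @export
lambda_lower_bound <- function(counts, alpha = 0.05,
                               method = c("binomial", "extrapolation"),
                               series = NULL, target_dose = NULL) {
  method <- match.arg(method)
  if (!inherits(counts, "color_count_table")) {
    counts <- color_count_table(counts)
  }
  if (alpha <= 0 || alpha >= 1) stop_invalid("`alpha` must be in (0, 1)")
  r <- counts$counts
  k <- counts$k
  n <- sum(r)
  if (n == 0) stop_degenerate("empty table")
  if (method == "binomial") {
    m <- n - r[k + 1L]
    if (m == n) {
      stop_degenerate("no cells express all ", k,
                      " colors; lower bound undefined")
    }
    # P(Binom(n, f(lambda)) <= m) increases in lambda (f decreases).
    g <- function(lam) {
      p <- expression_probability(lam, k)
      stats::pbinom(m, size = n, prob = 1 - p^k) - alpha
    }
    lam <- bisect_root(g)
    return(new_lambda_estimate(lam, method = "lower_bound_binomial",
                               saturated = r[k + 1L] == n, alpha = alpha,
                               n_cells = n, label = counts$label))
  }
  # extrapolation
  if (k != 3L) stop_invalid("extrapolation bound is defined for k = 3 only")
  if (is.null(series) || !inherits(series, "dose_series")) {
    stop_invalid("extrapolation requires a dose_series of lower-dose tables")
  }
  if (is.null(target_dose)) target_dose <- counts$dose
  if (is.null(target_dose) || is.na(target_dose) || target_dose <= 0) {
    stop_invalid("a positive target dose is required")
  }
  f2 <- vapply(series$tables, function(t) t$counts[3] / sum(t$counts),
               numeric(1))
  if (any(f2 <= 0)) stop_degenerate("two-color fraction must be positive ",
                                    "in every lower-dose table")
  fit <- stats::lm(log(f2) ~ log(series$doses))
  f2_hat <- exp(sum(stats::coef(fit) * c(1, log(target_dose))))
  # f2(p) = 3 p^2 (1-p) peaks at p = 2/3 with value 4/9; take the
  # high-lambda branch p in (2/3, 1), where f2 is decreasing.
  if (f2_hat >= 4 / 9 || f2_hat <= 0) {
    stop_degenerate("predicted two-color fraction ", signif(f2_hat, 4),
                    " outside the invertible range (0, 4/9)")
  }
  g <- function(lam) {
    p <- expression_probability(lam, 3L)
    f2_hat - 3 * p^2 * (1 - p)   # increasing in lambda on p > 2/3
  }
  lo <- -3 * log(1 / 3)  # lambda at p = 2/3
  lam <- bisect_root(g, lo = lo + 1e-9, hi = 200)
  new_lambda_estimate(lam, method = "lower_bound_extrapolation",
                      saturated = r[4] == n, alpha = NA_real_,
                      n_cells = n, label = counts$label,
                      extra = list(predicted_two_color_fraction = f2_hat))
}

#' Write lambda estimates to CSV
#'
#' Schema: `label,lambda,ci_low,ci_high,method,alpha,saturated,n_cells`.
#' Saturated point estimates are written with an empty lambda field.
#'
#' @param estimates A `lambda_estimate` or list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_lambda_estimates <- function(estimates, path) {
  if (inherits(estimates, "lambda_estimate")) estimates <- list(estimates)
  df <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(label = e$label,
               lambda = if (is.finite(e$lambda_hat)) e$lambda_hat else NA_real_,
               ci_low = e$ci_low, ci_high = e$ci_high, method = e$method,
               alpha = e$alpha, saturated = e$saturated, n_cells = e$n_cells)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
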