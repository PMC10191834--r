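# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, runs `code`, and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global
#' random stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Half-up decimal rounding (R's round() is round-half-even); used for
# the presentation-layer percentage and lambda columns.
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(abs(x - round(x)) < 1e-8)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("cotransduce_invalid", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("cotransduce_degenerate", "error")))
}
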