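# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so package functions never clobber user randomness.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Inverse of the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration. Used when
#' moment-matching the scaled-F prior of gene-wise residual variances.
#'
#' @param y positive numeric vector
#' @return numeric vector `x` with `trigamma(x)` equal to `y`
#' @examples
#' trigamma(trigamma_inverse(1.2))
#' @export
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y))
  out <- rep(NA_real_, length(y))
  for (i in seq_along(y)) {
    yi <- y[i]
    if (!is.finite(yi) || yi <= 0) {
      out[i] <- if (is.finite(yi)) Inf else NA_real_
      next
    }
    # trigamma(x) ~ 1/x + 1/(2x^2) for large x gives a good start
    x <- 0.5 + 1 / yi
    for (iter in 1:60) {
      f <- trigamma(x) - yi
      step <- f / psigamma(x, deriv = 2L)
      x_new <- x - step
      if (x_new <= 0) x_new <- x / 2
      if (abs(x_new - x) < 1e-10 * x) {
        x <- x_new
        break
      }
      x <- x_new
    }
    out[i] <- x
  }
  out
}

# Stable short hash of an R object (config fingerprints in output headers).
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# Error with a stage prefix, used by run_pipeline to localize failures.
stage_stop <- function(stage, ...) {
  stop(sprintf("stage '%s': %s", stage, paste0(..., collapse = "")),
       call. = FALSE)
}
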