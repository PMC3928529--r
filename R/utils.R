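# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Report tables in this package are rounded half away from zero (so 0.825
#' prints as 0.83), matching the convention of the monitoring reports the
#' package mirrors. Base \code{round()} rounds half to even, which differs at
#' exact midpoints.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.825, 2)  # 0.83
#' round_half_up(1.375, 2)  # 1.38
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small eps absorbs binary representation error at decimal midpoints
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-8) / scale
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

stop_nlakes <- function(...) stop(..., call. = FALSE)

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop_nlakes(sprintf("'%s' must be finite and >= 0", name))
  invisible(x)
}

# Draw lognormal noise with unit mean and the given coefficient of variation.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

log_stage <- function(stage, n_in, seed = NULL, ...) {
  extras <- list(...)
  msg <- sprintf("[%s] n=%d%s%s", stage, n_in,
                 if (is.null(seed)) "" else sprintf(" seed=%s", seed),
                 if (length(extras) == 0) "" else
                   paste0(" ", paste(names(extras), unlist(extras),
                                     sep = "=", collapse = " ")))
  message(msg)
}
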