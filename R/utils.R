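#' @keywords internal
"_PACKAGE"

expit <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Decimal rounding used for all displayed estimates. `base::round()` rounds
#' half to even; printed risks, risk ratios and NNT/NNH values in clinical
#' reports use half-away-from-zero (1/0.054 is reported as 19, not 18).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up(18.5)    # 19
#' round_half_up(-1.65, 1) # -1.7 (away from zero)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Derive a child seed from a root seed and a stream index. Keeps results
# below 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(stream)) %% 2147483647)
}

# Evaluate code under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_config(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}
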