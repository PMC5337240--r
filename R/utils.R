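#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("fpf", "llf", "label"))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(code)
}

# Trapezoidal integral of y over x (x non-decreasing).
trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Round half up (away from zero)
#'
#' Decimal rounding in which exact halves are rounded away from zero, the
#' convention used in the reported study tables (base [round()] rounds halves
#' to even). A small guard rounds away binary representation dust first, so
#' that e.g. the mean of 100.0, 81.5, 85.2, 85.2, 81.5 and 88.9 (exactly
#' 87.05 in decimal) rounds to 87.1 rather than 87.0.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.7315, 3) # 0.732
#' round_half_up(-0.0685, 3) # -0.069
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  z <- round(abs(x) * p, 8)
  sign(x) * floor(z + 0.5) / p
}

stop_undefined <- function(what, why) {
  stop(sprintf("%s is undefined: %s", what, why), call. = FALSE)
}
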