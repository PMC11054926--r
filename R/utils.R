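# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding: halves round away from zero (2.5 -> 3, -2.5 -> -3),
#' unlike [base::round()]'s round-half-to-even. All reported quantities in
#' this package use this rule; it is the only rule that reproduces the
#' published energy chain (3685.5 kcal rounds up).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
#' @examples
#' round_half_away(3685.5)      # 3686
#' round_half_away(2.345, 2)    # 2.35
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # shed floating-point dust so values representing an exact half round up
  y <- round(abs(x) * p, 9)
  sign(x) * floor(y + 0.5) / p
}

rounding_policies <- c("report_then_propagate", "full_precision")

match_rounding <- function(rounding) {
  match.arg(rounding, rounding_policies)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 104729) %% 2147483647)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
  invisible(x)
}
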