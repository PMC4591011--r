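# Internal helpers shared across modules.

#' Signal a classed pipeline error
#'
#' All user-facing errors carry a subclass so callers (and tests) can
#' distinguish failure modes without matching on message text.
#'
#' @param msg error message.
#' @param class character subclass(es), prepended to `"tsrpipe_error"`.
#' @noRd
tsr_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tsrpipe_error")))
}

#' Round half away from zero
#'
#' Report-boundary rounding. `base::round()` rounds half to even; published
#' tables in this field round halves away from zero (1.515 -> 1.52,
#' -1.515 -> -1.52), so reports use this variant. Internal computation is
#' always full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.125, -0.125), 2)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# scalar integer-ish check
is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}
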