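`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Reporting-layer rounding.  Base `round()` rounds half to even;
#' published efficiency tables conventionally round 0.4745 up to 0.475,
#' so summaries use this variant instead.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.4745, 3)
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_mraedid <- function(msg, class, data = list()) {
  cond <- structure(
    class = c(class, "mraedid_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}
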