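## Small internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used throughout reports: 12.345 -> 12.35 at 2 dp, and
#' 11.5 -> 12 at 0 dp. Internal metric values are never rounded; this is
#' applied only when formatting tables.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## stop() wrapper attaching a condition class so the CLI can map error
## families to distinct exit codes.
cxrStop <- function(msg, class = "cxr_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

isScalarNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

isScalarString <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

## Percentage formatting for display tables: value in [0,1] -> "90.80".
fmtPct <- function(p, digits = 2) {
  ifelse(is.na(p), "NA", sprintf(paste0("%.", digits, "f"), roundHalfUp(100 * p, digits)))
}
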