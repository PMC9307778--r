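#' Package logging
#'
#' Structured progress messages go to standard error and are switched on and
#' off globally with \code{options(sereg.verbose = TRUE/FALSE)} (default off).
#' Every filtering step in the pipeline reports input and surviving counts
#' through [log_filter()].
#'
#' @param ... message parts, pasted together.
#' @return Invisibly, the message string.
#' @export
sereg_log <- function(...) {
  msg <- paste0(...)
  if (isTRUE(getOption("sereg.verbose", FALSE))) {
    message("[sereg] ", msg)
  }
  invisible(msg)
}

#' @rdname sereg_log
#' @param step name of the filtering step.
#' @param n_in,n_out input and surviving record counts.
#' @export
log_filter <- function(step, n_in, n_out) {
  sereg_log(step, ": ", n_in, " in, ", n_out, " kept (",
            n_in - n_out, " removed)")
}

#' Express a ratio as a percentage
#'
#' Small reporting helper used for summary statements such as the fraction of
#' valid Hi-C contacts among all sequenced read pairs.
#'
#' @param numerator,denominator nonnegative numbers.
#' @param digits decimal places to round to (default 2).
#' @return `100 * numerator / denominator`, rounded.
#' @examples
#' as_percent(45, 60)  # 75
#' @export
as_percent <- function(numerator, denominator, digits = 2) {
  stopifnot(is.numeric(numerator), is.numeric(denominator), denominator > 0)
  round(100 * numerator / denominator, digits)
}
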