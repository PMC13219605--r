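#' Wet-bulb temperature from Stull's empirical fit
#'
#' Computes wet-bulb temperature (degrees C) from dry-bulb air temperature and
#' relative humidity using Stull's empirical inverse-psychrometric fit.  The
#' fit was derived for roughly -20..50 degrees C and relative humidity of at
#' least 5 percent at standard pressure; outside that envelope the formula is
#' still evaluated but the result carries a `flagged` attribute marking the
#' out-of-validity elements.
#'
#' @param t dry-bulb temperature, degrees C.
#' @param rh relative humidity, percent, in (0, 100].
#' @return numeric vector of wet-bulb temperatures (degrees C), with an
#'   attribute `flagged` (logical) when any input falls outside the fit's
#'   stated validity range.
#' @examples
#' stull_wbt(20, 50)
#' stull_wbt(c(30, 35), c(80, 60))
#' @export
stull_wbt <- function(t, rh) {
  if (length(t) != length(rh)) {
    n <- max(length(t), length(rh))
    t <- rep_len(t, n)
    rh <- rep_len(rh, n)
  }
  if (any(!is.finite(t)) || any(!is.finite(rh)))
    stop("stull_wbt: non-finite inputs", call. = FALSE)
  if (any(rh <= 0))
    stop("stull_wbt: relative humidity must be positive", call. = FALSE)
  if (any(rh > 100))
    stop("stull_wbt: relative humidity above 100%", call. = FALSE)
  tw <- t * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(t + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
  outside <- t < -20 | t > 50 | rh < 5
  if (any(outside)) attr(tw, "flagged") <- outside
  tw
}
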