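#' Derive named substream seeds from one root seed
#'
#' All randomness in the package flows from a single root seed; independent
#' stages (weather, demographics, labels, splits, training) each get their own
#' substream seed so that changing one stage's consumption of random numbers
#' does not perturb the others.
#'
#' @param seed integer root seed.
#' @param names character vector of substream names.
#' @return named integer vector of seeds, all below 2^31.
#' @keywords internal
substream_seeds <- function(seed, names) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  names(s) <- names
  s
}

#' Shift dates back by whole calendar years
#'
#' Feb 29 anchors map to Feb 28 in non-leap years, so the shifted date always
#' exists.
#'
#' @param dates Date vector.
#' @param j non-negative integer, number of years to subtract.
#' @return Date vector.
#' @keywords internal
shift_years <- function(dates, j) {
  lt <- as.POSIXlt(dates)
  feb29 <- lt$mon == 1L & lt$mday == 29L
  lt$year <- lt$year - as.integer(j)
  if (any(feb29)) {
    # in non-leap target years Feb 29 does not exist; pin to Feb 28
    yr <- lt$year + 1900L
    leap <- (yr %% 4L == 0L & yr %% 100L != 0L) | yr %% 400L == 0L
    lt$mday[feb29 & !leap] <- 28L
  }
  as.Date(lt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
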