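#' Mean age from a population pyramid
#'
#' Weighted average of bracket midpoints, weights being the proportion of the
#' population in each 5-year bracket.  Midpoint convention: lower bound plus
#' 2.5 years, including the open-ended top bracket.
#'
#' @param lower_bounds numeric vector of bracket lower bounds in years
#'   (5-year steps, e.g. 0, 5, ..., 95).
#' @param proportions population fraction per bracket; must be non-negative
#'   and sum to 1 (tolerance 1e-9).
#' @return mean age in years.
#' @export
mean_age <- function(lower_bounds, proportions) {
  check_pyramid(lower_bounds, proportions)
  sum((lower_bounds + 2.5) * proportions)
}

#' Age gradient of a population pyramid
#'
#' Compresses the shape of the pyramid into the slope of a least-squares line
#' where the response y is the bracket age (midpoint) and the regressor x is
#' the proportion of the population in that bracket:
#' \deqn{m = \frac{\bar x \bar y - \overline{xy}}{\bar x^2 - \overline{x^2}}}
#' Young, bottom-heavy pyramids (proportion falling with age) give a negative
#' slope; ageing, top-heavy pyramids give a positive one.
#'
#' @inheritParams mean_age
#' @return dimensionless slope (years per unit proportion).
#' @export
age_gradient <- function(lower_bounds, proportions) {
  check_pyramid(lower_bounds, proportions)
  x <- proportions
  y <- lower_bounds + 2.5
  denom <- mean(x)^2 - mean(x * x)
  if (abs(denom) < 1e-15)
    stop_config("age_gradient: all bracket proportions equal, slope undefined")
  (mean(x) * mean(y) - mean(x * y)) / denom
}

check_pyramid <- function(lower_bounds, proportions) {
  if (length(lower_bounds) != length(proportions) || length(proportions) < 3)
    stop_config("pyramid needs >= 3 aligned brackets")
  if (any(proportions < 0))
    stop_config("pyramid proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_config("pyramid proportions must sum to 1 (got %.12f)", sum(proportions))
  invisible(TRUE)
}

pyramid_lower_bounds <- function() seq(0, 95, by = 5)

pyramid_col_names <- function() {
  lb <- pyramid_lower_bounds()
  ifelse(lb == 95, "p_95_plus", sprintf("p_%02d_%02d", lb, lb + 4))
}

#' Compress a demographics table into model-ready features
#'
#' Adds `mean_age` and `age_gradient` columns computed from the pyramid
#' proportion columns of a demographics table.
#'
#' @param demographics table with columns `country_id`, `year`, `mean_bmi`,
#'   `sdi` and pyramid proportions `p_00_04` ... `p_95_plus`.
#' @return the table with `mean_age` and `age_gradient` appended.
#' @export
demographic_features <- function(demographics) {
  if (all(c("mean_age", "age_gradient") %in% names(demographics)))
    return(demographics)
  pc <- pyramid_col_names()
  miss <- setdiff(pc, names(demographics))
  if (length(miss))
    stop_config("demographics table missing pyramid columns: %s",
                paste(miss, collapse = ", "))
  pm <- as.matrix(demographics[, pc, drop = FALSE])
  lb <- pyramid_lower_bounds()
  demographics$mean_age <- vapply(seq_len(nrow(pm)),
                                  function(i) mean_age(lb, pm[i, ]), numeric(1))
  demographics$age_gradient <- vapply(seq_len(nrow(pm)),
                                      function(i) age_gradient(lb, pm[i, ]), numeric(1))
  demographics
}
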