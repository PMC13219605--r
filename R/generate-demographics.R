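#' Generate synthetic country-year demographic tables
#'
#' Emulates the structure of national sociodemographic inputs: mean BMI
#' (kg/m2, slowly drifting upwards), a Socio-Demographic Index in \[0, 1\],
#' and a 20-bracket population pyramid (5-year brackets, 0-4 ... 95+) whose
#' proportions follow an exponential trend in age.  The trend parameter is
#' drawn from a range spanning negative (young, bottom-heavy) and positive
#' (ageing, top-heavy) pyramids, so a corpus of many countries contains both
#' signs of age gradient.
#'
#' @param n_countries number of countries.
#' @param seed integer seed for the demographics substream.
#' @param years calendar years covered (default 1980:2014).
#' @return data frame with columns `country_id`, `year`, `mean_bmi`, `sdi`
#'   and pyramid proportions `p_00_04` ... `p_95_plus` (each row sums to 1).
#' @export
generate_demographics <- function(n_countries, seed = 1L, years = 1980:2014) {
  if (n_countries < 1) stop_config("generate_demographics: n_countries must be >= 1")
  set.seed(as.integer(seed))
  lb <- pyramid_lower_bounds()
  k <- seq_along(lb) - 1L
  rows <- vector("list", n_countries)
  for (ci in seq_len(n_countries)) {
    base_bmi <- stats::runif(1, 22, 31)
    base_sdi <- stats::runif(1, 0.35, 0.9)
    # exponential pyramid trend; negative -> young population
    delta0 <- stats::runif(1, -0.07, 0.05)
    ageing_rate <- stats::runif(1, 0, 0.0012)    # pyramids flatten over time
    eps <- stats::rnorm(length(k), 0, 0.02)      # country-specific bracket shape
    tab <- matrix(NA_real_, length(years), length(lb))
    bmi <- sdi <- numeric(length(years))
    for (yi in seq_along(years)) {
      dy <- years[yi] - years[1]
      delta <- delta0 + ageing_rate * dy
      w <- exp(delta * k + eps)
      tab[yi, ] <- w / sum(w)
      bmi[yi] <- min(35, max(20, base_bmi + 0.02 * dy + stats::rnorm(1, 0, 0.05)))
      sdi[yi] <- min(0.99, max(0.05, base_sdi + 0.003 * dy + stats::rnorm(1, 0, 0.004)))
    }
    colnames(tab) <- pyramid_col_names()
    rows[[ci]] <- cbind(
      data.frame(country_id = sprintf("country_%03d", ci), year = years,
                 mean_bmi = bmi, sdi = sdi, stringsAsFactors = FALSE),
      as.data.frame(tab))
  }
  do.call(rbind, rows)
}
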