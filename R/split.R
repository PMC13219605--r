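#' Chronological train/validation/test split by region
#'
#' To mitigate temporal leakage while preserving geographic balance, the most
#' recent `test_frac` of events within each region (ceiling rounding) form
#' the test set; a seeded, unstratified global sample of the remaining events
#' then forms the validation set, yielding an overall 80/10/10 split at the
#' defaults.  Within every region, all train and validation events predate
#' all test events.
#'
#' @param events event catalogue with `event_id`, `start_date` and the region
#'   column.
#' @param test_frac fraction of each region's events held out as test
#'   (default 0.10).
#' @param val_frac overall fraction used for validation (default 0.10;
#'   drawn as `val_frac / (1 - test_frac)` of the non-test events).
#' @param region_key column name defining the region (default `"city_id"`;
#'   `"country_id"` gives country-level splitting).
#' @param seed seed for the validation sample.
#' @return data frame `event_id`, `partition` (train/validation/test) with
#'   attribute `split_dates`: per region, the earliest test-event date.
#' @export
temporal_split <- function(events, test_frac = 0.10, val_frac = 0.10,
                           region_key = "city_id", seed = 1L) {
  if (!region_key %in% names(events))
    stop_config("temporal_split: no region column '%s'", region_key)
  if (test_frac <= 0 || test_frac >= 1 || val_frac < 0 || val_frac >= 1)
    stop_config("temporal_split: fractions must lie in (0, 1)")
  region <- as.character(events[[region_key]])
  partition <- rep("train", nrow(events))
  split_dates <- list()
  small <- character()
  for (rg in unique(region)) {
    idx <- which(region == rg)
    if (length(idx) < 3) {
      small <- c(small, rg)
      next
    }
    ord <- idx[order(events$start_date[idx])]
    n_test <- ceiling(test_frac * length(ord))
    test_idx <- ord[(length(ord) - n_test + 1L):length(ord)]
    partition[test_idx] <- "test"
    split_dates[[rg]] <- min(events$start_date[test_idx])
  }
  if (length(small))
    warning(sprintf("regions with < 3 events assigned wholly to train: %s",
                    paste(small, collapse = ", ")))
  rest <- which(partition == "train")
  n_val <- round(length(rest) * val_frac / (1 - test_frac))
  if (n_val > 0) {
    set.seed(as.integer(seed))
    partition[sample(rest, n_val)] <- "validation"
  }
  out <- data.frame(event_id = events$event_id, partition = partition,
                    stringsAsFactors = FALSE)
  attr(out, "split_dates") <- split_dates
  attr(out, "region_key") <- region_key
  out
}
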