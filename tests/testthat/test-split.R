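fake_events <- function(n_per_region, regions, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(regions), function(i) {
    n <- n_per_region[i]
    data.frame(event_id = sprintf("%s_e%d", regions[i], 1:n),
               city_id = regions[i], country_id = "country_001",
               start_date = as.Date("2000-01-01") + sort(sample(0:5000, n)),
               stringsAsFactors = FALSE)
  }))
}

test_that("the most recent events per region land in test", {
  ev <- fake_events(10, "city_a")
  sp <- temporal_split(ev, seed = 3)
  expect_equal(sum(sp$partition == "test"), 1)
  expect_equal(sp$event_id[sp$partition == "test"],
               ev$event_id[which.max(ev$start_date)])
})

test_that("no temporal leakage: train and validation predate test per region", {
  ev <- fake_events(c(40, 25, 13, 7), paste0("city_", letters[1:4]), seed = 4)
  sp <- temporal_split(ev, seed = 5)
  for (rg in unique(ev$city_id)) {
    d <- ev$start_date[ev$city_id == rg]
    pt <- sp$partition[ev$city_id == rg]
    expect_true(max(d[pt != "test"]) <= min(d[pt == "test"]), info = rg)
  }
  # split dates attribute records the per-region boundary
  sd <- attr(sp, "split_dates")
  expect_setequal(names(sd), unique(ev$city_id))
})

test_that("global partition shares approach 80/10/10 on a many-region corpus", {
  ev <- fake_events(rep(30, 140), sprintf("city_%03d", 1:140), seed = 6)
  sp <- temporal_split(ev, seed = 7)
  shares <- prop.table(table(sp$partition))
  expect_lt(abs(shares[["test"]] - 0.10), 0.01)
  expect_lt(abs(shares[["validation"]] - 0.10), 0.01)
  expect_lt(abs(shares[["train"]] - 0.80), 0.02)
})

test_that("tiny regions fall wholly into train with a warning", {
  ev <- fake_events(c(20, 2), c("city_a", "city_b"), seed = 8)
  expect_warning(sp <- temporal_split(ev, seed = 9), "city_b")
  expect_true(all(sp$partition[ev$city_id == "city_b"] %in% c("train", "validation")))
})

test_that("downsampling keeps all minority and the requested majority share", {
  set.seed(31)
  x <- data.frame(a = rnorm(1010), b = rnorm(1010))
  y <- c(rep(0L, 1000), rep(1L, 10))
  r <- downsample_majority(x, y, keep_fraction = 0.25, seed = 2)
  expect_equal(sum(r$labels == 1), 10)
  expect_equal(sum(r$labels == 0), 250)
  r1 <- downsample_majority(x, y, keep_fraction = 1, seed = 2)
  expect_equal(nrow(r1$features), 1010)
  expect_identical(downsample_majority(x, y, 0.25, seed = 2),
                   downsample_majority(x, y, 0.25, seed = 2))
  expect_error(downsample_majority(x, y, 0), "keep_fraction")
})

test_that("SMOTE interpolates inside the minority convex hull", {
  set.seed(32)
  # two minority points, k = 1: synthetics lie on the segment between them
  x <- data.frame(a = c(rnorm(50), 0, 1), b = c(rnorm(50), 0, 2))
  y <- c(rep(0L, 50), 1L, 1L)
  r <- smote(x, y, k = 1, target_ratio = 0.5, seed = 3)
  sx <- r$features[r$synthetic, ]
  u <- sx$a  # param along segment (0,0)-(1,2)
  expect_true(all(abs(sx$b - 2 * u) < 1e-12))
  expect_true(all(u >= 0 & u <= 1))

  # collinear minority points stay collinear
  x2 <- data.frame(a = c(rnorm(40), 1, 2, 3, 4, 5, 6),
                   b = c(rnorm(40), 2, 4, 6, 8, 10, 12))
  y2 <- c(rep(0L, 40), rep(1L, 6))
  r2 <- smote(x2, y2, k = 3, target_ratio = 1, seed = 4)
  sx2 <- r2$features[r2$synthetic, ]
  expect_true(all(abs(sx2$b - 2 * sx2$a) < 1e-10))

  # counts reach the target ratio and originals are untouched
  set.seed(33)
  x3 <- data.frame(a = rnorm(1000), b = rnorm(1000))
  y3 <- c(rep(0L, 990), rep(1L, 10))
  r3 <- smote(x3, y3, k = 5, target_ratio = 1, seed = 5)
  expect_equal(sum(r3$labels == 1), 990)
  expect_equal(r3$features[1:1000, ], x3, ignore_attr = TRUE)

  # general convex-hull property via per-coordinate bounds of neighbours
  minr <- which(y3 == 1)
  rng_a <- range(x3$a[minr]); rng_b <- range(x3$b[minr])
  sx3 <- r3$features[r3$synthetic, ]
  expect_true(all(sx3$a >= rng_a[1] & sx3$a <= rng_a[2]))
  expect_true(all(sx3$b >= rng_b[1] & sx3$b <= rng_b[2]))

  expect_error(smote(x3, c(rep(0L, 997), rep(1L, 3)), k = 5), "smaller k")
})
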