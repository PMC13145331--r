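test_that("count interpolation fills gaps linearly and is idempotent", {
  expect_equal(interpolate_counts(c(10, NA, 20)), c(10, 15, 20))
  expect_equal(interpolate_counts(c(NA, 8, NA)), c(8, 8, 8))
  full <- c(3, 7, 2, 9)
  expect_equal(interpolate_counts(full), full)
  # interior gap longer than one year, plus rounding
  expect_equal(interpolate_counts(c(10, NA, NA, 20)),
               c(10, 13, 17, 20))
  # idempotence on a random gappy matrix
  set.seed(1)
  m <- matrix(rpois(40, 50), 4, 10)
  m[sample(40, 10)] <- NA
  once <- interpolate_counts(m)
  expect_equal(interpolate_counts(once), once)
  expect_false(anyNA(once))
  m_bad <- rbind(allna = rep(NA_real_, 4))
  expect_error(interpolate_counts(m_bad), "allna")
})

test_that("female halving rounds half-up and splits totals consistently", {
  expect_equal(female_counts(300), 150)
  expect_equal(female_counts(301), 151)
  expect_equal(female_counts(0), 0)
  expect_error(female_counts(-2), "non-negative")
  # two halves recover the total or overshoot by exactly one
  for (c in 0:25) {
    expect_true((female_counts(c) + female_counts(c)) %in% c(c, c + 1))
  }
})

test_that("pooled age ratio is a count-weighted mean bounded by its inputs", {
  expect_equal(elsewhere_age_ratio(c(0.2, 0.1), c(100, 300)), 0.125)
  expect_equal(elsewhere_age_ratio(c(0.3, 0.1), c(5, 5)), 0.2)
  expect_equal(elsewhere_age_ratio(0.17, 42), 0.17)
  expect_error(elsewhere_age_ratio(c(0.1, 0.2), c(0, 0)), "zero")
  set.seed(2)
  for (k in 1:20) {
    r <- runif(5); w <- runif(5, 0, 10)
    v <- elsewhere_age_ratio(r, w)
    expect_gte(v, min(r))
    expect_lte(v, max(r))
  }
})

test_that("age-ratio split reproduces the juvenile:adult ratio", {
  expect_equal(juveniles_from_ratio(0.25, 500), 100)
  expect_equal(juveniles_from_ratio(0, 500), 0)
  expect_equal(juveniles_from_ratio(1, 500), 250)
  expect_error(juveniles_from_ratio(-0.1, 10), "non-negative")
})

test_that("growing degree days accumulate excess above base", {
  expect_equal(growing_degree_days(c(5, 6, 7), base = 5), 3)
  expect_equal(growing_degree_days(c(-3, 0, 4), base = 5), 0)
  expect_equal(growing_degree_days(c(1, 2), base = 0), 3)
  expect_error(growing_degree_days(numeric(0)), "empty")
  # non-decreasing as the window extends
  set.seed(3)
  temps <- rnorm(30, 5, 6)
  gdd <- vapply(1:30, function(k) growing_degree_days(temps, 2, 1:k), 0)
  expect_true(all(diff(gdd) >= 0))
})

test_that("cumulative snow counts precipitation on cold days", {
  expect_equal(cumulative_snow(c(1, 2, 3), c(-5, -1, -2), snow_temp = 0), 6)
  expect_equal(cumulative_snow(c(1, 2, 3), c(5, 1, 2), snow_temp = 0), 0)
  # hand-enumerated mixed series: days 1 and 4 are below the threshold
  expect_equal(cumulative_snow(c(2, 5, 1, 3), c(-1, 2, 0.5, -4),
                               snow_temp = 0), 2 + 3)
  expect_error(cumulative_snow(c(1, 2), c(0, 0, 0)), "misaligned")
})

test_that("storm days count low-pressure days", {
  expect_equal(storm_days(c(990, 985, 1000), threshold = 980), 0)
  expect_equal(storm_days(c(970, 975), threshold = 980), 2)
  expect_equal(storm_days(c(990, 975, 985), threshold = 980), 1)
  expect_error(storm_days(numeric(0)), "empty")
})

test_that("hunting periods follow the protection history", {
  expect_equal(hunting_period(1990), 0L)
  expect_equal(hunting_period(2007), 1L)
  expect_equal(hunting_period(2015), 2L)
  expect_equal(hunting_period(c(1983, 2005, 2006, 2008, 2009, 2022)),
               c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_error(hunting_period(1980), "study span")
  expect_error(hunting_period(2023), "study span")
  # non-decreasing in year
  expect_true(all(diff(hunting_period(1983:2022)) >= 0))
})

test_that("standardization centers, scales and handles degenerate series", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * 1.2247449, tolerance = 1e-4)
  expect_equal(standardize(rep(4, 6)), rep(0, 6))
  set.seed(4)
  x <- rnorm(50, 10, 3)
  expect_equal(mean(standardize(x)), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(standardize(x)^2)), 1, tolerance = 1e-12)
  expect_error(standardize(1), "at least two")
})

test_that("csv readers and group aggregation compose into model inputs", {
  td <- withr::local_tempdir()
  sites <- data.frame(site = c("wex", "isl", "lk", "e1", "e2"),
                      group = c("W", "Is", "LK", "E", "E"))
  write.csv(sites, file.path(td, "sites.csv"), row.names = FALSE)
  counts <- expand.grid(site = sites$site, year = 2001:2004)
  set.seed(5)
  counts$count <- rpois(nrow(counts), 400)
  counts$count[3] <- NA
  write.csv(counts, file.path(td, "counts.csv"), row.names = FALSE)
  s <- read_sites(file.path(td, "sites.csv"))
  cm <- read_counts(file.path(td, "counts.csv"))
  expect_equal(dim(cm), c(5, 4))
  fem <- prepare_counts(cm, s)
  expect_equal(rownames(fem), imm_groups())
  expect_false(anyNA(fem))
  # Elsewhere row pools its two sites, halved
  filled <- interpolate_counts(cm)
  expect_equal(fem["E", 2],
               female_counts(filled["e1", 2] + filled["e2", 2]))
  # ratios: Elsewhere pools by weight
  ar <- expand.grid(site = sites$site, year = 2001:2004)
  ar$ratio <- runif(nrow(ar), 0, 0.4)
  ar$weight <- rpois(nrow(ar), 300)
  write.csv(ar, file.path(td, "age_ratios.csv"), row.names = FALSE)
  ratios <- read_age_ratios(file.path(td, "age_ratios.csv"))
  jobs <- prepare_jobs(ratios, fem, s)
  e_sites <- rownames(ratios$ratio) %in% c("e1", "e2")
  pooled <- elsewhere_age_ratio(ratios$ratio[e_sites, 1],
                                ratios$weight[e_sites, 1])
  expect_equal(jobs["E", 1], juveniles_from_ratio(pooled, fem["E", 1]))
  expect_error(read_sites(file.path(td, "counts.csv")), "columns")
})

test_that("covariates computed from daily weather are standardized per group", {
  days <- seq(as.Date("2000-07-01"), as.Date("2006-08-31"), by = "day")
  set.seed(6)
  wx <- data.frame(date = days,
                   tmean_c = 8 + 10 * sinpi(2 * (as.numeric(days) %% 365) / 365) +
                     rnorm(length(days)),
                   precip_mm = rexp(length(days), 1),
                   pmin_hpa = rnorm(length(days), 1000, 12))
  weather <- list(r1 = wx, r2 = wx)
  regions <- setNames(rep(list(list(winter = "r1", stage = "r2", breed = "r2")), 4),
                      imm_groups())
  covs <- compute_covariates(weather, regions, years = 2001:2005)
  expect_s3_class(covs, "imm_covs")
  expect_equal(dim(covs$x), c(4, 5, 4))
  for (i in 1:4) for (k in 1:4) {
    expect_equal(mean(covs$x[i, , k]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(covs$x[i, , k]^2)), 1, tolerance = 1e-9)
  }
  expect_equal(length(covs$h), 4)
  expect_true(all(diff(covs$h) >= 0))
  expect_true(all(covs$raw$x >= 0))
})
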