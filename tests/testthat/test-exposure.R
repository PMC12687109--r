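test_that("suitable area combines binary climate with fractional habitat", {
  hf <- c(0.5, 0.2, 0.0)
  expect_equal(suitable_area_year(hf, rep(TRUE, 3), 582.02), 0.7 * 582.02)
  expect_equal(suitable_area_year(hf, c(TRUE, FALSE, TRUE), 582.02),
               0.5 * 582.02)
  expect_equal(suitable_area_year(rep(0, 3), rep(TRUE, 3), 582.02), 0)
  # climate-only freezes habitat at 2015; land-use-only ignores climate
  expect_equal(
    suitable_area_year(hf, c(TRUE, FALSE, TRUE), 1, "climate_only",
                       habitat_frac_2015 = c(1, 1, 1)), 2)
  expect_equal(suitable_area_year(hf, c(FALSE, FALSE, FALSE), 1,
                                  "landuse_only"), 0.7)
  expect_error(suitable_area_year(hf, rep(TRUE, 3), 1, "climate_only"),
               "2015")
})

test_that("the 2015 baseline assumes suitable climate everywhere", {
  expect_equal(sa_2015(rep(1, 4), 582.02), 4 * 582.02)
  expect_equal(sa_2015(c(0.25, 0.75), 582.02), 582.02)
  expect_equal(sa_2015(numeric(0), 582.02), 0)
})

test_that("the extinction rule zeroes everything from the first zero year on", {
  r <- apply_extinction_rule(c(`2015` = 5, `2016` = 0, `2017` = 3))
  expect_equal(unname(r$sa), c(5, 0, 0))
  expect_equal(r$extinct_year, 2016L)
  r2 <- apply_extinction_rule(c(5, 4, 6))
  expect_equal(r2$sa, c(5, 4, 6))
  expect_true(is.na(r2$extinct_year))
  r3 <- apply_extinction_rule(c(0, 1, 2))
  expect_equal(r3$sa, c(0, 0, 0))
})

test_that("the extinction rule is absorbing and idempotent on random trajectories", {
  set.seed(55)
  for (i in 1:50) {
    sa <- stats::runif(30, 0, 100)
    sa[stats::runif(30) < 0.15] <- 0
    once <- apply_extinction_rule(sa)
    twice <- apply_extinction_rule(once$sa)
    expect_identical(once$sa, twice$sa)
    expect_identical(once$extinct_year, twice$extinct_year)
    if (!is.na(once$extinct_year))
      expect_true(all(once$sa[once$extinct_year:30] == 0))
  }
})

test_that("percent change follows the asymmetric gain/loss equations", {
  pc <- percent_change(c(0, 10, 20), 10)
  expect_equal(pc$pct_change, c(-100, 0, 50))
  expect_equal(pc$index_0_200, c(0, 100, 150))
  expect_equal(pc$exposure_fraction, c(1, 0, 0))
  expect_error(percent_change(5, 0), "positive")
  expect_error(percent_change(-1, 5), "non-negative")
})

test_that("the change index stays within [0, 200) over extreme area ratios", {
  ratios <- c(0, 10^seq(-6, 6, by = 0.01))
  pc <- percent_change(ratios, 1)
  expect_true(all(pc$index_0_200 >= 0))
  expect_true(all(pc$index_0_200 < 200))
  expect_true(all(pc$pct_change >= -100 & pc$pct_change < 100))
})

test_that("trajectories freeze habitat for climate-only and spin up before 2020", {
  yrs <- 2015:2025
  hf <- matrix(0.5, 2, length(yrs), dimnames = list(1:2, yrs))
  hf[, as.character(2020:2025)] <- 0.25   # land-use loss from 2020
  flags <- matrix(TRUE, 2, length(yrs), dimnames = dimnames(hf))
  flags[2, as.character(2018:2025)] <- FALSE  # pre-2020 flags are ignored
  tr <- sa_trajectory(hf, flags, 1, "combined")
  expect_equal(tr$sa_2015, 1)
  expect_equal(tr$trajectory$sa_km2[tr$trajectory$year == 2018], 1)
  expect_equal(tr$trajectory$sa_km2[tr$trajectory$year == 2021], 0.25)
  co <- sa_trajectory(hf, flags, 1, "climate_only")
  expect_equal(co$trajectory$sa_km2[co$trajectory$year == 2021], 0.5)
  lo <- sa_trajectory(hf, NULL, 1, "landuse_only")
  expect_equal(lo$trajectory$sa_km2[lo$trajectory$year == 2021], 0.5)
  expect_error(sa_trajectory(hf * 0, flags, 1, "combined"),
               "no-initial-habitat")
})

test_that("half the range turned climatically unsuitable gives exposure one half", {
  yrs <- 2015:2100
  hf <- matrix(0.4, 10, length(yrs), dimnames = list(1:10, yrs))
  flags <- matrix(TRUE, 10, length(yrs), dimnames = dimnames(hf))
  flags[1:5, as.character(2020:2100)] <- FALSE
  tr <- sa_trajectory(hf, flags, 582.02, "combined")
  final <- tr$trajectory[tr$trajectory$year == 2100, ]
  expect_equal(final$exposure_fraction, 0.5, tolerance = 1e-12)
  expect_equal(final$pct_change, -50, tolerance = 1e-12)
})

test_that("driver attribution separates heat, land use, both and the union effect", {
  expect_equal(attribute_driver(0.9, 0.60, 0.20, 0.5), "heat")
  expect_equal(attribute_driver(0.9, 0.20, 0.60, 0.5), "landuse")
  expect_equal(attribute_driver(0.98, 0.9, 0.9, 0.5), "both")
  expect_equal(attribute_driver(0.55, 0.10, 0.10, 0.5), "combined_only")
  expect_error(attribute_driver(0.3, 0.9, 0.9, 0.5), "not applicable")
})

test_that("threshold counts use a greater-or-equal comparison per group", {
  ex <- tibble::tibble(exposure_fraction = c(0.4, 0.5, 1.0),
                       taxon = c("bird", "bird", "reptile"))
  tc <- threshold_counts(ex, thresholds = c(0.5, 1.0))
  expect_equal(tc$n_over[tc$threshold == 0.5], 2L)
  expect_equal(tc$n_over[tc$threshold == 1.0], 1L)
  by_tax <- threshold_counts(ex, 0.5, group_by = "taxon")
  expect_equal(by_tax$n_over[by_tax$group == "bird"], 1L)
  expect_equal(by_tax$pct[by_tax$group == "reptile"], 100)
  # counts are non-increasing in the threshold
  expect_true(all(diff(threshold_counts(ex, c(0.3, 0.5, 0.9, 1))$n_over) <= 0))
})
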