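test_that("the FRET ratio is blank-subtracted channel division", {
  time <- 0:9
  # equal blank-subtracted channels -> ratio identically 1
  f480 <- matrix(150, 10, 1, dimnames = list(NULL, "S01"))
  f520 <- matrix(150, 10, 1, dimnames = list(NULL, "S01"))
  lay <- tibble::tibble(well = c("S01", "B1"),
                        variant_id = c("v1", NA),
                        replicate = c(1L, NA),
                        is_blank = c(FALSE, TRUE))
  pl <- fret_plate(time, cbind(f480, B1 = 100), cbind(f520, B1 = 100), lay)
  expect_equal(fret_ratio(pl, "S01")$ratio, rep(1, 10))

  # F480 - B = 50, F520 - B = 100 -> 0.5
  pl2 <- fret_plate(time, cbind(S01 = rep(150, 10), B1 = 100),
                    cbind(S01 = rep(200, 10), B1 = 100), lay)
  expect_equal(fret_ratio(pl2, "S01")$ratio, rep(0.5, 10))

  # scaling all raw signals (incl. blanks) by c > 0 leaves the ratio alone
  pl3 <- fret_plate(time, 7 * cbind(S01 = rep(150, 10), B1 = 100),
                    7 * cbind(S01 = rep(200, 10), B1 = 100), lay)
  expect_equal(fret_ratio(pl3, "S01")$ratio,
               fret_ratio(pl2, "S01")$ratio)

  expect_error(fret_ratio(pl, "nope"), "not on the plate")
})

test_that("non-positive denominators are masked, fully-masked traces error", {
  time <- 0:4
  lay <- tibble::tibble(well = c("S01", "B1"), variant_id = c("v1", NA),
                        replicate = c(1L, NA), is_blank = c(FALSE, TRUE))
  f520 <- cbind(S01 = c(200, 200, 100, 200, 200), B1 = rep(100, 5))
  f480 <- cbind(S01 = rep(150, 5), B1 = rep(100, 5))
  pl <- fret_plate(time, f480, f520, lay)
  expect_warning(s <- fret_ratio(pl, "S01"), "masked")
  expect_true(is.na(s$ratio[3]))
  expect_equal(s$ratio[-3], rep(0.5, 4))

  all_bad <- fret_plate(time, f480,
                        cbind(S01 = rep(100, 5), B1 = rep(100, 5)), lay)
  expect_error(suppressWarnings(fret_ratio(all_bad, "S01")), "all timepoints")
})

test_that("truncation keeps the prefix before the first threshold crossing", {
  s <- fret_series_for_test(c(0.40, 0.45, 0.50, 0.56, 0.70))
  out <- truncate_series(s, 0.55)
  expect_equal(out$ratio, c(0.40, 0.45, 0.50))

  capped <- fret_series_for_test(seq(0.40, 0.50, length.out = 8))
  expect_length(truncate_series(capped, 0.55)$ratio, 8)

  # a noisy dip back below the threshold cannot re-admit late points
  dippy <- fret_series_for_test(c(0.40, 0.56, 0.50, 0.52))
  expect_length(truncate_series(dippy, 0.55)$ratio, 1)

  high <- truncate_series(fret_series_for_test(c(0.60, 0.70, 0.80)), 0.55)
  expect_error(fit_initial_slope(high), "fewer than two")

  expect_error(truncate_series(s, -1), "positive")
})

test_that("truncated prefix length is non-increasing in threshold", {
  set.seed(31)
  for (i in 1:25) {
    trace <- cumsum(abs(rnorm(40, 0.01, 0.005))) + 0.4
    s <- fret_series_for_test(trace)
    lens <- vapply(seq(0.45, 0.95, by = 0.05), function(th) {
      length(truncate_series(s, th)$ratio)
    }, numeric(1))
    expect_true(all(diff(lens) >= 0))
  }
})

test_that("initial slopes are ordinary least squares on ratio vs time", {
  t <- 0:29
  exact <- fret_series_for_test(0.4 + 0.01 * t, time = t)
  expect_equal(fit_initial_slope(exact), 0.01)
  expect_equal(fit_initial_slope(fret_series_for_test(rep(0.45, 10))), 0)

  # Monte-Carlo: noisy line with known slope, recovered within 3 SE
  # (closed-form OLS slope SE = sigma / sqrt(sum((t - mean(t))^2)))
  se <- 0.005 / sqrt(sum((t - mean(t))^2))
  set.seed(77)
  slopes <- vapply(1:100, function(i) {
    fit_initial_slope(fret_series_for_test(
      0.4 + 0.02 * t + rnorm(30, 0, 0.005), time = t))
  }, numeric(1))
  expect_gte(sum(abs(slopes - 0.02) < 3 * se), 97)
  expect_lt(abs(mean(slopes) - 0.02), 3 * se / sqrt(100))
})

test_that("normalization yields WT = 1 and scales linearly", {
  wt_slopes <- c(0.010, 0.011, 0.009)
  wt <- normalize_fitness(wt_slopes, mean(wt_slopes))
  expect_identical(wt$fitness, 1)

  v4 <- normalize_fitness(4 * wt_slopes, mean(wt_slopes))
  expect_equal(v4$fitness, 4)
  expect_identical(normalize_fitness(c(0, 0, 0), 0.01)$fitness, 0)
  # negative mean slope clips to zero fitness, raw values preserved
  neg <- normalize_fitness(c(-0.002, -0.001, 0.0005), 0.01)
  expect_identical(neg$fitness, 0)
  expect_lt(min(neg$per_replicate), 0)
  expect_error(normalize_fitness(c(0.01), 0), "positive")
  expect_error(normalize_fitness(c(0.01), -0.1), "positive")
})

test_that("plate scoring recovers assigned fitness ordering noiselessly", {
  land <- manual_landscape(region_B, c(AAA = 0, CCC = 0.5, HHH = 4))
  pl <- simulate_plate(c("LQE", "AAA", "CCC", "HHH"), land,
                       noiseless_kin(), seed = 1)
  sc <- score_plate(pl, "B_LQE")
  got <- setNames(sc$fitness, sub("B_", "", sc$variant_id))
  truth <- c(LQE = 1, AAA = 0, CCC = 0.5, HHH = 4)
  expect_identical(order(got[names(truth)]), order(truth))
  expect_identical(unname(got["LQE"]), 1)
  # triplicate wells with identical series -> SD exactly 0
  expect_equal(sc$sd_fitness[sc$variant_id == "B_HHH"], 0)
})

test_that("scoring a plate of blanks, or without the reference, errors", {
  time <- 0:9
  lay <- tibble::tibble(well = c("B1", "B2"), variant_id = c(NA, NA),
                        replicate = c(NA, NA), is_blank = c(TRUE, TRUE))
  pl <- fret_plate(time, cbind(B1 = rep(100, 10), B2 = rep(100, 10)),
                   cbind(B1 = rep(100, 10), B2 = rep(100, 10)), lay)
  expect_error(score_plate(pl, "wt"), "only blank")

  land <- manual_landscape(region_B, c(AAA = 2))
  pl2 <- simulate_plate("AAA", land, noiseless_kin(), seed = 1)
  expect_error(score_plate(pl2, "B_missing"), "absent")
})

test_that("fitness scores are invariant to overall signal scale", {
  land <- make_landscape(region_B, "dense", seed = 8)
  lib <- random_library(region_B, 6, seed = 8)
  pl <- simulate_plate(lib, land, kinetic_params(), seed = 8)
  sc1 <- score_plate(pl, "B_LQE")
  scaled <- fret_plate(pl$time, 3.7 * pl$f480, 3.7 * pl$f520, pl$layout)
  sc2 <- score_plate(scaled, "B_LQE")
  expect_equal(sc2$fitness, sc1$fitness)
  expect_equal(sc2$sd_fitness, sc1$sd_fitness)
})

test_that("scored tables round-trip through delimited text", {
  land <- manual_landscape(region_B, c(AAA = 0.5))
  pl <- simulate_plate("AAA", land, noiseless_kin(), seed = 2)
  sc <- score_plate(pl, "B_LQE")
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores(sc, f)
  back <- read_scores(f)
  expect_equal(back$fitness, sc$fitness)
  expect_identical(back$variant_id, sc$variant_id)
})
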