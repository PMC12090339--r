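test_that("training sets enforce the WT-anchored contract", {
  ts <- training_set(region_B, c("AAA", "CCC"), c(0.2, 3))
  expect_identical(ts$identities[1], "LQE")
  expect_identical(ts$fitness[1], 1)
  expect_error(training_set(region_B, c("AAA", "AAA"), c(1, 1)), "duplicate")
  expect_error(training_set(region_B, "AAA", -0.5), "non-negative")
  expect_error(training_set(region_B, c("LQE", "AAA"), c(2, 1)),
               "wild-type fitness")
})

test_that("members train on floor(fraction * n) records without replacement", {
  lib <- random_library(region_B, 48, seed = 2)
  ts <- training_set(region_B, lib$identities, runif(48))
  ens <- fit_ensemble(ts, k = 5, bootstrap_fraction = 0.9, seed = 1)
  expect_identical(ens$subsample_size, 44L)  # floor(0.9 * 49)
  expect_length(ens$members, 5)
  for (idx in ens$subsamples) {
    expect_length(idx, 44)
    expect_identical(anyDuplicated(idx), 0L)
  }
  expect_error(fit_ensemble(training_set(region_B, "AAA", 0.5), seed = 1),
               "larger initial library")
  expect_error(fit_ensemble(ts, k = 1, seed = 1), "at least 2")
})

test_that("constant-fitness data yields near-constant predictions", {
  lib <- random_library(region_B, 30, seed = 7)
  ts <- training_set(region_B, lib$identities, rep(1, 30))
  ens <- fit_ensemble(ts, seed = 3)
  pp <- predict_posterior(ens, enumerate_space(region_B))
  expect_lt(max(abs(pp$mean - 1)), 0.05)
})

test_that("the fit-and-predict path is deterministic in (data, seed)", {
  lib <- random_library(region_B, 20, seed = 5)
  ts <- training_set(region_B, lib$identities, runif(20, 0, 2))
  probe <- c("AAA", "LQY", "WWW")
  e1 <- fit_ensemble(ts, seed = 42)
  e2 <- fit_ensemble(ts, seed = 42)
  expect_identical(predict_posterior(e1, probe), predict_posterior(e2, probe))
  e3 <- fit_ensemble(ts, seed = 43)
  expect_false(identical(predict_posterior(e1, probe)$mean,
                         predict_posterior(e3, probe)$mean))
})

test_that("posterior SD is member-order invariant and zero for clones", {
  lib <- random_library(region_B, 20, seed = 6)
  ts <- training_set(region_B, lib$identities, runif(20, 0, 2))
  ens <- fit_ensemble(ts, seed = 2)
  probe <- random_library(region_B, 25, seed = 99)$identities
  pp <- predict_posterior(ens, probe)
  perm <- ens
  perm$members <- perm$members[c(3, 5, 1, 2, 4)]
  expect_equal(predict_posterior(perm, probe)$sd, pp$sd)

  clones <- ens
  clones$members <- rep(ens$members[1], 5)
  expect_equal(predict_posterior(clones, probe)$sd, rep(0, 25))
})

test_that("draw_member samples members uniformly and deterministically", {
  lib <- random_library(region_B, 20, seed = 8)
  ts <- training_set(region_B, lib$identities, runif(20))
  ens <- fit_ensemble(ts, seed = 1)
  set.seed(123)
  idx <- vapply(1:10000, function(i) {
    attr(draw_member(ens), "member_index")
  }, integer(1))
  counts <- tabulate(idx, 5)
  # binomial 5-sigma band around 2000
  expect_true(all(abs(counts - 2000) < 5 * sqrt(10000 * 0.2 * 0.8)))

  set.seed(9); a <- attr(draw_member(ens), "member_index")
  set.seed(9); b <- attr(draw_member(ens), "member_index")
  expect_identical(a, b)
  # the drawn prediction function matches the member's posterior column
  set.seed(9); f <- draw_member(ens)
  expect_equal(f("AAA"),
               predict_posterior(clone_single(ens, a), "AAA")$mean)
})

test_that("posterior mean ranks held-out variants better than chance", {
  # smooth landscape, 48 noisy measurements + WT: Spearman correlation of
  # posterior mean with truth on the full space is positive, seed after seed
  rhos <- vapply(1:20, function(s) {
    land <- make_landscape(region_B, "dense", seed = 7000 + s)
    lib <- random_library(region_B, 48, seed = s)
    pl <- simulate_plate(lib, land, kinetic_params(), seed = s)
    sc <- score_plate(pl, "B_LQE")
    ts <- training_set(region_B, sub("B_", "", sc$variant_id), sc$fitness)
    ens <- fit_ensemble(ts, seed = s)
    held_out <- setdiff(enumerate_space(region_B), ts$identities)
    pp <- predict_posterior(ens, held_out)
    cor(pp$mean, true_fitness(land, held_out), method = "spearman")
  }, numeric(1))
  # sign-test style: positive rank correlation in at least 15 of 20 seeds
  expect_gte(sum(rhos > 0), 15)
  expect_gt(mean(rhos), 0.3)
})

test_that("an additive landscape's optimum is recovered from 200 labels", {
  # noiseless labels for 200 random variants; the true top-1 variant must
  # rank within the top 50 of the posterior-mean ordering of all 8000
  hits <- vapply(1:20, function(s) {
    land <- make_landscape(region_B, "additive", seed = 5000 + s)
    lib <- random_library(region_B, 200, seed = s)
    ts <- training_set(region_B, lib$identities,
                       true_fitness(land, lib$identities))
    ens <- fit_ensemble(ts, seed = s)
    pp <- predict_posterior(ens, enumerate_space(region_B))
    top1 <- which.max(as.numeric(land$fitness))
    rank(-pp$mean)[top1] <= 50
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("ensembles survive a save/load round trip", {
  lib <- random_library(region_B, 20, seed = 3)
  ts <- training_set(region_B, lib$identities, runif(20))
  ens <- fit_ensemble(ts, seed = 4)
  d <- withr::local_tempdir()
  save_ensemble(ens, d)
  back <- load_ensemble(d)
  expect_identical(predict_posterior(back, "AAA"),
                   predict_posterior(ens, "AAA"))
})
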