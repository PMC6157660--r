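test_that("noiseless chains are inverted exactly by the matching estimator", {
  # plankton-only chain, single-TDF estimator
  cfg <- food_chain_config(
    levels = data.frame(name = c("producer", "grazer"),
                        tp_true = c(1, 2), tdf_type = c(NA, "plankton"),
                        stringsAsFactors = FALSE),
    noise_sd_aa = 0, noise_sd_bulk = 0, n_per_level = 1, seed = 3)
  chain <- generate_food_chain(cfg)
  grazer <- chain$specimens[[2]]
  spac <- aa_value(grazer$profile, "Glu") - aa_value(grazer$profile, "Phe")
  expect_equal(spac, 3.4 + 7.6, tolerance = 1e-12)
  expect_equal(estimate_tp(list(grazer), "single")$tp, 2, tolerance = 1e-12)

  # avian top step above a TP-2 plankton regime, multi-TDF estimator
  chain2 <- generate_food_chain(noiseless_bird_chain())
  bird <- chain2$specimens[[3]]
  expect_equal(estimate_tp(list(bird), "multi")$tp, 3.4, tolerance = 1e-12)

  # fractional avian steps: the round trip is the identity per level
  cfg3 <- food_chain_config(
    levels = data.frame(
      name = c("producer", "plankton", "bird_lo", "bird_hi"),
      tp_true = c(1, 2, 2.9, 3.44),
      tdf_type = c(NA, "plankton", "bird", "bird"),
      stringsAsFactors = FALSE),
    noise_sd_aa = 0, noise_sd_bulk = 0, n_per_level = 2, seed = 4)
  chain3 <- generate_food_chain(cfg3)
  rep3 <- recovery_report(chain3$specimens[1:4], chain3$truth[1:4, ], "single")
  expect_true(all(abs(rep3$mean_error) < 1e-12))
  expect_true(all(rep3$rmse < 1e-12))
  rep3b <- recovery_report(chain3$specimens[5:8], chain3$truth[5:8, ], "multi")
  expect_true(all(abs(rep3b$mean_error) < 1e-12))
})

test_that("generated bulk delta15N spacing equals bulk_step per trophic step", {
  cfg <- noiseless_bird_chain()
  chain <- generate_food_chain(cfg)
  bulk <- vapply(chain$specimens, `[[`, numeric(1), "bulk_d15N")
  expect_equal(diff(bulk), 3.4 * diff(c(1, 2, 3.4)), tolerance = 1e-12)
})

test_that("generation is deterministic in the seed", {
  cfg <- food_chain_config(n_per_level = 3, seed = 77)
  a <- generate_food_chain(cfg)
  b <- generate_food_chain(cfg)
  expect_identical(a, b)
  c <- generate_food_chain(food_chain_config(n_per_level = 3, seed = 78))
  expect_false(identical(a$specimens[[1]]$profile, c$specimens[[1]]$profile))
})

test_that("noisy estimation recovers true TP within sampling error", {
  n <- 200
  sd_aa <- 0.5
  cfg <- food_chain_config(
    levels = data.frame(name = c("producer", "zooplankton", "bird"),
                        tp_true = c(1, 2, 3.4),
                        tdf_type = c(NA, "plankton", "bird"),
                        stringsAsFactors = FALSE),
    noise_sd_aa = sd_aa, noise_sd_bulk = 0.2, n_per_level = n, seed = 5)
  chain <- generate_food_chain(cfg)
  birds <- chain$specimens[chain$truth$level_name == "bird"]
  rep <- recovery_report(birds, chain$truth, "multi")
  se <- (sd_aa * sqrt(2) / 3.5) / sqrt(n) # spacing noise over avian TDF
  expect_lt(abs(rep$mean_error[rep$level == "bird"]), 3 * se)
  zoo <- chain$specimens[chain$truth$level_name == "zooplankton"]
  repz <- recovery_report(zoo, chain$truth, "single")
  sez <- (sd_aa * sqrt(2) / 7.6) / sqrt(n)
  expect_lt(abs(repz$mean_error[repz$level == "zooplankton"]), 3 * sez)
})

test_that("a single-TDF estimator is biased low on avian steps as predicted", {
  n <- 200
  cfg <- food_chain_config(
    levels = data.frame(name = c("producer", "fish", "bird"),
                        tp_true = c(1, 2.4, 3.4),
                        tdf_type = c(NA, "plankton", "bird"),
                        stringsAsFactors = FALSE),
    noise_sd_aa = 0.3, noise_sd_bulk = 0.2, n_per_level = n, seed = 6)
  chain <- generate_food_chain(cfg)
  birds <- chain$specimens[chain$truth$level_name == "bird"]
  rep <- recovery_report(birds, chain$truth, "single")
  delta_tp <- 1 # the avian step spans one trophic level
  expected_bias <- -(7.6 - 3.5) * delta_tp / 7.6
  se <- (0.3 * sqrt(2) / 7.6) / sqrt(n)
  expect_lt(abs(rep$mean_error[rep$level == "bird"] - expected_bias), 3 * se)
})

test_that("invalid chain configurations are rejected with all violations", {
  bad_levels <- data.frame(name = c("a", "b"), tp_true = c(2, 1.5),
                           tdf_type = c(NA, "plankton"),
                           stringsAsFactors = FALSE)
  err <- tryCatch(food_chain_config(levels = bad_levels, n_per_level = 0),
                  error = identity)
  expect_match(conditionMessage(err), "tp_true = 1")
  expect_match(conditionMessage(err), "strictly increasing")
  expect_match(conditionMessage(err), "n_per_level")
  expect_error(food_chain_config(noise_sd_aa = -1), "noise")
})

test_that("a custom estimator function can be scored against truth", {
  chain <- generate_food_chain(noiseless_bird_chain())
  naive <- function(glu, phe, model) 1 + (glu - phe - model$beta) / 7.6
  rep <- recovery_report(chain$specimens, chain$truth, naive)
  expect_equal(rep$mean_error[rep$level == "producer"], 0, tolerance = 1e-12)
  expect_lt(rep$mean_error[rep$level == "bird"], 0)
})
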