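test_that("low-rank reconstruction tracks smooth surfaces", {
  b <- bliss_null_block()
  pred <- reconstruct_block(b)
  expect_lt(max(abs(b$response - pred)), 5)
  expect_equal(nrow(flag_combination_outliers(b, predicted = pred)$flags), 0)
})

test_that("a constant surface is reconstructed exactly", {
  b <- make_block(matrix(0, 4, 4), g1 = c(0, 1, 2, 4), g2 = c(0, 1, 2, 4))
  b$response[] <- 5; b$response[1, 1] <- 5
  pred <- reconstruct_block(b)
  expect_lt(max(abs(pred - 5)), 1e-6)
})

test_that("an injected spike is the only flagged cell", {
  sim <- simulate_block(simulation_spec(
    noise_sd = 0, outliers = list(list(cell = c(4, 4), shift = 30)), seed = 2))
  report <- flag_combination_outliers(sim$block)
  expect_equal(nrow(report$flags), 1)
  expect_equal(report$flags$cell[[1]], c(4L, 4L))
  expect_gt(abs(report$flags$deviation[1]), 20)
})

test_that("a deviation of exactly the threshold is not flagged", {
  b <- bliss_null_block()
  pred <- reconstruct_block(b)
  b2 <- b
  b2$response[3, 4] <- pred[3, 4] + 20   # exactly at the cutoff
  report <- flag_combination_outliers(b2, predicted = pred)
  expect_equal(nrow(report$flags), 0)
  b2$response[3, 4] <- pred[3, 4] + 20.5
  report2 <- flag_combination_outliers(b2, predicted = pred)
  expect_equal(nrow(report2$flags), 1)
})

test_that("flags are invariant under a constant response shift", {
  sim <- simulate_block(simulation_spec(
    noise_sd = 2, outliers = list(list(cell = c(3, 5), shift = 30)), seed = 8))
  r1 <- flag_combination_outliers(sim$block)
  b2 <- sim$block
  b2$response <- b2$response + 17
  r2 <- flag_combination_outliers(b2)
  expect_equal(r1$flags$cell, r2$flags$cell)
  expect_equal(r2$flags$predicted - r1$flags$predicted,
               rep(17, nrow(r1$flags)), tolerance = 1e-6)
})

test_that("replacement restores spiked cells and is idempotent", {
  sim <- simulate_block(simulation_spec(
    noise_sd = 0, outliers = list(list(cell = c(4, 4), shift = 30)), seed = 2))
  clean <- sim$truth$clean[4, 4]
  report <- flag_combination_outliers(sim$block)
  fixed <- replace_outliers(sim$block, report)
  expect_equal(fixed$response[4, 4], clean, tolerance = 5)
  # original untouched
  expect_equal(sim$block$response[4, 4], clean + 30, tolerance = 1e-9)
  # re-flagging the corrected block flags nothing
  expect_equal(nrow(flag_combination_outliers(fixed)$flags), 0)
  expect_true(all(fixed$replaced$replaced))
})

test_that("an empty report leaves the block byte-identical", {
  b <- bliss_null_block()
  report <- flag_combination_outliers(b)
  expect_equal(nrow(report$flags), 0)
  expect_identical(replace_outliers(b, report)$response, b$response)
})

test_that("a stale report is rejected", {
  sim <- simulate_block(simulation_spec(
    noise_sd = 0, outliers = list(list(cell = c(4, 4), shift = 30)), seed = 2))
  report <- flag_combination_outliers(sim$block)
  small <- make_block(sim$block$response[1:3, 1:3],
                      g1 = sim$block$dose_grid[[1]][1:3],
                      g2 = sim$block$dose_grid[[2]][1:3])
  expect_error(replace_outliers(small, report),
               class = "synscreen_consistency_error")
})

test_that("single-agent outliers are found by leave-one-out refits", {
  sim <- simulate_block(simulation_spec(noise_sd = 1, seed = 7))
  b <- sim$block
  b$response[4, 1] <- b$response[4, 1] + 40
  report <- suppressWarnings(flag_single_agent_outliers(b))
  expect_equal(nrow(report$flags), 1)
  expect_equal(report$flags$cell[[1]], c(4L, 1L))
  expect_identical(report$flags$kind, "single_agent")
  # clean axes yield no flags
  expect_equal(nrow(flag_single_agent_outliers(sim$block)$flags), 0)
  # replacement brings the axis back; re-scan is clean
  fixed <- replace_outliers(b, report)
  expect_equal(nrow(suppressWarnings(flag_single_agent_outliers(fixed))$flags), 0)
  expect_equal(fixed$response[4, 1], sim$truth$singles[[1]][4], tolerance = 6)
})

test_that("single-agent deviation at exactly the threshold is not flagged", {
  sim <- simulate_block(simulation_spec(noise_sd = 0, seed = 7))
  b <- sim$block
  ax <- synscreen:::axis_responses(b, 1)
  loo <- fit_hill(b$dose_grid[[1]][-4], ax[-4])
  pred <- predict_response(loo, b$dose_grid[[1]][4])
  b$response[4, 1] <- pred + 20    # exact boundary
  expect_equal(nrow(suppressWarnings(flag_single_agent_outliers(b))$flags), 0)
})

test_that("short axes are skipped with a warning", {
  M <- matrix(c(0, 10, 30, 20, 35, 60, 40, 55, 80), nrow = 3)
  b <- make_block(M, g1 = c(0, 1, 2), g2 = c(0, 1, 2))
  warns <- capture_warnings(report <- flag_single_agent_outliers(b))
  expect_length(warns, 2)   # one skip per drug axis
  expect_match(warns, "fewer than 4 usable axis points", all = TRUE)
  expect_equal(nrow(report$flags), 0)
  # a grid smaller than 3 x 3 cannot be reconstructed (guard on the raw
  # container, which the validating constructor would refuse to build)
  tiny <- structure(list(block_id = "t", sample_id = NA_character_,
                         drugs = c("A", "B"),
                         dose_grid = list(A = c(0, 1), B = c(0, 1)),
                         response = M[1:2, 1:2]),
                    class = "combination_block")
  expect_error(reconstruct_block(tiny),
               class = "synscreen_insufficient_data_error")
})

test_that("spike detection holds up under plate noise", {
  withr::with_seed(1, {
    hits <- 0; false_flags <- 0; n <- 10
    for (i in seq_len(n)) {
      sim <- simulate_block(simulation_spec(
        noise_sd = 3,
        outliers = list(list(cell = c(4, 5), shift = c(30, -30)[i %% 2 + 1])),
        seed = 500 + i))
      report <- flag_combination_outliers(sim$block)
      hit <- any(vapply(report$flags$cell, function(cc) all(cc == c(4, 5)), TRUE))
      hits <- hits + hit
      false_flags <- false_flags + nrow(report$flags) - hit
    }
    expect_gte(hits / n, 0.9)
    expect_lte(false_flags / n, 1)
  })
})

test_that("outlier reports export as flat tables", {
  sim <- simulate_block(simulation_spec(
    noise_sd = 0, outliers = list(list(cell = c(4, 4), shift = 30)), seed = 2))
  report <- flag_combination_outliers(sim$block)
  tab <- outlier_table(report, sim$block)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$conc_DrugA, sim$block$dose_grid[[1]][4])
  expect_named(tab, c("block_id", "sample_id", "conc_DrugA", "conc_DrugB",
                      "observed", "predicted", "deviation", "kind", "replaced"))
})
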