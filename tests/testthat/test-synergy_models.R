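test_that("Bliss and HSA expectations match their closed forms", {
  expect_equal(expected_bliss(c(50, 50)), 75)
  expect_equal(expected_bliss(c(50, 50, 50)), 87.5)
  expect_equal(expected_bliss(c(0, 37.2)), 37.2)   # 0 is the identity
  expect_equal(expected_hsa(c(30, 60)), 60)
  expect_equal(expected_hsa(rep(42, 5)), 42)
  expect_equal(expected_hsa(c(-10, 20)), 20)       # stimulation allowed
  expect_error(expected_bliss(numeric(0)), class = "synscreen_domain_error")
  expect_error(expected_hsa(numeric(0)), class = "synscreen_domain_error")
})

test_that("HSA expectation never exceeds Bliss on [0, 100]", {
  withr::with_seed(7, {
    for (n in 2:4) {
      y <- matrix(runif(500 * n, 0, 100), ncol = n)
      for (r in seq_len(nrow(y))) {
        expect_lte(expected_hsa(y[r, ]), expected_bliss(y[r, ]) + 1e-12)
      }
    }
  })
})

test_that("Loewe solves the sham combination exactly", {
  cv <- make_curve(l = 0, u = 100, ec50 = 1, h = 1)
  # a drug combined with itself at (d, d) must equal the monotherapy at 2d
  expect_equal(expected_loewe(list(cv, cv), c(1, 1)), 100 * 2 / 3,
               tolerance = 1e-3)
  for (d in c(0.2, 0.7, 3)) {
    expect_equal(expected_loewe(list(cv, cv), c(d, d)),
                 predict_response(cv, 2 * d), tolerance = 1e-4)
  }
  # vanishing partner dose -> single-drug limit
  expect_equal(expected_loewe(list(cv, cv), c(1.3, 1e-12)),
               predict_response(cv, 1.3), tolerance = 1e-4)
  # non-overlapping response ranges are degenerate
  expect_error(expected_loewe(list(make_curve(l = 60, u = 100),
                                   make_curve(l = 0, u = 50)), c(1, 1)),
               class = "synscreen_degenerate_curves_error")
})

test_that("bisection Loewe agrees with a brute-force effect-axis scan", {
  withr::with_seed(21, {
    for (i in 1:10) {
      c1 <- make_curve(l = runif(1, 0, 5), u = runif(1, 70, 100),
                       ec50 = 10^runif(1, -1, 1), h = runif(1, 0.6, 3))
      c2 <- make_curve(l = runif(1, 0, 5), u = runif(1, 70, 100),
                       ec50 = 10^runif(1, -1, 1), h = runif(1, 0.6, 3))
      doses <- 10^runif(2, -1, 1)
      y_bis <- expected_loewe(list(c1, c2), doses)
      y_scan <- loewe_grid_oracle(list(c1, c2), doses)
      span <- min(c1$u, c2$u) - max(c1$l, c2$l)
      expect_equal(y_bis, y_scan, tolerance = 2 * span / 1e6 + 1e-6)
    }
  })
})

test_that("model surfaces score a Bliss-null block as expected", {
  b <- bliss_null_block()
  curves <- suppressWarnings(lapply(1:2, function(k)
    fit_hill(b$dose_grid[[k]], synscreen:::axis_responses(b, k),
             drug = b$drugs[k])))
  sb <- synergy_surface(b, "bliss", curves)
  expect_true(all(abs(sb$delta) < 1e-9))
  sh <- synergy_surface(b, "hsa", curves)
  expect_true(all(sh$delta >= -1e-9))  # Bliss-built cells beat the HSA null
  expect_identical(dim(sb$delta), c(5L, 5L))
})

test_that("three-drug blocks score with the 3-d positive subgrid", {
  sim <- simulate_block(simulation_spec(
    drugs = list(A = list(l = 0, u = 90, ec50 = 1, h = 1),
                 B = list(l = 0, u = 85, ec50 = 2, h = 1.2),
                 C = list(l = 0, u = 80, ec50 = 4, h = 0.9)),
    dose_grid = list(A = c(0, 0.5, 1, 2, 4), B = c(0, 1, 2, 4, 8),
                     C = c(0, 2, 4, 8, 16)),
    noise_sd = 0, seed = 5))
  s <- synergy_surface(sim$block, "bliss")
  expect_identical(dim(s$delta), c(4L, 4L, 4L))
  expect_true(all(abs(s$delta) < 1e-9))
  # consensus is defined for any number of drugs
  cs <- consensus_surface(sim$block)
  expect_identical(dim(cs$delta), c(4L, 4L, 4L))
})

test_that("expected effects are invariant under drug permutation", {
  withr::with_seed(13, {
    y <- runif(3, 0, 100)
    expect_equal(expected_bliss(y), expected_bliss(rev(y)))
    expect_equal(expected_hsa(y), expected_hsa(sample(y)))
    c1 <- make_curve(ec50 = 0.5, h = 1.5, u = 90)
    c2 <- make_curve(ec50 = 2, h = 0.8, u = 95)
    expect_equal(expected_loewe(list(c1, c2), c(0.3, 1.1)),
                 expected_loewe(list(c2, c1), c(1.1, 0.3)), tolerance = 1e-6)
  })
})

test_that("ZIP delta vanishes on a multiplicative-survival surface", {
  b <- bliss_null_block()
  zs <- suppressWarnings(zip_surface(b))
  expect_lt(max(abs(zs$delta)), 0.5)
})

test_that("ZIP recovers a uniform interior shift", {
  b <- bliss_null_block(delta = 15)
  zs <- suppressWarnings(zip_surface(b))
  expect_equal(mean(zs$delta), 15, tolerance = 1)
})

test_that("ZIP refuses under-sampled or higher-order blocks", {
  # guard on the raw container; the validating constructor refuses 2-dose
  # grids outright
  b <- structure(list(block_id = "t", sample_id = NA_character_,
                      drugs = c("A", "B"),
                      dose_grid = list(A = c(0, 1, 2), B = c(0, 1)),
                      response = matrix(c(0, 10, 20, 40, 30, 60), nrow = 3)),
                 class = "combination_block")
  expect_error(zip_surface(b), class = "synscreen_insufficient_data_error")
  sim3 <- simulate_block(simulation_spec(
    drugs = list(A = list(l = 0, u = 90, ec50 = 1, h = 1),
                 B = list(l = 0, u = 85, ec50 = 2, h = 1.2),
                 C = list(l = 0, u = 80, ec50 = 4, h = 0.9)),
    dose_grid = list(A = c(0, 1, 2, 4), B = c(0, 1, 2, 4), C = c(0, 1, 2, 4)),
    noise_sd = 0, seed = 5))
  expect_error(zip_surface(sim3$block), class = "synscreen_domain_error")
})

test_that("consensus is the pointwise max expectation / min delta", {
  withr::with_seed(31, {
    for (i in 1:5) {
      sim <- simulate_block(simulation_spec(noise_sd = 3, seed = 400 + i))
      b <- sim$block
      curves <- suppressWarnings(
        lapply(1:2, function(k) fit_hill(b$dose_grid[[k]],
                                         synscreen:::axis_responses(b, k))))
      parts <- lapply(c("bliss", "loewe", "hsa"), function(m)
        synergy_surface(b, m, curves))
      cs <- consensus_surface(b, curves)
      expect_equal(cs$expected, pmax(parts[[1]]$expected, parts[[2]]$expected,
                                     parts[[3]]$expected), tolerance = 1e-12)
      expect_equal(cs$delta, pmin(parts[[1]]$delta, parts[[2]]$delta,
                                  parts[[3]]$delta), tolerance = 1e-12)
      # consensus summary is the most conservative of the three
      ms <- vapply(parts, function(p) mean(p$delta), 0)
      expect_lte(summarize_surface(cs)$mean_delta, min(ms) + 1e-12)
    }
  })
})

test_that("consensus reports missing with a warning when Loewe is degenerate", {
  b <- bliss_null_block()
  curves <- list(make_curve(l = 60, u = 100), make_curve(l = 0, u = 50))
  expect_warning(cs <- consensus_surface(b, curves),
                 class = "synscreen_consensus_undefined_warning")
  expect_true(all(is.na(cs$delta)))
})

test_that("surface summaries compute mean and windowed maxima", {
  delta <- matrix(0, 5, 5)
  delta[1:3, 1:3] <- 9
  surf <- structure(list(block_id = "b", sample_id = NA_character_,
                         drugs = c("A", "B"), model = "bliss",
                         dose_grid_pos = list(1:5, 1:5),
                         observed = delta, expected = delta * 0,
                         delta = delta, weight = NULL),
                    class = "synergy_surface")
  s <- summarize_surface(surf, msa_window = 3)
  expect_equal(s$msa_delta, 9)
  expect_equal(s$mean_delta, 81 / 25)
  expect_equal(summarize_surface(surf, msa_window = 1)$msa_delta, 9) # max cell
  # constant delta: mean == msa
  surf$delta <- matrix(4.2, 5, 5)
  s2 <- summarize_surface(surf)
  expect_equal(s2$mean_delta, 4.2)
  expect_equal(s2$msa_delta, 4.2)
  # over-large window is clipped with a warning
  expect_warning(s3 <- summarize_surface(surf, msa_window = 9),
                 class = "synscreen_window_warning")
  expect_equal(s3$msa_delta, 4.2)
})

test_that("surface long-format export carries doses and deltas", {
  b <- bliss_null_block()
  s <- synergy_surface(b, "bliss")
  tab <- surface_table(s)
  expect_equal(nrow(tab), 25)
  expect_named(tab, c("block_id", "sample_id", "model", "conc_A", "conc_B",
                      "observed", "expected", "delta", "weight"))
  expect_equal(tab$delta, tab$observed - tab$expected, tolerance = 1e-12)
})
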