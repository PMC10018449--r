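# Stochastic sorting-junction outcome model.

test_that("required force is a power law, increasing in volume and frequency", {
  p <- junction_params()
  expect_gt(required_force(150, 1000, p), required_force(75, 1000, p))
  expect_gt(required_force(75, 2000, p), required_force(75, 1000, p))
  # default normalisation: 75 pL at 1 kHz requires unit force
  expect_equal(required_force(75, 1000, p), 1, tolerance = 1e-12)
  p0 <- junction_params(volume_exponent = 0, frequency_exponent = 0,
                        force_scale = 0.7)
  expect_equal(required_force(10, 500, p0), 0.7, tolerance = 1e-12)
  expect_equal(required_force(900, 3000, p0), 0.7, tolerance = 1e-12)
  expect_error(required_force(-1, 1000, p), class = "aads_config_error")
})

test_that("deterministic junction outcomes follow the force rules", {
  # unpulsed droplets follow the bias oil into the negative outlet, intact
  out <- resolve_outcome(c("negative", "positive"), pulsed = FALSE,
                         params = junction_params(seed = 1))
  expect_identical(out$outlet, c("negative", "negative"))
  expect_identical(out$fragmented, c(FALSE, FALSE))
  expect_identical(out$category, c("correct_negative", "false_negative"))
  # overwhelming force: certain intact positive sort
  strong <- junction_params(applied_force = 12, seed = 2)
  out2 <- resolve_outcome(rep("positive", 500), pulsed = TRUE, params = strong)
  expect_true(all(out2$category == "correct_positive"))
  expect_true(all(!out2$fragmented))
})

test_that("marginal force at 2 kHz produces fragmentation", {
  p <- junction_params(seed = 3)
  out <- resolve_outcome(rep("positive", 10000), pulsed = TRUE,
                         frequency_hz = 2000, params = p)
  expect_gt(mean(out$fragmented), 0)
  expect_true(all(out$category[out$fragmented] == "partial_false_negative"))
})

test_that("seeded junction draws are exactly reproducible", {
  p <- junction_params(seed = 4)
  a <- resolve_outcome(rep("positive", 200), TRUE, frequency_hz = 1500,
                       params = p)
  b <- resolve_outcome(rep("positive", 200), TRUE, frequency_hz = 1500,
                       params = p)
  expect_identical(a, b)
})

test_that("P(correct | pulsed positive) is non-increasing in frequency and volume", {
  n <- 10000
  p_at <- function(f, v, seed) {
    out <- resolve_outcome(rep("positive", n), TRUE, volume_pl = v,
                           frequency_hz = f,
                           params = junction_params(seed = seed))
    mean(out$category == "correct_positive")
  }
  se2 <- 2 * sqrt(0.25 / n)
  f_rates <- c(p_at(1000, 75, 5), p_at(1500, 75, 6), p_at(2000, 75, 7))
  expect_true(all(diff(f_rates) <= se2))
  v_rates <- c(p_at(1200, 60, 8), p_at(1200, 90, 9), p_at(1200, 140, 10))
  expect_true(all(diff(v_rates) <= se2))
})

test_that("efficiency sweep reproduces the frequency ordering with exact conservation", {
  sw <- sweep_efficiency(n_events = 2000, seed = 11)
  expect_identical(sw$frequency_hz, c(1000, 1500, 2000))
  # correct fraction 1 at 1 kHz under the default calibration, then decaying
  expect_equal(sw$correct[1], 1, tolerance = 1e-12)
  expect_true(all(diff(sw$correct) < 0))
  cats <- c("correct_positive", "correct_negative", "false_positive",
            "false_negative", "partial_false_positive",
            "partial_false_negative")
  expect_equal(rowSums(sw[, cats]), rep(1, 3), tolerance = 1e-12)
  # overwhelming force: perfect everywhere
  sw2 <- sweep_efficiency(n_events = 500,
                          params = junction_params(applied_force = 100),
                          seed = 12)
  expect_equal(sw2$correct, rep(1, 3), tolerance = 1e-12)
})
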