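# Streaming peak detection: recovery against simulator ground truth,
# chunking invariance, offline-oracle equivalence, flags.

test_that("a constant-baseline trace yields no events", {
  tr <- trace_signal(rep(1, 5000), 1e5)
  expect_identical(nrow(detect_events(tr)), 0L)
})

test_that("noise-free droplets are recovered with exact counts and tight absorbance", {
  tr <- simulate_trace(two_pop_train(0.1, seed = 1), quiet_acq())
  ev <- detect_events(tr)
  expect_identical(nrow(ev), 100L)
  expect_true(all(ev$flag == "resolved"))
  m <- match_events_truth(ev, tr$truth)
  expect_true(!anyNA(m) && !anyDuplicated(m))
  expect_true(all(abs(ev$absorbance - tr$truth$true_absorbance[m]) < 0.01))
})

test_that("recovery holds at default noise over 1000 droplets", {
  tr <- simulate_trace(two_pop_train(1, seed = 2))
  ev <- detect_events(tr)
  res <- ev[ev$flag == "resolved", ]
  m <- match_events_truth(res, tr$truth)
  # one-to-one recall of at least 99.9%
  matched <- unique(m[!is.na(m)])
  expect_gte(length(matched) / nrow(tr$truth), 0.999)
  expect_false(anyDuplicated(m[!is.na(m)]) > 0)
  expect_lt(mean(abs(res$absorbance - tr$truth$true_absorbance[m])), 0.02)
})

test_that("streaming detection is invariant to chunking", {
  tr <- simulate_trace(two_pop_train(0.03, seed = 3))
  whole <- detect_events(tr)
  expect_gt(nrow(whole), 20)
  for (size in c(1, 7, 997, 50000)) {
    chunked <- detect_events_streaming(split_chunks(tr$samples, size),
                                       sample_rate = tr$sample_rate)
    expect_identical(chunked, whole)
  }
})

test_that("streaming result matches an exhaustive offline segmentation", {
  # noise-free trace with a constant, known baseline
  params <- detector_params()
  tr <- simulate_trace(two_pop_train(0.3, seed = 4), quiet_acq())
  expect_lte(length(tr$samples), 50000)
  ev <- detect_events(tr, params)
  orc <- oracle_segment(tr$samples, 1.0, params, tr$sample_rate)
  orc <- orc[(orc$i_end - orc$i_start) / tr$sample_rate >= params$min_width, ]
  expect_identical(nrow(ev), nrow(orc))
  # same minima (oracle indices are 1-based, detector times 0-based); ties on
  # the flat dip bottom may fall on neighbouring samples
  expect_true(all(abs(ev$t_min_s - (orc$i_min - 1) / tr$sample_rate) < 2e-4))
  expect_equal(ev$v_min_v, orc$v_min, tolerance = 1e-9)
})

test_that("detection count is robust to moderate edge shoulders", {
  acq <- quiet_acq()
  base <- detect_events(simulate_trace(two_pop_train(0.1, seed = 5), acq))
  shoulder <- detect_events(simulate_trace(
    two_pop_train(0.1, seed = 5, oil = oil_mixture(0.30)), acq))
  expect_identical(nrow(shoulder), nrow(base))
  expect_identical(sum(shoulder$flag == "resolved"),
                   sum(base$flag == "resolved"))
})

test_that("broad merged peaks (unmatched oil, near-touching droplets) are unresolved", {
  trn <- train_config(0.05, oil = oil_mixture(0), transit_fraction = 0.98,
                      populations = tartrazine_populations(
                        conc_mm = 5, proportions = 1, volume_pl = 150),
                      seed = 6)
  ev <- detect_events(simulate_trace(trn))
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$flag == "unresolved"))
  expect_true(all(is.na(ev$absorbance)))
})

test_that("events touching the saturation ceiling are flagged saturated", {
  trn <- single_pop_train(0.05, seed = 7, oil = oil_mixture(0.1))
  ev <- detect_events(simulate_trace(trn),
                      detector_params(v_sat = 1.25))
  expect_gt(nrow(ev), 0)
  expect_true(any(ev$flag == "saturated"))
})

test_that("peak_absorbance enforces its domain and inverts transduction", {
  expect_identical(peak_absorbance(1, 1), 0)
  expect_equal(peak_absorbance(0.1, 1), 1, tolerance = 1e-12)
  expect_error(peak_absorbance(0, 1), class = "aads_data_error")
  expect_error(peak_absorbance(1.1, 1), class = "aads_data_error")
})

test_that("event frequency is the reciprocal median inter-event interval", {
  ev <- data.frame(t_min_s = seq(0, 0.099, by = 1e-3))
  expect_equal(event_frequency(ev), 1000, tolerance = 1e-9)
  ev2 <- data.frame(t_min_s = seq(0, 0.0495, by = 5e-4))
  expect_equal(event_frequency(ev2), 2000, tolerance = 1e-9)
  expect_error(event_frequency(ev[1, , drop = FALSE]),
               class = "aads_data_error")
  # jittered 1.5 kHz train recovered within 1%
  trn <- single_pop_train(0.4, seed = 8, frequency_hz = 1500,
                          jitter_sd = 5e-5)
  evj <- detect_events(simulate_trace(trn))
  expect_equal(event_frequency(evj), 1500, tolerance = 0.01)
})

test_that("event tables round-trip through TSV", {
  tr <- simulate_trace(two_pop_train(0.02, seed = 9))
  ev <- detect_events(tr)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(back$t_min_s, ev$t_min_s, tolerance = 1e-9)
  expect_identical(back$flag, ev$flag)
})
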