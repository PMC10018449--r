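# Synthetic photodetector traces: waveform anatomy, train structure, file IO.

test_that("droplet waveform reproduces the dip/shoulder anatomy", {
  acq <- quiet_acq()
  # index-matched oil, no chromophore: flat segment at the baseline
  matched <- oil_mixture(match_fraction(1.337))
  tr_flat <- train_config(0.01, oil = matched)
  water <- droplet_population(0, 75, "water", 1)
  expect_equal(droplet_waveform(water, tr_flat, acq),
               rep(acq$v0, 40), tolerance = 1e-12)

  # matched oil, chromophore: unimodal dip whose minimum is exactly the
  # Beer-Lambert transmitted voltage; no sample above the baseline
  pop <- tartrazine_populations(conc_mm = 5, proportions = 1)[[1]]
  w <- droplet_waveform(pop, tr_flat, acq)
  a_true <- absorbance(pop$concentration_m, pop$epsilon,
                       effective_path_length(pop$volume_pl))
  expect_equal(min(w), acq$v0 * 10^(-a_true), tolerance = 1e-12)
  expect_true(all(w <= acq$v0 + 1e-12))
  dips <- which(w < acq$v0 - 1e-9)
  expect_true(all(diff(dips) == 1))  # single contiguous dip

  # index mismatch: at least one sample above baseline at each edge
  tr_mis <- train_config(0.01, oil = oil_mixture(0.25))
  w2 <- droplet_waveform(water, tr_mis, acq)
  n <- length(w2)
  expect_gt(max(w2[1:(n %/% 2)]), acq$v0)
  expect_gt(max(w2[(n %/% 2):n]), acq$v0)
  # saturation clipping with unmatched oil (strong shoulders)
  w3 <- droplet_waveform(water, train_config(0.01, oil = oil_mixture(0)), acq)
  expect_true(all(w3 <= acq$v_sat))
  expect_true(any(w3 == acq$v_sat))
})

test_that("shoulder amplitude decays to zero at the index match point", {
  acq <- quiet_acq()
  water <- tartrazine_populations(conc_mm = 0, proportions = 1)
  phi_star <- match_fraction(1.337)
  phis <- seq(0, phi_star, length.out = 8)
  amps <- vapply(phis, function(p) {
    tr <- train_config(0.01, oil = oil_mixture(p), populations = water)
    max(simulate_trace(tr, acq)$samples) - acq$v0
  }, 0)
  expect_true(all(diff(amps) <= 1e-12))       # monotone non-increasing
  expect_lt(amps[length(amps)], 1e-9)         # zero at the match point
  expect_gt(amps[1], 0.2)                     # clipped-strong with plain oil
})

test_that("simulated trains have the configured event structure", {
  tr <- simulate_trace(train_config(1, seed = 1))
  expect_identical(nrow(tr$truth), 1000L)      # floor(T f) events
  expect_identical(length(tr$samples), 100000L)
  # truth intervals disjoint and ordered
  expect_true(all(diff(tr$truth$start_s) > 0))
  expect_true(all(tr$truth$end_s[-1000] <= tr$truth$start_s[-1]))
  expect_true(all(tr$samples <= acquisition_config()$v_sat))

  # determinism under a fixed seed
  tr2 <- simulate_trace(train_config(1, seed = 1))
  expect_identical(tr$samples, tr2$samples)
  expect_identical(tr$truth, tr2$truth)
  tr3 <- simulate_trace(train_config(1, seed = 2))
  expect_false(identical(tr$samples, tr3$samples))

  # jittered trains keep truth intervals disjoint
  trj <- simulate_trace(train_config(0.2, jitter_sd = 2e-4, seed = 3))
  expect_true(all(trj$truth$end_s[-nrow(trj$truth)] <= trj$truth$start_s[-1]))

  # too-coarse sampling is rejected
  expect_error(
    simulate_trace(train_config(0.1), acquisition_config(sample_rate = 1e4)),
    class = "aads_data_error")
})

test_that("the two tartrazine populations separate in the trace minima", {
  tr <- simulate_trace(two_pop_train(0.5, seed = 4))
  ev <- detect_events(tr)
  m <- match_events_truth(ev, tr$truth)
  lab <- tr$truth$label[m]
  v <- ev$v_min_v
  expect_lt(mean(v[lab == "tartrazine_5mM"]), mean(v[lab == "tartrazine_0.5mM"]))
})

test_that("empty droplets keep a small detectable residual dip", {
  tr <- simulate_trace(single_pop_train(0.5, seed = 5, empty_fraction = 0.3))
  ev <- detect_events(tr)
  m <- match_events_truth(ev, tr$truth)
  empt <- which(tr$truth$label == "empty")
  expect_gt(length(empt), 50)
  # nearly all empties are still detected (for frequency measurements)
  expect_gt(mean(empt %in% m), 0.99)
  a_emp <- ev$absorbance[!is.na(m) & m %in% empt]
  expect_true(all(a_emp < 0.05, na.rm = TRUE))
})

test_that("trace CSV and truth TSV round-trip losslessly", {
  tr <- simulate_trace(train_config(0.02, seed = 6))
  f <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, f, ft)
  back <- read_trace(f, ft)
  expect_equal(back$samples, tr$samples, tolerance = 1e-12)
  expect_equal(back$sample_rate, tr$sample_rate, tolerance = 1e-9)
  expect_equal(back$truth$start_s, tr$truth$start_s, tolerance = 1e-12)
  expect_identical(back$truth$label, tr$truth$label)

  # empty trace: header-only file reads back empty
  fe <- withr::local_tempfile(fileext = ".csv")
  write_trace(trace_signal(numeric(), 1e5), fe)
  expect_identical(readLines(fe)[1], "time_s,voltage_v")
  expect_identical(length(read_trace(fe)$samples), 0L)

  # malformed file: error names the offending line
  fb <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,voltage_v", "0,1.0", "1e-5,oops", "2e-5,1.0"), fb)
  expect_error(read_trace(fb), "line 3", class = "aads_data_error")
  fn <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,voltage_v", "0,1.0", "1e-5,1.0", "1e-5,1.0"), fn)
  expect_error(read_trace(fn), "line 4", class = "aads_data_error")
})
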