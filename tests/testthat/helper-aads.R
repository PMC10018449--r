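# Shared builders for the test suite. All fixtures are generated in code.

quiet_acq <- function(...) acquisition_config(noise_sd = 0, ...)

single_pop_train <- function(duration_s, conc_mm = 0.5, seed = 1, ...) {
  train_config(duration_s,
               populations = tartrazine_populations(conc_mm = conc_mm,
                                                    proportions = 1),
               seed = seed, ...)
}

two_pop_train <- function(duration_s, seed = 1, ...) {
  train_config(duration_s, seed = seed, ...)
}

# Independent offline segmentation oracle for noise-free, constant-baseline
# traces: smooth with the same causal moving average, mark samples outside
# the [baseline - enter_delta, baseline + shoulder_delta] band, take maximal
# runs, report each run's minimum (earliest index on ties).
oracle_segment <- function(samples, baseline, params, sample_rate) {
  k <- params$smooth_n
  y <- as.numeric(stats::filter(samples, rep(1 / k, k), sides = 1))
  # causal partial windows at the start
  for (i in seq_len(min(k - 1, length(samples)))) y[i] <- mean(samples[1:i])
  out <- y < baseline - params$enter_delta | y > baseline + params$shoulder_delta
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(i_start = starts[keep], i_end = ends[keep],
             i_min = mapply(function(a, b) a + which.min(y[a:b]) - 1L,
                            starts[keep], ends[keep]),
             v_min = mapply(function(a, b) min(y[a:b]), starts[keep], ends[keep]))
}

split_chunks <- function(x, size) {
  split(x, ceiling(seq_along(x) / size))
}
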