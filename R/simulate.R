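#' Droplet train configuration
#'
#' Describes a monodisperse droplet train passing the optical detection
#' point: droplet frequency, recording duration, the mixture of droplet
#' populations, the carrier oil and the phenomenological shoulder model.
#'
#' Edge shoulders are voltage excursions above baseline caused by refraction
#' at the water-oil interface. Their amplitude is modelled as
#' \eqn{s = k (n_{aq} - n_{mix})^2 V_0}: quadratic in the index mismatch, as
#' for Fresnel reflectance at a weak-contrast interface, so shoulders vanish
#' smoothly at the match point and reappear symmetrically on either side.
#' With the defaults the oil matches the aqueous phase at
#' `match_fraction(1.337)` which is approximately 34.3% additive.
#'
#' @param duration_s Recording duration, s.
#' @param frequency_hz Droplet frequency, Hz (typically 1000--2000).
#' @param populations List of [droplet_population()]; proportions must sum
#'   to 1.
#' @param oil An [oil_mixture()]; default 35% additive, effectively
#'   index-matched.
#' @param n_aqueous Refractive index of the droplet (aqueous) phase. Default
#'   1.337, representative of a buffered assay mix with cell lysate (slightly
#'   above pure water's 1.333).
#' @param transit_fraction Fraction of the droplet period during which the
#'   droplet occupies the optical path, in (0, 1).
#' @param shoulder_gain Shoulder gain `k`, V per squared refractive-index
#'   unit. The default (300) clips shoulders at the photodetector ceiling for
#'   unmatched oil and renders them negligible above ~30% additive.
#' @param empty_fraction Fraction of droplets that carry no chromophore.
#' @param empty_dip Residual fractional dip (relative to `v0`) of an empty
#'   droplet, so empties remain detectable for frequency and gating purposes.
#' @param jitter_sd Gaussian timing jitter of droplet centres, s. Jitter is
#'   clamped so droplet transit windows never overlap.
#' @param seed Integer seed; the simulation is deterministic given a seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(duration_s, frequency_hz = 1000,
                         populations = tartrazine_populations(),
                         oil = oil_mixture(0.35), n_aqueous = 1.337,
                         transit_fraction = 0.4, shoulder_gain = 300,
                         empty_fraction = 0, empty_dip = 0.02,
                         jitter_sd = 0, seed = NULL) {
  if (duration_s <= 0) .stop_config("duration_s must be positive")
  if (frequency_hz <= 0) .stop_config("frequency_hz must be positive")
  if (transit_fraction <= 0 || transit_fraction >= 1) {
    .stop_config("transit_fraction must lie in (0, 1)")
  }
  if (empty_fraction < 0 || empty_fraction > 1) {
    .stop_config("empty_fraction must lie in [0, 1]")
  }
  if (jitter_sd < 0) .stop_config("jitter_sd must be nonnegative")
  stopifnot(inherits(oil, "oil_mixture"))
  if (length(populations) == 0L ||
      !all(vapply(populations, inherits, TRUE, "droplet_population"))) {
    .stop_config("populations must be a nonempty list of droplet_population objects")
  }
  props <- vapply(populations, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-8) {
    .stop_config("population proportions must sum to 1 (got ", sum(props), ")")
  }
  structure(list(duration_s = duration_s, frequency_hz = frequency_hz,
                 populations = populations, oil = oil, n_aqueous = n_aqueous,
                 transit_fraction = transit_fraction,
                 shoulder_gain = shoulder_gain,
                 empty_fraction = empty_fraction, empty_dip = empty_dip,
                 jitter_sd = jitter_sd, seed = seed),
            class = "train_config")
}

# Shoulder peak amplitude in volts for a train's oil/aqueous pair.
shoulder_amplitude <- function(train, acq) {
  dn <- train$n_aqueous - mixture_refractive_index(train$oil)
  train$shoulder_gain * dn * dn * acq$v0
}

# Tukey-style dip profile on u in [0, 1): cosine ramps over the outer
# `taper` fraction, flat at 1 in the middle. The flat bottom guarantees the
# sampled minimum equals the Beer-Lambert prediction exactly (noise-free).
.dip_profile <- function(u, taper = 0.3) {
  w <- numeric(length(u))
  lo <- u < taper
  hi <- u > 1 - taper
  w[lo] <- 0.5 * (1 - cos(pi * u[lo] / taper))
  w[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / taper))
  w[!lo & !hi] <- 1
  w
}

# Raised-cosine shoulder lobes over the outer `edge` fraction of the transit.
.shoulder_profile <- function(u, edge = 0.15) {
  g <- numeric(length(u))
  lo <- u < edge
  hi <- u > 1 - edge
  g[lo] <- 0.5 * (1 - cos(2 * pi * u[lo] / edge))
  g[hi] <- 0.5 * (1 - cos(2 * pi * (1 - u[hi]) / edge))
  g
}

#' Noise-free voltage waveform of a single droplet transit
#'
#' One droplet produces a smooth symmetric dip from the baseline `v0` down to
#' the Beer-Lambert transmitted voltage, flanked by two shoulder lobes above
#' baseline whose amplitude follows the squared refractive-index mismatch
#' between the aqueous phase and the carrier oil. The waveform is clipped at
#' the photodetector saturation ceiling. With index-matched oil no sample
#' exceeds `v0`.
#'
#' @param pop A [droplet_population()].
#' @param train A [train_config()] (supplies oil, aqueous index, shoulder
#'   gain and transit fraction).
#' @param acq An [acquisition_config()].
#' @param n_samples Number of samples across the transit window; defaults to
#'   the transit duration at the acquisition sampling rate.
#' @param residual_dip Residual fractional dip floor (used for empty
#'   droplets); 0 gives a perfectly flat segment when the concentration is 0
#'   and the oil is matched.
#' @return Numeric vector of voltages of length `n_samples`.
#' @export
droplet_waveform <- function(pop, train, acq = acquisition_config(),
                             n_samples = NULL, residual_dip = 0) {
  stopifnot(inherits(pop, "droplet_population"), inherits(train, "train_config"),
            inherits(acq, "acquisition_config"))
  if (is.null(n_samples)) {
    n_samples <- max(1L, floor(train$transit_fraction / train$frequency_hz *
                                 acq$sample_rate))
  }
  a <- absorbance(pop$concentration_m, pop$epsilon,
                  effective_path_length(pop$volume_pl, acq$channel_depth_um))
  v_min <- min(acq$v0 * 10^(-a), acq$v0 * (1 - residual_dip))
  s <- shoulder_amplitude(train, acq)
  u <- (seq_len(n_samples) - 1) / n_samples
  v <- acq$v0 - (acq$v0 - v_min) * .dip_profile(u) + s * .shoulder_profile(u)
  pmin(pmax(v, 0), acq$v_sat)
}

#' Simulate a photodetector trace of a droplet train
#'
#' Places `floor(duration_s * frequency_hz)` droplets at regular intervals
#' (with optional clamped Gaussian timing jitter), draws each droplet's
#' population by the configured proportions (or marks it empty), superimposes
#' each droplet's waveform on the baseline, adds Gaussian voltage noise and
#' clips at the saturation ceiling. The returned object carries a ground-truth
#' event log.
#'
#' @param train A [train_config()].
#' @param acq An [acquisition_config()].
#' @return An object of class `trace_signal`: a list with `sample_rate`,
#'   `samples` (voltage vector) and `truth`, a data frame with columns
#'   `start_s`, `end_s`, `label`, `true_absorbance`.
#' @examples
#' tr <- simulate_trace(train_config(0.05, seed = 1))
#' tr
#' @export
simulate_trace <- function(train, acq = acquisition_config()) {
  stopifnot(inherits(train, "train_config"), inherits(acq, "acquisition_config"))
  transit_n <- floor(train$transit_fraction / train$frequency_hz * acq$sample_rate)
  if (transit_n < 8) {
    .stop_data("fewer than 8 samples per droplet transit (", transit_n,
               "); increase sample_rate or transit_fraction")
  }
  n_total <- floor(train$duration_s * acq$sample_rate)
  n_drops <- floor(train$duration_s * train$frequency_hz)
  period <- 1 / train$frequency_hz
  half_transit <- train$transit_fraction * period / 2

  with_local_seed(train$seed, {
    samples <- rep(acq$v0, n_total)
    centres <- (seq_len(n_drops) - 0.5) * period
    if (train$jitter_sd > 0 && n_drops > 0) {
      jit <- rnorm(n_drops, 0, train$jitter_sd)
      # clamp so transit windows stay inside their own period (disjoint truth)
      slack <- (period / 2 - half_transit) * 0.999
      jit <- pmax(pmin(jit, slack), -slack)
      centres <- centres + jit
    }
    n_pop <- length(train$populations)
    props <- vapply(train$populations, `[[`, 0, "proportion")
    pop_idx <- if (n_drops > 0) sample.int(n_pop, n_drops, replace = TRUE, prob = props) else integer()
    is_empty <- if (n_drops > 0) runif(n_drops) < train$empty_fraction else logical()

    labels <- character(n_drops)
    true_a <- numeric(n_drops)
    start_s <- numeric(n_drops)
    end_s <- numeric(n_drops)

    for (k in seq_len(n_drops)) {
      t_a <- centres[k] - half_transit
      i0 <- floor(t_a * acq$sample_rate) + 1  # first sample index inside window
      idx <- i0:(i0 + transit_n - 1L)
      keep <- idx >= 1L & idx <= n_total
      pop <- train$populations[[pop_idx[k]]]
      if (is_empty[k]) {
        pop <- droplet_population(0, pop$volume_pl, "empty", 1, pop$epsilon)
        seg <- droplet_waveform(pop, train, acq, transit_n,
                                residual_dip = train$empty_dip)
        labels[k] <- "empty"
        true_a[k] <- 0
      } else {
        seg <- droplet_waveform(pop, train, acq, transit_n)
        labels[k] <- pop$label
        true_a[k] <- absorbance(pop$concentration_m, pop$epsilon,
                                effective_path_length(pop$volume_pl,
                                                      acq$channel_depth_um))
      }
      samples[idx[keep]] <- seg[keep]
      start_s[k] <- t_a
      end_s[k] <- t_a + 2 * half_transit
    }

    if (acq$noise_sd > 0) samples <- samples + rnorm(n_total, 0, acq$noise_sd)
    samples <- pmin(pmax(samples, 0), acq$v_sat)

    structure(list(sample_rate = acq$sample_rate, samples = samples,
                   truth = data.frame(start_s = start_s, end_s = end_s,
                                      label = labels, true_absorbance = true_a,
                                      stringsAsFactors = FALSE)),
              class = "trace_signal")
  })
}

#' Construct a trace signal from raw samples
#'
#' @param samples Numeric voltage vector, uniformly sampled.
#' @param sample_rate Sampling rate, Hz.
#' @param truth Optional ground-truth event log (data frame with `start_s`,
#'   `end_s`, `label`, `true_absorbance`).
#' @return A `trace_signal` object.
#' @export
trace_signal <- function(samples, sample_rate, truth = NULL) {
  if (sample_rate <= 0) .stop_config("sample_rate must be positive")
  structure(list(sample_rate = sample_rate, samples = as.numeric(samples),
                 truth = truth), class = "trace_signal")
}

#' @export
print.trace_signal <- function(x, ...) {
  cat(sprintf("droplet trace: %d samples @ %g Hz (%.3f s)",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  if (!is.null(x$truth)) cat(sprintf(", %d truth events", nrow(x$truth)))
  cat("\n")
  invisible(x)
}

#' Write / read a voltage trace as CSV
#'
#' The trace file is a two-column CSV with header `time_s,voltage_v` and a
#' strictly increasing uniform time grid. The ground-truth event log, if
#' present, goes to a TSV sidecar with columns
#' `start_s`, `end_s`, `label`, `true_absorbance`.
#'
#' @param trace A `trace_signal`.
#' @param path Path of the trace CSV.
#' @param truth_path Optional path of the truth sidecar TSV.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `trace_signal`.
#' @export
write_trace <- function(trace, path, truth_path = NULL) {
  stopifnot(inherits(trace, "trace_signal"))
  n <- length(trace$samples)
  dt <- data.table::data.table(
    time_s = if (n) (seq_len(n) - 1) / trace$sample_rate else numeric(),
    voltage_v = trace$samples)
  data.table::fwrite(dt, path)
  if (!is.null(truth_path)) {
    if (is.null(trace$truth)) {
      data.table::fwrite(data.table::data.table(
        start_s = numeric(), end_s = numeric(), label = character(),
        true_absorbance = numeric()), truth_path, sep = "\t")
    } else {
      data.table::fwrite(trace$truth, truth_path, sep = "\t")
    }
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, truth_path = NULL) {
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = ","),
    error = function(e) .stop_data("cannot parse trace file '", path, "': ",
                                   conditionMessage(e)))
  if (!identical(names(dt), c("time_s", "voltage_v"))) {
    .stop_data("trace file '", path,
               "' line 1: expected header 'time_s,voltage_v', got '",
               paste(names(dt), collapse = ","), "'")
  }
  if (nrow(dt) == 0L) return(trace_signal(numeric(), sample_rate = 1))
  dt$time_s <- suppressWarnings(as.numeric(dt$time_s))
  dt$voltage_v <- suppressWarnings(as.numeric(dt$voltage_v))
  bad <- which(!is.finite(dt$time_s) | !is.finite(dt$voltage_v))
  if (length(bad)) {
    .stop_data("trace file '", path, "' line ", bad[1] + 1L,
               ": malformed numeric value")
  }
  if (nrow(dt) == 1L) {
    sr <- 1
  } else {
    steps <- diff(dt$time_s)
    if (any(steps <= 0)) {
      .stop_data("trace file '", path, "' line ", which(steps <= 0)[1] + 2L,
                 ": time not strictly increasing")
    }
    if (max(steps) - min(steps) > 1e-9 * steps[1]) {
      .stop_data("trace file '", path, "' line ",
                 which.max(abs(steps - steps[1])) + 2L,
                 ": non-uniform time step")
    }
    sr <- 1 / steps[1]
  }
  truth <- NULL
  if (!is.null(truth_path)) {
    truth <- as.data.frame(data.table::fread(truth_path, sep = "\t"))
  }
  trace_signal(dt$voltage_v, sr, truth)
}
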