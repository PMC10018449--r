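#' Peak-detector parameters
#'
#' Tuning constants of the streaming droplet-event detector. All voltage
#' deltas are relative to the tracked baseline; widths and times are in
#' seconds.
#'
#' @param baseline_alpha Exponential-moving-average factor for the baseline,
#'   in (0, 1]. Only samples inside the baseline band update the baseline, so
#'   dips and shoulders cannot drag it.
#' @param enter_delta Drop below baseline (V) that opens a dip event.
#' @param shoulder_delta Rise above baseline (V) recognised as an edge
#'   shoulder; shoulders open events too and are absorbed into the adjacent
#'   dip rather than reported separately.
#' @param exit_band Half-width (V) of the band around the opening baseline
#'   within which the signal must stay for `debounce` consecutive samples to
#'   close an event.
#' @param min_width Events narrower than this are discarded as noise blips, s.
#' @param max_width Events wider than this are flagged `unresolved`
#'   (merged/broad peaks with no identifiable minimum), s.
#' @param debounce Number of consecutive in-band samples required to close an
#'   event.
#' @param smooth_n Length (samples) of the causal moving average applied
#'   before thresholding and minimum extraction; suppresses single-sample
#'   noise without biasing flat-bottomed dips.
#' @param init_time Length (s) of the initial window whose median seeds the
#'   baseline estimate. The window is buffered and replayed, so events inside
#'   it are still detected.
#' @param v_sat Photodetector saturation ceiling (V); events touching it are
#'   flagged `saturated`. `Inf` disables the check.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(baseline_alpha = 0.01, enter_delta = 0.012,
                            shoulder_delta = 0.02, exit_band = 0.01,
                            min_width = 1e-4, max_width = 2e-3,
                            debounce = 3L, smooth_n = 5L,
                            init_time = 0.01, v_sat = Inf) {
  if (baseline_alpha <= 0 || baseline_alpha > 1) {
    .stop_config("baseline_alpha must lie in (0, 1]")
  }
  if (enter_delta <= 0 || shoulder_delta <= 0 || exit_band <= 0) {
    .stop_config("enter_delta, shoulder_delta and exit_band must be positive")
  }
  if (min_width >= max_width) .stop_config("min_width must be < max_width")
  if (debounce < 1 || smooth_n < 1) {
    .stop_config("debounce and smooth_n must be >= 1")
  }
  structure(list(baseline_alpha = baseline_alpha, enter_delta = enter_delta,
                 shoulder_delta = shoulder_delta, exit_band = exit_band,
                 min_width = min_width, max_width = max_width,
                 debounce = as.integer(debounce), smooth_n = as.integer(smooth_n),
                 init_time = init_time, v_sat = v_sat),
            class = "detector_params")
}

# Convert raw emitted events (0-based sample indices) to the public event
# table: times in seconds, width filtering, flags and absorbance.
.postprocess_events <- function(raw, params, sample_rate) {
  ev <- data.frame(i_start = raw$i_start, i_min = raw$i_min, i_end = raw$i_end,
                   v_min = raw$v_min, baseline = raw$baseline,
                   below = as.logical(raw$below),
                   saturated = as.logical(raw$saturated),
                   forced_open = as.logical(raw$forced_open))
  ev$t_start_s <- ev$i_start / sample_rate
  ev$t_min_s <- ev$i_min / sample_rate
  ev$t_end_s <- ev$i_end / sample_rate
  ev$width_s <- ev$t_end_s - ev$t_start_s
  ev <- ev[ev$width_s >= params$min_width, , drop = FALSE]
  n <- nrow(ev)
  flag <- rep("resolved", n)
  unres <- ev$forced_open | ev$width_s > params$max_width | !ev$below |
    ev$v_min <= 0
  flag[unres] <- "unresolved"
  flag[!unres & ev$saturated] <- "saturated"
  a <- rep(NA_real_, n)
  ok <- !unres & ev$v_min > 0 & ev$v_min <= ev$baseline
  a[ok] <- -log10(ev$v_min[ok] / ev$baseline[ok])
  # minima above the frozen baseline cannot occur for dip events that set
  # `below`; guard anyway
  a[!unres & !ok] <- NA_real_
  out <- data.frame(t_start_s = ev$t_start_s, t_min_s = ev$t_min_s,
                    t_end_s = ev$t_end_s, v_min_v = ev$v_min,
                    baseline_v = ev$baseline, absorbance = a,
                    width_s = ev$width_s, flag = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.empty_events <- function() {
  data.frame(t_start_s = numeric(), t_min_s = numeric(), t_end_s = numeric(),
             v_min_v = numeric(), baseline_v = numeric(),
             absorbance = numeric(), width_s = numeric(), flag = character(),
             stringsAsFactors = FALSE)
}

#' Create a streaming droplet-event detector
#'
#' Low-level streaming interface with constant per-sample work and memory:
#' feed voltage samples in chunks of any size, then finish. The emitted event
#' list is identical for every chunking of the same trace (including chunk
#' size 1), and identical to the offline [detect_events()].
#'
#' @inheritParams detect_events
#' @param sample_rate Sampling rate of the incoming samples, Hz.
#' @return An object of class `stream_detector` with methods
#'   `$feed(samples)` (returns events closed so far, invisibly accumulates)
#'   and `$finish()` (returns the complete event table).
#' @examples
#' det <- stream_detector(sample_rate = 1e5)
#' tr <- simulate_trace(train_config(0.02, seed = 1))
#' for (chunk in split(tr$samples, ceiling(seq_along(tr$samples) / 1000)))
#'   det$feed(chunk)
#' ev <- det$finish()
#' @export
stream_detector <- function(params = detector_params(), sample_rate) {
  stopifnot(inherits(params, "detector_params"), sample_rate > 0)
  init_n <- max(1L, as.integer(round(params$init_time * sample_rate)))
  state <- cpp_detector_init(params$smooth_n, init_n)
  raws <- list()
  done <- FALSE
  feed <- function(samples) {
    if (done) .stop_data("detector already finished")
    res <- cpp_detector_feed(as.numeric(samples), state,
                             params$baseline_alpha, params$enter_delta,
                             params$shoulder_delta, params$exit_band,
                             params$debounce, params$v_sat)
    state <<- res$state
    raws[[length(raws) + 1L]] <<- res$events
    invisible(.postprocess_events(res$events, params, sample_rate))
  }
  finish <- function() {
    if (done) .stop_data("detector already finished")
    res <- cpp_detector_finish(state, params$baseline_alpha,
                               params$enter_delta, params$shoulder_delta,
                               params$exit_band, params$debounce,
                               params$v_sat)
    raws[[length(raws) + 1L]] <<- res$events
    done <<- TRUE
    all <- list(
      i_start = unlist(lapply(raws, `[[`, "i_start")),
      i_min = unlist(lapply(raws, `[[`, "i_min")),
      i_end = unlist(lapply(raws, `[[`, "i_end")),
      v_min = unlist(lapply(raws, `[[`, "v_min")),
      baseline = unlist(lapply(raws, `[[`, "baseline")),
      below = unlist(lapply(raws, `[[`, "below")),
      saturated = unlist(lapply(raws, `[[`, "saturated")),
      forced_open = unlist(lapply(raws, `[[`, "forced_open")))
    if (length(all$i_start) == 0L) return(.empty_events())
    .postprocess_events(all, params, sample_rate)
  }
  structure(list(feed = feed, finish = finish), class = "stream_detector")
}

#' Detect droplet events in a voltage trace
#'
#' Extracts droplet passages from a uniformly sampled photodetector trace.
#' An event opens when the (smoothed) signal leaves the baseline band --
#' either dipping below `baseline - enter_delta` or rising above
#' `baseline + shoulder_delta` (an edge shoulder) -- and closes once the
#' signal has returned within `exit_band` of the baseline for `debounce`
#' consecutive samples, so shoulder spikes are attached to their droplet's
#' dip and the true absorbance minimum between the spikes is recovered.
#' Events wider than `max_width` or whose minimum never crosses
#' `enter_delta` below baseline (broad/merged peaks with no identifiable
#' minimum) are flagged `unresolved` and carry no absorbance; events that
#' touch the saturation ceiling are flagged `saturated`.
#'
#' @param trace A `trace_signal` (see [simulate_trace()], [read_trace()]).
#' @param params A [detector_params()].
#' @return A data frame with one row per event and columns `t_start_s`,
#'   `t_min_s`, `t_end_s`, `v_min_v`, `baseline_v`, `absorbance`, `width_s`,
#'   `flag` (`"resolved"`, `"unresolved"` or `"saturated"`).
#' @examples
#' tr <- simulate_trace(train_config(0.02, seed = 1))
#' ev <- detect_events(tr)
#' table(ev$flag)
#' @export
detect_events <- function(trace, params = detector_params()) {
  stopifnot(inherits(trace, "trace_signal"))
  det <- stream_detector(params, trace$sample_rate)
  det$feed(trace$samples)
  det$finish()
}

#' @rdname detect_events
#' @param chunks A list of numeric vectors that concatenate to the full
#'   trace.
#' @param sample_rate Sampling rate, Hz.
#' @export
detect_events_streaming <- function(chunks, params = detector_params(),
                                    sample_rate) {
  det <- stream_detector(params, sample_rate)
  for (ch in chunks) det$feed(ch)
  det$finish()
}

#' Absorbance from a peak minimum
#'
#' Inverse of [transmitted_voltage()] below saturation:
#' \eqn{A = -\log_{10}(V_{min} / V_{baseline})}.
#'
#' @param v_min Minimum voltage inside the event, V; must be positive and
#'   not exceed `baseline`.
#' @param baseline Baseline voltage at the event, V.
#' @return Absorbance (AU).
#' @export
peak_absorbance <- function(v_min, baseline) {
  if (any(v_min <= 0)) .stop_data("v_min must be positive")
  if (any(v_min > baseline)) .stop_data("v_min must not exceed the baseline")
  -log10(v_min / baseline)
}

#' Droplet frequency from detected events
#'
#' The reciprocal of the median inter-event interval (all events count,
#' including unresolved ones: empty droplets matter for frequency).
#'
#' @param events An event table from [detect_events()].
#' @return Estimated droplet frequency, Hz.
#' @export
event_frequency <- function(events) {
  if (nrow(events) < 2L) .stop_data("need at least 2 events to estimate frequency")
  1 / median(diff(events$t_min_s))
}

#' Write / read a detected-event table as TSV
#'
#' Columns: `t_start_s`, `t_min_s`, `t_end_s`, `v_min_v`, `baseline_v`,
#' `absorbance`, `width_s`, `flag`.
#'
#' @param events Event table from [detect_events()].
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path, sep = "\t")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
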