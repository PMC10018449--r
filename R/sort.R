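#' Sorting gate
#'
#' Acceptance window for sorting decisions, expressed in absorbance units so
#' it is invariant to baseline drift (a volts mode gates on the raw event
#' minimum instead, reproducing simpler firmware).
#'
#' @param a_low,a_high Absorbance bounds of the gate (volts bounds on
#'   `v_min_v` when `mode = "volts"`).
#' @param min_width,max_width Acceptable event widths, s.
#' @param sort_empty Should detectable empty droplets ever trigger? Default
#'   `FALSE`; with the gate expressed in absorbance this only matters for
#'   gates reaching down to ~0 AU.
#' @param mode `"absorbance"` (default) or `"volts"`.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(a_low = 0.5, a_high = 1.5, min_width = 1e-4,
                        max_width = 2e-3, sort_empty = FALSE,
                        mode = c("absorbance", "volts")) {
  mode <- match.arg(mode)
  if (a_low >= a_high) .stop_config("a_low must be < a_high")
  if (min_width <= 0 || max_width <= 0 || min_width >= max_width) {
    .stop_config("need 0 < min_width < max_width")
  }
  structure(list(a_low = a_low, a_high = a_high, min_width = min_width,
                 max_width = max_width, sort_empty = sort_empty, mode = mode),
            class = "gate_config")
}

#' Electrode pulse timing
#'
#' @param delay Detector-to-electrode travel time: a triggering droplet
#'   reaches the sorting junction `delay` seconds after its event closes, s.
#' @param width Pulse duration, s.
#' @param refractory Minimum spacing between accepted pulse starts, s; a
#'   trigger arriving within the refractory period of the previous accepted
#'   one is dropped (a sorter cannot stack pulses), not queued.
#' @return An object of class `pulse_config`.
#' @export
pulse_config <- function(delay = 5e-4, width = 1e-4, refractory = 5e-4) {
  if (delay <= 0 || width <= 0 || refractory <= 0) {
    .stop_config("delay, width and refractory must be positive")
  }
  if (refractory < width) .stop_config("refractory must be >= width")
  structure(list(delay = delay, width = width, refractory = refractory),
            class = "pulse_config")
}

#' Sorting decision for detected events
#'
#' A detected event triggers the sorter iff it is resolved (unresolved and
#' saturated events never trigger -- fail-safe), its absorbance lies inside
#' the gate and its width lies within the gate's width bounds. The decision
#' is made at event close (`t_end_s`): the full dip must have been observed,
#' as for a causal controller.
#'
#' @param events Event table from [detect_events()] (vectorised over rows).
#' @param gate A [gate_config()].
#' @return Logical vector: trigger or not, one per event.
#' @export
decide <- function(events, gate = gate_config()) {
  stopifnot(inherits(gate, "gate_config"))
  if (nrow(events) == 0L) return(logical())
  value <- if (gate$mode == "volts") events$v_min_v else events$absorbance
  ok <- events$flag == "resolved" &
    !is.na(value) & value >= gate$a_low & value <= gate$a_high &
    events$width_s >= gate$min_width & events$width_s <= gate$max_width
  ok & !is.na(ok)
}

#' Schedule electrode pulses from sorting decisions
#'
#' Each accepted trigger at decision time `t` yields a pulse interval
#' `[t + delay, t + delay + width]`. Triggers arriving within the refractory
#' period of the previously accepted trigger are dropped and logged.
#'
#' @param decision_times Nondecreasing times (s) of accepted sorting
#'   decisions (event close times).
#' @param pulse A [pulse_config()].
#' @return A data frame with columns `t_decision_s`, `triggered`,
#'   `t_pulse_start_s`, `t_pulse_end_s`, `drop_reason` (`""` or
#'   `"refractory"`).
#' @export
schedule_pulses <- function(decision_times, pulse = pulse_config()) {
  stopifnot(inherits(pulse, "pulse_config"))
  n <- length(decision_times)
  if (n == 0L) {
    return(data.frame(t_decision_s = numeric(), triggered = logical(),
                      t_pulse_start_s = numeric(), t_pulse_end_s = numeric(),
                      drop_reason = character(), stringsAsFactors = FALSE))
  }
  if (is.unsorted(decision_times)) {
    .stop_data("decision times must be nondecreasing")
  }
  triggered <- logical(n)
  reason <- character(n)
  last_start <- -Inf
  for (k in seq_len(n)) {
    t_start <- decision_times[k] + pulse$delay
    if (t_start - last_start < pulse$refractory) {
      triggered[k] <- FALSE
      reason[k] <- "refractory"
    } else {
      triggered[k] <- TRUE
      reason[k] <- ""
      last_start <- t_start
    }
  }
  data.frame(t_decision_s = decision_times, triggered = triggered,
             t_pulse_start_s = ifelse(triggered, decision_times + pulse$delay, NA_real_),
             t_pulse_end_s = ifelse(triggered, decision_times + pulse$delay + pulse$width, NA_real_),
             drop_reason = reason, stringsAsFactors = FALSE)
}

#' Run the full detector + trigger engine over a trace
#'
#' Single pass over the samples: streaming event detection, gating at event
#' close, and pulse scheduling. Output is identical for any chunking of the
#' trace and the per-sample cost is constant.
#'
#' @param trace A `trace_signal`.
#' @param params A [detector_params()].
#' @param gate A [gate_config()].
#' @param pulse A [pulse_config()].
#' @param chunk_size Optional chunk length (samples) used to feed the
#'   detector; the result is chunking-invariant, this only exercises the
#'   streaming path.
#' @return A list with `events` (event table), `decisions` (decision/pulse
#'   log: events joined to triggers) and `pulses` (accepted pulse intervals).
#' @export
run_sorter <- function(trace, params = detector_params(),
                       gate = gate_config(), pulse = pulse_config(),
                       chunk_size = NULL) {
  stopifnot(inherits(trace, "trace_signal"))
  if (is.null(chunk_size)) {
    events <- detect_events(trace, params)
  } else {
    idx <- seq_along(trace$samples)
    chunks <- split(trace$samples, ceiling(idx / chunk_size))
    events <- detect_events_streaming(chunks, params, trace$sample_rate)
  }
  trig <- decide(events, gate)
  sched <- schedule_pulses(events$t_end_s[trig], pulse)
  decisions <- data.frame(t_decision_s = events$t_end_s,
                          absorbance = events$absorbance,
                          flag = events$flag,
                          gated = trig,
                          triggered = FALSE,
                          t_pulse_start_s = NA_real_,
                          t_pulse_end_s = NA_real_,
                          drop_reason = ifelse(trig, "", "gate"),
                          stringsAsFactors = FALSE)
  if (any(trig)) {
    decisions$triggered[trig] <- sched$triggered
    decisions$t_pulse_start_s[trig] <- sched$t_pulse_start_s
    decisions$t_pulse_end_s[trig] <- sched$t_pulse_end_s
    decisions$drop_reason[trig] <- sched$drop_reason
  }
  pulses <- sched[sched$triggered, c("t_pulse_start_s", "t_pulse_end_s"),
                  drop = FALSE]
  rownames(pulses) <- NULL
  list(events = events, decisions = decisions, pulses = pulses)
}
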