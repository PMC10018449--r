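#' Match detected events to ground-truth droplets
#'
#' One-to-one matching by time: an event belongs to the truth droplet whose
#' transit interval contains the event minimum. Used for parameter-recovery
#' checks and for resolving per-droplet sorting outcomes in simulated runs.
#'
#' @param events Event table from [detect_events()].
#' @param truth Truth log of a simulated trace (`trace$truth`).
#' @return Integer vector of length `nrow(events)`: row index into `truth`,
#'   or `NA` for events matching no truth droplet.
#' @export
match_events_truth <- function(events, truth) {
  if (nrow(events) == 0L) return(integer())
  idx <- findInterval(events$t_min_s, truth$start_s)
  ok <- idx >= 1L & events$t_min_s <= truth$end_s[pmax(idx, 1L)]
  ifelse(ok, idx, NA_integer_)
}

#' Resolve per-droplet sorting outcomes for a simulated run
#'
#' Combines the trigger engine's pulse schedule with the junction model:
#' every truth droplet is marked pulsed iff one of its detected events
#' produced an accepted pulse, its outcome at the junction is drawn from the
#' junction model, and pulses are checked for neighbour capture (another
#' droplet whose junction arrival falls inside the pulse interval is
#' deflected too, and the triggering droplet is then not "sorted alone").
#'
#' @param trace A simulated `trace_signal` with a truth log.
#' @param sorter_out Result of [run_sorter()] on that trace.
#' @param positive_labels Truth labels counted as truly positive.
#' @param frequency_hz Droplet frequency of the train, Hz.
#' @param volume_pl Droplet volume, pL.
#' @param junction A [junction_params()].
#' @param pulse The [pulse_config()] used by the sorter (for arrival times).
#' @return A data frame, one row per truth droplet: `droplet_id`, `label`,
#'   `true_label`, `pulsed`, `outlet`, `fragmented`, `category`, `alone`.
#' @export
resolve_sort_outcomes <- function(trace, sorter_out, positive_labels,
                                  frequency_hz, volume_pl = 75,
                                  junction = junction_params(),
                                  pulse = pulse_config()) {
  truth <- trace$truth
  n <- nrow(truth)
  events <- sorter_out$events
  decisions <- sorter_out$decisions
  ev_match <- match_events_truth(events, truth)

  pulsed <- rep(FALSE, n)
  t_arrival <- truth$end_s + pulse$delay
  pulse_of <- rep(NA_integer_, n)  # accepted-pulse row triggering droplet k
  acc <- which(decisions$triggered)
  if (length(acc)) {
    ev_rows <- acc  # decisions rows align with events rows
    for (j in seq_along(ev_rows)) {
      k <- ev_match[ev_rows[j]]
      if (!is.na(k)) {
        pulsed[k] <- TRUE
        pulse_of[k] <- j
        t_arrival[k] <- decisions$t_pulse_start_s[ev_rows[j]]
      }
    }
  }
  # droplets whose own event exists get arrival at their event close + delay
  own_ev <- which(!is.na(ev_match))
  t_arrival[ev_match[own_ev]] <- events$t_end_s[own_ev] + pulse$delay

  true_label <- ifelse(truth$label %in% positive_labels, "positive", "negative")
  out <- resolve_outcome(true_label, pulsed, volume_pl = volume_pl,
                         frequency_hz = frequency_hz, params = junction)

  # neighbour capture: an unpulsed droplet arriving during someone else's
  # pulse is deflected into the positive outlet (intact)
  alone <- rep(TRUE, n)
  pl <- sorter_out$pulses
  if (nrow(pl) && n > 0) {
    for (k in which(!pulsed)) {
      hit <- which(t_arrival[k] >= pl$t_pulse_start_s &
                     t_arrival[k] <= pl$t_pulse_end_s)
      if (length(hit)) {
        out$outlet[k] <- "positive"
        out$category[k] <- if (true_label[k] == "positive") "correct_positive"
                           else "false_positive"
        trig <- which(!is.na(pulse_of) & pulse_of == hit[1])
        if (length(trig)) alone[trig] <- FALSE
      }
    }
  }
  data.frame(droplet_id = seq_len(n), label = truth$label,
             true_label = true_label, pulsed = pulsed,
             outlet = out$outlet, fragmented = out$fragmented,
             category = out$category, alone = alone,
             stringsAsFactors = FALSE)
}

#' Tally sorting outcomes
#'
#' Fractions of the six outcome categories (they sum to 1 exactly), plus the
#' overall `correct` fraction. A droplet counts as correct only if its
#' category is `correct_*` (hence intact) and it was sorted alone -- a
#' triggering droplet whose pulse also captured a neighbour is not correctly
#' sorted.
#'
#' @param outcomes Data frame with a `category` column (and optionally
#'   `alone`), e.g. from [resolve_outcome()] or [resolve_sort_outcomes()].
#' @return Named numeric vector: the six category fractions and `correct`.
#' @export
tally_outcomes <- function(outcomes) {
  if (NROW(outcomes) == 0L) .stop_data("cannot tally an empty outcome list")
  cats <- c("correct_positive", "correct_negative", "false_positive",
            "false_negative", "partial_false_positive",
            "partial_false_negative")
  fr <- vapply(cats, function(cc) mean(outcomes$category == cc), 0)
  alone <- if ("alone" %in% names(outcomes)) outcomes$alone else TRUE
  correct <- mean(outcomes$category %in% c("correct_positive",
                                           "correct_negative") & alone)
  c(fr, correct = correct)
}

#' Run a complete simulated sorting experiment
#'
#' Trace simulation, streaming detection, gating, pulse scheduling and
#' junction resolution for a droplet train, returning per-droplet outcomes
#' and their tally. This is the desk-scale analogue of videoing ~100 sorting
#' events and scoring each droplet's fate.
#'
#' @param train A [train_config()].
#' @param acq An [acquisition_config()].
#' @param params A [detector_params()].
#' @param gate A [gate_config()].
#' @param pulse A [pulse_config()].
#' @param junction A [junction_params()].
#' @param positive_labels Truth labels counted as truly positive; default:
#'   the last population's label (the high-absorbance one in the canonical
#'   two-population train).
#' @return A list with `trace`, `sorter` (events/decisions/pulses),
#'   `outcomes` and `tally`.
#' @export
run_sort_experiment <- function(train, acq = acquisition_config(),
                                params = detector_params(),
                                gate = gate_config(),
                                pulse = pulse_config(),
                                junction = junction_params(),
                                positive_labels = NULL) {
  if (is.null(positive_labels)) {
    positive_labels <- train$populations[[length(train$populations)]]$label
  }
  vol <- train$populations[[1]]$volume_pl
  trace <- simulate_trace(train, acq)
  sorter <- run_sorter(trace, params, gate, pulse)
  outcomes <- resolve_sort_outcomes(trace, sorter, positive_labels,
                                    frequency_hz = train$frequency_hz,
                                    volume_pl = vol, junction = junction,
                                    pulse = pulse)
  list(trace = trace, sorter = sorter, outcomes = outcomes,
       tally = tally_outcomes(outcomes))
}

#' Plate-assay classifier statistics
#'
#' Control statistics of the secondary (microplate, 340 nm endpoint) assay
#' used to classify recovered clones: mean and standard deviation of the
#' positive and negative control measurements.
#'
#' @param pos_mean,pos_sd Mean and SD of the positive control, AU.
#' @param neg_mean,neg_sd Mean and SD of the negative control, AU.
#' @return An object of class `classifier_stats`.
#' @export
classifier_stats <- function(pos_mean = 1.0, pos_sd = 0.08,
                             neg_mean = 0.15, neg_sd = 0.05) {
  if (pos_sd < 0 || neg_sd < 0) .stop_config("standard deviations must be nonnegative")
  structure(list(pos_mean = pos_mean, pos_sd = pos_sd,
                 neg_mean = neg_mean, neg_sd = neg_sd),
            class = "classifier_stats")
}

#' Two-standard-deviation clone classification
#'
#' A clone is confidently positive if its assay value lies within two
#' standard deviations of the positive-control mean (i.e. at or above
#' `pos_mean - 2 pos_sd`), confidently negative if at or below
#' `neg_mean + 2 neg_sd`, and ambiguous otherwise. If the two bands overlap,
#' positive takes precedence and a warning is emitted.
#'
#' @param value Assay value(s), AU (vectorised).
#' @param stats A [classifier_stats()].
#' @return Character vector: `"positive"`, `"negative"` or `"ambiguous"`.
#' @export
classify_clone <- function(value, stats = classifier_stats()) {
  stopifnot(inherits(stats, "classifier_stats"))
  pos_lo <- stats$pos_mean - 2 * stats$pos_sd
  neg_hi <- stats$neg_mean + 2 * stats$neg_sd
  if (neg_hi >= pos_lo) {
    warning("positive and negative two-SD bands overlap; positive takes precedence")
  }
  ifelse(value >= pos_lo, "positive",
         ifelse(value <= neg_hi, "negative", "ambiguous"))
}

#' True positive rate, percent
#'
#' @param n_pos Number of clones classified positive.
#' @param n_total Total clones tested.
#' @return `100 n_pos / n_total`, rounded to the nearest integer percent
#'   (34 of 38 gives 89).
#' @examples
#' true_positive_rate(34, 38) # 89
#' @export
true_positive_rate <- function(n_pos, n_total) {
  if (n_total <= 0) .stop_data("n_total must be positive")
  if (n_pos < 0 || n_pos > n_total) .stop_data("need 0 <= n_pos <= n_total")
  round(100 * n_pos / n_total)
}

#' Pre/post-sort library composition
#'
#' @param pos_before,neg_before Positive/negative counts before sorting.
#' @param pos_after,neg_after Positive/negative counts after sorting.
#' @return An object of class `enrichment_counts`.
#' @export
enrichment_counts <- function(pos_before, neg_before, pos_after, neg_after) {
  v <- c(pos_before, neg_before, pos_after, neg_after)
  if (any(v < 0)) .stop_data("counts must be nonnegative")
  structure(list(pos_before = pos_before, neg_before = neg_before,
                 pos_after = pos_after, neg_after = neg_after),
            class = "enrichment_counts")
}

#' Enrichment factor, fraction-ratio convention
#'
#' The ratio of the positive *fraction* after sorting to the positive
#' fraction before:
#' \deqn{E = \frac{p_a/(p_a+n_a)}{p_b/(p_b+n_b)}.}
#'
#' @param counts An [enrichment_counts()].
#' @return Enrichment fold.
#' @examples
#' enrichment_zinchenko(enrichment_counts(1, 100, 34, 4)) # ~90.4
#' @export
enrichment_zinchenko <- function(counts) {
  stopifnot(inherits(counts, "enrichment_counts"))
  if (counts$pos_before <= 0) .stop_data("pos_before must be positive")
  if (counts$pos_after + counts$neg_after <= 0) {
    .stop_data("no droplets after sorting")
  }
  frac_after <- counts$pos_after / (counts$pos_after + counts$neg_after)
  frac_before <- counts$pos_before / (counts$pos_before + counts$neg_before)
  frac_after / frac_before
}

#' Enrichment factor, odds-ratio convention
#'
#' The ratio of positive:negative *odds* after sorting to the odds before:
#' \deqn{E = \frac{p_a/n_a}{p_b/n_b}.}
#' When no negatives survive sorting the odds are unbounded; `Inf` is
#' returned as the unbounded-enrichment sentinel, with a warning.
#'
#' @param counts An [enrichment_counts()].
#' @return Enrichment fold (possibly `Inf`).
#' @examples
#' enrichment_baret(enrichment_counts(1, 100, 34, 4)) # 850
#' @export
enrichment_baret <- function(counts) {
  stopifnot(inherits(counts, "enrichment_counts"))
  if (counts$pos_before <= 0) .stop_data("pos_before must be positive")
  if (counts$neg_before <= 0) .stop_data("neg_before must be positive")
  if (counts$neg_after == 0) {
    warning("no negatives after sorting: unbounded enrichment (Inf)")
    return(Inf)
  }
  (counts$pos_after / counts$neg_after) /
    (counts$pos_before / counts$neg_before)
}

#' End-to-end mock-library screening simulation
#'
#' Desk-scale emulation of a droplet enrichment screen: a mock library of
#' positive and negative clones (default 1:100) is encapsulated with Poisson
#' occupancy, the droplet train is synthesised and sorted at the configured
#' frequency, per-droplet junction outcomes are resolved, the positive-outlet
#' pool is scored, and a sample of recovered clones is re-assayed in a
#' simulated secondary plate assay and classified by the two-SD rule.
#'
#' A droplet is truly positive if it received at least one positive cell
#' (Poisson thinning: `P = 1 - exp(-lambda * p)` with `p` the positive cell
#' fraction), empty with probability `exp(-lambda)`.
#'
#' @param ratio Positive:negative cell ratio of the mock library (0.01 =
#'   1:100).
#' @param n_droplets Number of droplets screened (desk-scale stand-in for
#'   the instrument-scale hundreds of thousands).
#' @param occupancy_lambda Mean cells per droplet.
#' @param frequency_hz Sorting frequency, Hz.
#' @param volume_pl Droplet volume, pL.
#' @param assay A [classifier_stats()] describing the secondary plate assay.
#' @param n_clones Number of recovered clones tested in the plate assay.
#' @param acq,params,gate,pulse,junction Component configurations.
#' @param conc_mm Chromophore concentrations (mM) of negative and positive
#'   droplets in the primary droplet assay.
#' @param seed Integer seed; every random stage derives a substream from it.
#' @return An object of class `aads_screen`: counts, rates, enrichment
#'   folds, outcome tally and the per-droplet outcome table.
#' @export
run_mock_screen <- function(ratio = 0.01, n_droplets = 10000,
                            occupancy_lambda = 0.3, frequency_hz = 1000,
                            volume_pl = 75, assay = classifier_stats(),
                            n_clones = 38, acq = acquisition_config(),
                            params = detector_params(), gate = gate_config(),
                            pulse = pulse_config(),
                            junction = junction_params(),
                            conc_mm = c(0.5, 5), seed = 1) {
  if (n_droplets < 1000) .stop_config("n_droplets must be >= 1000")
  p_cell_pos <- ratio / (1 + ratio)
  p_empty <- exp(-occupancy_lambda)
  p_pos <- 1 - exp(-occupancy_lambda * p_cell_pos)   # >=1 positive cell
  p_neg <- 1 - p_empty - p_pos
  pops <- tartrazine_populations(
    conc_mm = conc_mm, volume_pl = volume_pl,
    proportions = c(p_neg, p_pos) / (p_neg + p_pos),
    labels = c("negative_clone", "positive_clone"))
  train <- train_config(duration_s = n_droplets / frequency_hz,
                        frequency_hz = frequency_hz, populations = pops,
                        empty_fraction = p_empty,
                        seed = substream_seed(seed, 1L))
  junction$seed <- junction$seed %||% substream_seed(seed, 2L)
  exp_out <- run_sort_experiment(train, acq, params, gate, pulse, junction,
                                 positive_labels = "positive_clone")
  outcomes <- exp_out$outcomes

  occupied <- outcomes$label != "empty"
  pos_before <- sum(outcomes$label == "positive_clone")
  neg_before <- sum(outcomes$label == "negative_clone")
  in_pool <- (outcomes$outlet == "positive" | outcomes$fragmented) & occupied
  pos_after <- sum(in_pool & outcomes$true_label == "positive")
  neg_after <- sum(in_pool & outcomes$true_label == "negative")
  counts <- enrichment_counts(pos_before, neg_before, pos_after, neg_after)

  pool_labels <- outcomes$true_label[in_pool]
  clone_res <- with_local_seed(substream_seed(seed, 3L), {
    if (length(pool_labels) == 0L) {
      list(values = numeric(), labels = character())
    } else {
      lab <- sample(pool_labels, n_clones, replace = length(pool_labels) < n_clones)
      val <- ifelse(lab == "positive",
                    rnorm(n_clones, assay$pos_mean, assay$pos_sd),
                    rnorm(n_clones, assay$neg_mean, assay$neg_sd))
      list(values = val, labels = lab)
    }
  })
  cls <- if (length(clone_res$values)) classify_clone(clone_res$values, assay)
         else character()
  tp <- if (length(cls)) true_positive_rate(sum(cls == "positive"), length(cls))
        else NA_real_

  structure(list(
    counts = counts,
    tp_rate = tp,
    enrichment_zinchenko = enrichment_zinchenko(counts),
    enrichment_baret = if (neg_after == 0) Inf else enrichment_baret(counts),
    tally = exp_out$tally,
    outcomes = outcomes,
    clones = data.frame(value = clone_res$values,
                        true_label = clone_res$labels,
                        classified = cls, stringsAsFactors = FALSE),
    settings = list(ratio = ratio, n_droplets = n_droplets,
                    occupancy_lambda = occupancy_lambda,
                    frequency_hz = frequency_hz, seed = seed)),
    class = "aads_screen")
}

#' @export
print.aads_screen <- function(x, ...) {
  s <- x$settings
  cat(sprintf("mock droplet screen: %d droplets @ %g Hz, ratio %.4g, lambda %.2f (seed %s)\n",
              s$n_droplets, s$frequency_hz, s$ratio, s$occupancy_lambda,
              format(s$seed)))
  cat(sprintf("  library: %d positive / %d negative clones in droplets\n",
              x$counts$pos_before, x$counts$neg_before))
  cat(sprintf("  positive outlet: %d positive / %d negative\n",
              x$counts$pos_after, x$counts$neg_after))
  cat(sprintf("  true positive rate (plate assay, %d clones): %s%%\n",
              nrow(x$clones), format(x$tp_rate)))
  cat(sprintf("  enrichment: %.3g-fold (fraction ratio), %s-fold (odds ratio)\n",
              x$enrichment_zinchenko,
              if (is.infinite(x$enrichment_baret)) "unbounded"
              else format(signif(x$enrichment_baret, 3))))
  cat("  outcome fractions:\n")
  for (nm in names(x$tally)) {
    cat(sprintf("    %-24s %.4f\n", nm, x$tally[[nm]]))
  }
  invisible(x)
}

#' Flatten a screen result to a key-value report table
#'
#' @param screen An `aads_screen` from [run_mock_screen()].
#' @return A data frame with columns `key` and `value` (machine-readable
#'   flat summary: counts, rates, folds, outcome fractions).
#' @export
screen_report <- function(screen) {
  stopifnot(inherits(screen, "aads_screen"))
  kv <- c(pos_before = screen$counts$pos_before,
          neg_before = screen$counts$neg_before,
          pos_after = screen$counts$pos_after,
          neg_after = screen$counts$neg_after,
          tp_rate_percent = screen$tp_rate,
          enrichment_zinchenko = screen$enrichment_zinchenko,
          enrichment_baret = screen$enrichment_baret,
          screen$tally)
  data.frame(key = names(kv), value = unname(kv), stringsAsFactors = FALSE)
}
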