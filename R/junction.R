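#' Sorting-junction model parameters
#'
#' Stochastic model of what happens to a droplet at the sorting junction.
#' The dielectrophoretic force required to pull a droplet into the positive
#' outlet grows with droplet volume and with droplet frequency as a power
#' law, \eqn{F_{req} = \alpha V^\beta f^\gamma}. A pulsed droplet whose
#' applied force comfortably exceeds the requirement (by the safety margin
#' `margin`) is sorted intact; in the marginal zone it still crosses but may
#' fragment against the gapped divider; below the requirement it stays in
#' the negative outlet, fragmenting with a probability that rises smoothly
#' with the force deficit.
#'
#' Defaults are calibrated so that a 75 pL droplet at 1000 Hz is sorted
#' intact with certainty (`F_req = 1 <= F_app / (1 + margin)`), a crossing at
#' 1500 Hz is marginal (possible fragmentation at the divider) and a crossing
#' at 2000 Hz fails outright, reproducing the observed degradation of
#' sorting efficiency with frequency.
#'
#' @param force_scale Force prefactor `alpha` (arbitrary force units); the
#'   default `1/75000` normalises `F_req(75 pL, 1000 Hz)` to 1.
#' @param volume_exponent Power-law exponent `beta` for droplet volume.
#' @param frequency_exponent Power-law exponent `gamma` for droplet
#'   frequency.
#' @param applied_force Dielectrophoretic force delivered by the electrode
#'   pulse, same units as `force_scale`.
#' @param margin Safety margin `m`: applied force at least `(1+m) F_req`
#'   guarantees an intact crossing.
#' @param fragmentation_sharpness Slope of the fragmentation probability in
#'   the relative force deficit.
#' @param seed Optional seed for reproducible outcome draws.
#' @return An object of class `junction_params`.
#' @export
junction_params <- function(force_scale = 1 / 75000, volume_exponent = 1,
                            frequency_exponent = 1, applied_force = 1.6,
                            margin = 0.2, fragmentation_sharpness = 10,
                            seed = NULL) {
  if (force_scale <= 0 || applied_force <= 0 || margin <= 0 ||
      fragmentation_sharpness <= 0) {
    .stop_config("force_scale, applied_force, margin and fragmentation_sharpness must be positive")
  }
  if (volume_exponent < 0 || frequency_exponent < 0) {
    .stop_config("exponents must be nonnegative")
  }
  structure(list(force_scale = force_scale, volume_exponent = volume_exponent,
                 frequency_exponent = frequency_exponent,
                 applied_force = applied_force, margin = margin,
                 fragmentation_sharpness = fragmentation_sharpness,
                 seed = seed),
            class = "junction_params")
}

#' Force required to deflect a droplet into the positive outlet
#'
#' \eqn{F_{req} = \alpha V^\beta f^\gamma}: strictly increasing in both
#' droplet volume and droplet frequency (larger droplets need more force;
#' faster trains leave less time to act on each droplet).
#'
#' @param volume_pl Droplet volume, pL (vectorised).
#' @param frequency_hz Droplet frequency, Hz (vectorised).
#' @param params A [junction_params()].
#' @return Required force, arbitrary units.
#' @export
required_force <- function(volume_pl, frequency_hz, params = junction_params()) {
  stopifnot(inherits(params, "junction_params"))
  if (any(volume_pl <= 0) || any(frequency_hz <= 0)) {
    .stop_config("volume and frequency must be positive")
  }
  params$force_scale * volume_pl^params$volume_exponent *
    frequency_hz^params$frequency_exponent
}

# fragmentation probability for a relative excess deficit x >= 0:
# smooth, 0 at x = 0, saturating at 1
.frag_prob <- function(x, sharpness) {
  ifelse(x <= 0, 0, tanh(sharpness * x / 2))
}

#' Resolve the physical outcome of one or more droplets at the junction
#'
#' Unpulsed droplets follow the bias-oil barrier into the negative outlet,
#' intact. A pulsed droplet crosses to the positive outlet iff the applied
#' force reaches the required force; fragmentation probability rises smoothly
#' (a logistic-family ramp in the relative force deficit below the
#' `(1+margin)` comfort level), so marginal crossings may split against the
#' divider (partial outcomes) and failed crossings may split on collision.
#'
#' Categories: `correct_positive`/`correct_negative` (right outlet, intact),
#' `false_positive`/`false_negative` (wrong outlet, intact),
#' `partial_false_positive`/`partial_false_negative` (fragmented, with a
#' fragment in the wrong outlet). A fragmented droplet is never "correct".
#'
#' @param true_label Character vector, `"positive"` or `"negative"` per
#'   droplet.
#' @param pulsed Logical vector: did this droplet receive an electrode
#'   pulse?
#' @param volume_pl Droplet volume(s), pL.
#' @param frequency_hz Droplet frequency, Hz.
#' @param params A [junction_params()]; `params$seed`, if set, makes the
#'   draws reproducible.
#' @return A data frame with columns `true_label`, `pulsed`, `outlet`
#'   (`"positive"`/`"negative"`, main body), `fragmented` and `category`.
#' @export
resolve_outcome <- function(true_label, pulsed, volume_pl = 75,
                            frequency_hz = 1000,
                            params = junction_params()) {
  stopifnot(inherits(params, "junction_params"))
  true_label <- as.character(true_label)
  if (!all(true_label %in% c("positive", "negative"))) {
    .stop_config("true_label must be 'positive' or 'negative'")
  }
  n <- length(true_label)
  pulsed <- rep_len(as.logical(pulsed), n)
  f_req <- rep_len(required_force(volume_pl, frequency_hz, params), n)
  with_local_seed(params$seed, {
    outlet <- rep("negative", n)
    fragmented <- rep(FALSE, n)
    crosses <- pulsed & params$applied_force >= f_req
    outlet[crosses] <- "positive"
    # relative deficit below the comfortable (1+m)*F_req level
    x <- ((1 + params$margin) * f_req - params$applied_force) / f_req
    p_frag <- .frag_prob(x, params$fragmentation_sharpness)
    p_frag[!pulsed] <- 0
    fragmented <- runif(n) < p_frag
    category <- ifelse(
      fragmented,
      ifelse(true_label == "positive", "partial_false_negative",
             "partial_false_positive"),
      ifelse(outlet == "positive",
             ifelse(true_label == "positive", "correct_positive",
                    "false_positive"),
             ifelse(true_label == "negative", "correct_negative",
                    "false_negative")))
    data.frame(true_label = true_label, pulsed = pulsed, outlet = outlet,
               fragmented = fragmented, category = category,
               stringsAsFactors = FALSE)
  })
}

#' Sorting-efficiency sweep over droplet frequencies
#'
#' Monte-Carlo sweep of junction outcomes under gate-perfect decisions
#' (every positive droplet pulsed, every negative droplet not): at each
#' frequency, `n_events` droplets are drawn, resolved at the junction and
#' tallied. With the default calibration the correct fraction is 1 at
#' 1 kHz and decays monotonically with frequency as fragmentation and failed
#' crossings set in.
#'
#' @param frequencies_hz Droplet frequencies to probe, Hz.
#' @param n_events Droplets per frequency point (>= 100).
#' @param positive_fraction Fraction of positive droplets.
#' @param volume_pl Droplet volume, pL.
#' @param params A [junction_params()].
#' @param seed Optional seed (overrides `params$seed`).
#' @return A data frame with one row per frequency: the six category
#'   fractions (summing to 1) and `correct` (correct_positive +
#'   correct_negative).
#' @export
sweep_efficiency <- function(frequencies_hz = c(1000, 1500, 2000),
                             n_events = 1000, positive_fraction = 0.5,
                             volume_pl = 75, params = junction_params(),
                             seed = NULL) {
  if (n_events < 100) .stop_config("n_events must be >= 100")
  seed <- seed %||% params$seed
  cats <- c("correct_positive", "correct_negative", "false_positive",
            "false_negative", "partial_false_positive",
            "partial_false_negative")
  with_local_seed(seed, {
    rows <- lapply(frequencies_hz, function(f) {
      labels <- ifelse(runif(n_events) < positive_fraction, "positive",
                       "negative")
      p <- params
      p$seed <- NULL  # draws come from the surrounding stream
      out <- resolve_outcome(labels, pulsed = labels == "positive",
                             volume_pl = volume_pl, frequency_hz = f,
                             params = p)
      fr <- vapply(cats, function(cc) mean(out$category == cc), 0)
      c(frequency_hz = f, fr,
        correct = unname(fr["correct_positive"] + fr["correct_negative"]))
    })
    as.data.frame(do.call(rbind, rows))
  })
}
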