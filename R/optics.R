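#' Carrier oil mixture
#'
#' Describes a fluorinated carrier oil blended with a high-refractive-index
#' additive used to match the refractive index of the aqueous droplet phase
#' and so suppress edge-refraction shoulders in the photodetector trace.
#' Defaults correspond to HFE-7500 (\eqn{n_D = 1.29}) blended with
#' 1,3-bis(trifluoromethyl)-5-bromobenzene (\eqn{n_D = 1.427}).
#'
#' @param phi Additive volume fraction, in `[0, 1]`.
#' @param n_base Refractive index of the base oil.
#' @param n_additive Refractive index of the additive.
#' @return An object of class `oil_mixture`.
#' @examples
#' oil_mixture(0.35)
#' @export
oil_mixture <- function(phi, n_base = 1.29, n_additive = 1.427) {
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (phi < 0 || phi > 1) {
    .stop_config("oil additive fraction phi must lie in [0, 1], got ", phi)
  }
  structure(list(n_base = n_base, n_additive = n_additive, phi = phi),
            class = "oil_mixture")
}

#' @export
print.oil_mixture <- function(x, ...) {
  cat(sprintf("oil mixture: phi = %.4g (n_base = %.4g, n_additive = %.4g, n = %.5g)\n",
              x$phi, x$n_base, x$n_additive, mixture_refractive_index(x)))
  invisible(x)
}

#' Refractive index of an oil/additive mixture
#'
#' Linear volumetric (Arago-Biot) mixing rule:
#' \eqn{n = (1-\phi) n_{base} + \phi n_{additive}}. The rule is the simplest
#' one consistent with the monotone dependence of the trace on additive
#' content; it is exact at both endpoints and strictly monotone in `phi`.
#'
#' @param mix An [oil_mixture()].
#' @return The mixture refractive index (dimensionless).
#' @examples
#' mixture_refractive_index(oil_mixture(0))     # 1.29, base oil
#' mixture_refractive_index(oil_mixture(0.35))  # 1.33795
#' @export
mixture_refractive_index <- function(mix) {
  stopifnot(inherits(mix, "oil_mixture"))
  (1 - mix$phi) * mix$n_base + mix$phi * mix$n_additive
}

#' Additive fraction required to reach a target refractive index
#'
#' Inverts the linear mixing rule of [mixture_refractive_index()]: returns the
#' additive volume fraction whose mixture index equals `n_target`. Matching
#' the aqueous phase (pure water, \eqn{n_D = 1.333}) with the default oils
#' requires a fraction of about 0.314, inside the 30--35\% additive window
#' found to remove edge shoulders in practice.
#'
#' @param n_target Target refractive index; must lie between `n_base` and
#'   `n_additive`.
#' @inheritParams oil_mixture
#' @return The additive volume fraction in `[0, 1]`.
#' @examples
#' match_fraction(1.333) # ~0.3139, matches water
#' @export
match_fraction <- function(n_target, n_base = 1.29, n_additive = 1.427) {
  stopifnot(is.numeric(n_target), length(n_target) == 1L)
  lo <- min(n_base, n_additive); hi <- max(n_base, n_additive)
  if (n_target < lo || n_target > hi) {
    .stop_config("target index ", n_target, " is outside the attainable range [",
                 lo, ", ", hi, "]")
  }
  (n_target - n_base) / (n_additive - n_base)
}

#' Diameter of a spherical droplet
#'
#' Converts a droplet volume in picolitres to the diameter of the equivalent
#' sphere in micrometres, \eqn{d = (6V/\pi)^{1/3}}.
#'
#' @param volume_pl Droplet volume in picolitres (vectorised).
#' @return Diameter in micrometres.
#' @examples
#' droplet_diameter(75)   # ~52.3 um
#' droplet_diameter(180)  # ~70.0 um
#' @export
droplet_diameter <- function(volume_pl) {
  stopifnot(is.numeric(volume_pl))
  if (any(volume_pl < 0)) .stop_config("droplet volume must be nonnegative")
  # 1 pL = 1e3 um^3
  (6 * volume_pl * 1e3 / pi)^(1 / 3)
}

#' Effective optical path length of a droplet
#'
#' The optical path through a droplet is its spherical diameter, capped at the
#' channel depth: droplets comparable to the channel depth travel as plugs and
#' cannot present a path longer than the channel is deep.
#'
#' @inheritParams droplet_diameter
#' @param channel_depth_um Channel depth at the detection point, micrometres.
#' @return Effective path length in micrometres.
#' @export
effective_path_length <- function(volume_pl, channel_depth_um = 100) {
  pmin(droplet_diameter(volume_pl), channel_depth_um)
}

#' Beer-Lambert absorbance
#'
#' \eqn{A = \epsilon c l}, with the path length supplied in micrometres and
#' converted to centimetres internally (the only place such a conversion
#' occurs).
#'
#' @param conc_m Chromophore concentration in mol/L (vectorised).
#' @param epsilon Molar extinction coefficient, L mol^-1 cm^-1.
#' @param path_um Optical path length in micrometres.
#' @return Absorbance (dimensionless AU).
#' @examples
#' absorbance(5e-3, 38000, effective_path_length(75)) # ~1 AU
#' @export
absorbance <- function(conc_m, epsilon, path_um) {
  stopifnot(is.numeric(conc_m), is.numeric(epsilon), is.numeric(path_um))
  if (any(conc_m < 0) || any(epsilon < 0) || any(path_um < 0)) {
    .stop_config("absorbance inputs must be nonnegative")
  }
  epsilon * conc_m * (path_um / 1e4)
}

#' Photodetector acquisition settings
#'
#' @param sample_rate Sampling rate of the voltage acquisition, Hz.
#' @param v0 Baseline (oil-only) photodetector voltage, V.
#' @param v_sat Saturation ceiling of the photodetector, V; samples are
#'   clipped here, never above.
#' @param noise_sd Standard deviation of the additive Gaussian voltage
#'   noise, V.
#' @param channel_depth_um Detection channel depth, micrometres.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate = 1e5, v0 = 1.0, v_sat = 1.25,
                               noise_sd = 0.005, channel_depth_um = 100) {
  if (sample_rate <= 0) .stop_config("sample_rate must be positive")
  if (v0 <= 0 || v0 > v_sat) .stop_config("need 0 < v0 <= v_sat")
  if (noise_sd < 0) .stop_config("noise_sd must be nonnegative")
  structure(list(sample_rate = sample_rate, v0 = v0, v_sat = v_sat,
                 noise_sd = noise_sd, channel_depth_um = channel_depth_um),
            class = "acquisition_config")
}

#' Transmitted voltage for a given absorbance
#'
#' Log-linear transduction \eqn{V = \min(V_0 10^{-A}, V_{sat})}: the
#' photodetector voltage is proportional to transmitted light, so absorbance
#' and voltage space are exactly interconvertible below saturation (see
#' [peak_absorbance()] for the inverse). Saturation is clipping, not an error.
#'
#' @param a Absorbance (vectorised), nonnegative.
#' @param acq An [acquisition_config()].
#' @return Voltage in volts.
#' @export
transmitted_voltage <- function(a, acq = acquisition_config()) {
  stopifnot(is.numeric(a), inherits(acq, "acquisition_config"))
  if (any(a < 0)) .stop_config("absorbance must be nonnegative")
  pmin(acq$v0 * 10^(-a), acq$v_sat)
}

#' Concentration fold-change from droplet miniaturisation
#'
#' A fixed number of product molecules confined in a smaller droplet gives a
#' proportionally higher concentration: the fold-change is the volume ratio.
#' Shrinking from 180 pL to 75 pL concentrates the product 2.4-fold.
#'
#' @param v_small_pl Smaller droplet volume, pL.
#' @param v_large_pl Larger droplet volume, pL.
#' @return The concentration fold-change (large/small volume ratio).
#' @examples
#' fold_concentration(75, 180) # 2.4
#' @export
fold_concentration <- function(v_small_pl, v_large_pl) {
  if (any(v_small_pl <= 0) || any(v_large_pl <= 0)) {
    .stop_config("droplet volumes must be positive")
  }
  v_large_pl / v_small_pl
}

#' Number of chromophore molecules in a droplet
#'
#' @param conc_m Concentration, mol/L.
#' @param volume_pl Droplet volume, pL.
#' @return Molecule count \eqn{c V N_A}.
#' @examples
#' molecules_per_droplet(2e-9, 2)      # ~2.4e3
#' molecules_per_droplet(7.5e-6, 180)  # ~8.1e8
#' @export
molecules_per_droplet <- function(conc_m, volume_pl) {
  if (any(conc_m < 0)) .stop_config("concentration must be nonnegative")
  if (any(volume_pl <= 0)) .stop_config("droplet volume must be positive")
  conc_m * volume_pl * 1e-12 * .N_AVOGADRO
}

#' Droplet population
#'
#' One component of a droplet train: a chromophore concentration, extinction
#' coefficient at the detection wavelength (455 nm for tartrazine / reduced
#' WST-1), droplet volume and mixture proportion. The default extinction
#' coefficient (38000 L mol^-1 cm^-1) is chosen so that 5 mM chromophore in a
#' 75 pL droplet reads close to 1 AU.
#'
#' @param concentration_m Chromophore concentration, mol/L.
#' @param volume_pl Droplet volume, pL.
#' @param label Class tag (e.g. `"low"`, `"high"`, `"empty"`).
#' @param proportion Fraction of this population in the train, `[0, 1]`.
#' @param epsilon Extinction coefficient, L mol^-1 cm^-1.
#' @return An object of class `droplet_population`.
#' @export
droplet_population <- function(concentration_m, volume_pl, label,
                               proportion = 1, epsilon = 38000) {
  if (concentration_m < 0) .stop_config("concentration must be nonnegative")
  if (epsilon <= 0) .stop_config("epsilon must be positive")
  if (volume_pl <= 0) .stop_config("volume must be positive")
  if (proportion < 0 || proportion > 1) .stop_config("proportion must lie in [0, 1]")
  structure(list(concentration_m = concentration_m, epsilon = epsilon,
                 volume_pl = volume_pl, label = as.character(label),
                 proportion = proportion),
            class = "droplet_population")
}

#' Canonical two-population tartrazine mixture
#'
#' Convenience builder for the standard validation pair: 0.5 mM and 5 mM
#' tartrazine-analogue droplets at equal proportions.
#'
#' @param conc_mm Concentrations in mM, one per population.
#' @param volume_pl Common droplet volume, pL.
#' @param proportions Mixture proportions, summing to 1.
#' @param epsilon Extinction coefficient, L mol^-1 cm^-1.
#' @param labels Population labels.
#' @return A list of [droplet_population()] objects.
#' @export
tartrazine_populations <- function(conc_mm = c(0.5, 5), volume_pl = 75,
                                   proportions = rep(1 / length(conc_mm), length(conc_mm)),
                                   epsilon = 38000,
                                   labels = paste0("tartrazine_", conc_mm, "mM")) {
  stopifnot(length(conc_mm) == length(proportions))
  mapply(function(c_mm, p, lab) {
    droplet_population(c_mm * 1e-3, volume_pl, lab, p, epsilon)
  }, conc_mm, proportions, labels, SIMPLIFY = FALSE)
}
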