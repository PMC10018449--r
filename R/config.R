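# Run configuration: one nested YAML document mirroring the component
# constructors. Every section is validated field-by-field at load time and
# unknown keys are rejected, so a typo fails loudly instead of silently
# falling back to a default.

.check_known <- function(section, given, allowed) {
  extra <- setdiff(names(given), allowed)
  if (length(extra)) {
    .stop_config("unknown key", if (length(extra) > 1) "s" else "", " in '",
                 section, "': ", paste0(section, ".", extra, collapse = ", "))
  }
}

.build_section <- function(cfg, section, constructor, allowed) {
  given <- cfg[[section]] %||% list()
  .check_known(section, given, allowed)
  tryCatch(do.call(constructor, given),
           aads_config_error = function(e) {
             .stop_config("in section '", section, "': ", conditionMessage(e))
           })
}

#' Default run configuration
#'
#' The full nested configuration consumed by [load_run_config()] and the
#' command line, populated with the package defaults: a 1 s, 1 kHz,
#' two-population (0.5/5 mM analogue) 75 pL train in 35%-additive oil.
#'
#' @param seed Global seed recorded in the configuration.
#' @return A nested list; serialise with [yaml::write_yaml()].
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    out_dir = ".",
    acquisition = list(sample_rate = 1e5, v0 = 1.0, v_sat = 1.25,
                       noise_sd = 0.005, channel_depth_um = 100),
    oil = list(phi = 0.35, n_base = 1.29, n_additive = 1.427),
    train = list(duration_s = 1, frequency_hz = 1000, n_aqueous = 1.337,
                 transit_fraction = 0.4, shoulder_gain = 300,
                 empty_fraction = 0, empty_dip = 0.02, jitter_sd = 0),
    populations = list(
      list(label = "tartrazine_0.5mM", concentration_mm = 0.5,
           volume_pl = 75, proportion = 0.5, epsilon = 38000),
      list(label = "tartrazine_5mM", concentration_mm = 5,
           volume_pl = 75, proportion = 0.5, epsilon = 38000)),
    detector = list(baseline_alpha = 0.01, enter_delta = 0.012,
                    shoulder_delta = 0.02, exit_band = 0.01,
                    min_width = 1e-4, max_width = 2e-3, debounce = 3,
                    smooth_n = 5, init_time = 0.01),
    gate = list(a_low = 0.5, a_high = 1.5, min_width = 1e-4,
                max_width = 2e-3, sort_empty = FALSE, mode = "absorbance"),
    pulse = list(delay = 5e-4, width = 1e-4, refractory = 5e-4),
    junction = list(force_scale = 1 / 75000, volume_exponent = 1,
                    frequency_exponent = 1, applied_force = 1.6,
                    margin = 0.2, fragmentation_sharpness = 10),
    screen = list(ratio = 0.01, n_droplets = 10000, occupancy_lambda = 0.3,
                  n_clones = 38,
                  assay = list(pos_mean = 1.0, pos_sd = 0.08,
                               neg_mean = 0.15, neg_sd = 0.05)))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (see [default_run_config()] for the schema),
#' rejects unknown keys, enforces every component invariant, and returns
#' ready-built component objects.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @param seed_override Optional seed overriding the configured one.
#' @return A list with the built components (`acq`, `oil`, `train`, `gate`,
#'   `detector`, `pulse`, `junction`, `screen`, `seed`, `out_dir`) and the
#'   raw configuration (`raw`).
#' @export
load_run_config <- function(path = NULL, seed_override = NULL) {
  cfg <- if (is.null(path)) {
    default_run_config()
  } else {
    if (!file.exists(path)) .stop_config("config file not found: ", path)
    tryCatch(yaml::read_yaml(path),
             error = function(e) .stop_config("cannot parse config '", path,
                                              "': ", conditionMessage(e)))
  }
  .check_known("<top level>", cfg,
               c("seed", "out_dir", "acquisition", "oil", "train",
                 "populations", "detector", "gate", "pulse", "junction",
                 "screen"))
  seed <- as.integer(seed_override %||% cfg$seed %||% 1L)

  acq <- .build_section(cfg, "acquisition", acquisition_config,
                        c("sample_rate", "v0", "v_sat", "noise_sd",
                          "channel_depth_um"))
  oil_given <- cfg$oil %||% list(phi = 0.35)
  .check_known("oil", oil_given, c("phi", "n_base", "n_additive"))
  oil <- tryCatch(do.call(oil_mixture, oil_given),
                  aads_config_error = function(e) {
                    .stop_config("in section 'oil.phi': ", conditionMessage(e))
                  })

  pops_given <- cfg$populations %||% default_run_config()$populations
  pops <- lapply(seq_along(pops_given), function(i) {
    p <- pops_given[[i]]
    .check_known(paste0("populations[", i, "]"), p,
                 c("label", "concentration_mm", "volume_pl", "proportion",
                   "epsilon"))
    droplet_population(concentration_m = (p$concentration_mm %||% 0) * 1e-3,
                       volume_pl = p$volume_pl %||% 75,
                       label = p$label %||% paste0("pop", i),
                       proportion = p$proportion %||% 1,
                       epsilon = p$epsilon %||% 38000)
  })

  train_given <- cfg$train %||% list()
  .check_known("train", train_given,
               c("duration_s", "frequency_hz", "n_aqueous",
                 "transit_fraction", "shoulder_gain", "empty_fraction",
                 "empty_dip", "jitter_sd"))
  train_args <- c(train_given,
                  list(populations = pops, oil = oil,
                       seed = substream_seed(seed, 1L)))
  if (is.null(train_args$duration_s)) train_args$duration_s <- 1
  train <- do.call(train_config, train_args)

  detector <- .build_section(cfg, "detector", detector_params,
                             c("baseline_alpha", "enter_delta",
                               "shoulder_delta", "exit_band", "min_width",
                               "max_width", "debounce", "smooth_n",
                               "init_time", "v_sat"))
  gate <- .build_section(cfg, "gate", gate_config,
                         c("a_low", "a_high", "min_width", "max_width",
                           "sort_empty", "mode"))
  pulse <- .build_section(cfg, "pulse", pulse_config,
                          c("delay", "width", "refractory"))
  junction_given <- cfg$junction %||% list()
  .check_known("junction", junction_given,
               c("force_scale", "volume_exponent", "frequency_exponent",
                 "applied_force", "margin", "fragmentation_sharpness"))
  junction <- do.call(junction_params,
                      c(junction_given, list(seed = substream_seed(seed, 2L))))

  screen_given <- cfg$screen %||% list()
  .check_known("screen", screen_given,
               c("ratio", "n_droplets", "occupancy_lambda", "n_clones",
                 "assay"))
  assay_given <- screen_given$assay %||% list()
  .check_known("screen.assay", assay_given,
               c("pos_mean", "pos_sd", "neg_mean", "neg_sd"))
  screen <- list(ratio = screen_given$ratio %||% 0.01,
                 n_droplets = screen_given$n_droplets %||% 10000,
                 occupancy_lambda = screen_given$occupancy_lambda %||% 0.3,
                 n_clones = screen_given$n_clones %||% 38,
                 assay = do.call(classifier_stats, assay_given))

  list(seed = seed, out_dir = cfg$out_dir %||% ".", acq = acq, oil = oil,
       train = train, detector = detector, gate = gate, pulse = pulse,
       junction = junction, screen = screen, raw = cfg)
}
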