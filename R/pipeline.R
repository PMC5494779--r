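#' Default pipeline configuration
#'
#' All tunable constants of the simulate -> features -> invert -> correlate
#' chain, as a nested list matching the YAML schema accepted by
#' [load_config()].
#'
#' @param seed Integer RNG seed.
#' @return A `pipeline_config` list with sections `transducer`,
#'   `acquisition`, `layers`, `calibration`, `analysis`, and `seed`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    transducer = list(center_frequency = 4.7e7, fractional_bandwidth = 0.62),
    acquisition = list(sampling_rate = 1e9, record_length = 2048L,
                       n_alines = 10L, n_repeats = 3L,
                       noise_sd = NA_real_, anterior_arrival = 0.5e-6),
    layers = list(cornea_thickness = 0.8e-3, cornea_speed = 1580),
    calibration = list(iop_low = 10, iop_high = 50,
                       Z1_low = 1.5399, Z1_high = 1.5519,
                       Z2_low = 1.5393, Z2_high = 1.5698,
                       ant_amp_low = 1.6347, ant_amp_high = 2.1454,
                       post_amp_low = 0.5778),
    analysis = list(iops = seq(10, 50, by = 10),
                    min_separation = 0.2e-6, window_frac = 0.7),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

validate_config <- function(cfg) {
  defaults <- unclass(default_config())
  bad_sections <- setdiff(names(cfg), names(defaults))
  if (length(bad_sections))
    stop("unknown config sections: ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  for (sec in setdiff(names(defaults), "seed")) {
    if (is.null(cfg[[sec]])) { cfg[[sec]] <- defaults[[sec]]; next }
    bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown keys in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    miss <- setdiff(names(defaults[[sec]]), names(cfg[[sec]]))
    cfg[[sec]][miss] <- defaults[[sec]][miss]
  }
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  if (!is.na(cfg$acquisition$noise_sd) && cfg$acquisition$noise_sd < 0)
    stop("noise_sd must be nonnegative", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$analysis$iops <- as.numeric(unlist(cfg$analysis$iops))
  structure(cfg, class = "pipeline_config")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills defaults for omitted keys, and rejects unknown
#' keys. A `seed` entry is mandatory.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  # yaml reads NA/.na as NA already; ensure noise_sd is numeric
  if (!is.null(raw$acquisition$noise_sd))
    raw$acquisition$noise_sd <- as.numeric(raw$acquisition$noise_sd)
  validate_config(raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_objects <- function(cfg) {
  tspec <- transducer_spec(cfg$transducer$center_frequency,
                           cfg$transducer$fractional_bandwidth)
  aspec <- acquisition_spec(sampling_rate = cfg$acquisition$sampling_rate,
                            record_length = cfg$acquisition$record_length,
                            n_alines = cfg$acquisition$n_alines,
                            n_repeats = cfg$acquisition$n_repeats,
                            noise_sd = cfg$acquisition$noise_sd,
                            anterior_arrival = cfg$acquisition$anterior_arrival,
                            seed = cfg$seed)
  cal <- iop_calibration(cfg$calibration$iop_low, cfg$calibration$iop_high,
                         cfg$calibration$Z1_low, cfg$calibration$Z1_high,
                         cfg$calibration$Z2_low, cfg$calibration$Z2_high)
  calib <- calibrate_endpoints(cfg$calibration$ant_amp_low,
                               cfg$calibration$ant_amp_high,
                               cfg$calibration$post_amp_low,
                               cal = cal,
                               cornea_thickness = cfg$layers$cornea_thickness,
                               cornea_speed = cfg$layers$cornea_speed)
  list(tspec = tspec, aspec = aspec, cal = cal, calib = calib)
}

#' Run the full simulate -> features -> invert -> correlate pipeline
#'
#' Simulates the pressure-series experiment defined by the configuration,
#' extracts echo features, inverts them to impedances, aggregates per IOP
#' level, and correlates the anterior/posterior amplitudes and impedances
#' with pressure. When `out_dir` is given, all intermediate tables and a
#' JSON summary are written there; every file is regenerable bit-for-bit
#' from the configuration and seed.
#'
#' @param cfg A `pipeline_config` (see [default_config()],
#'   [load_config()]).
#' @param out_dir Optional output directory.
#' @return A list with `features`, `impedances`, `per_iop_features`,
#'   `per_iop_impedances`, `correlations` (list of
#'   `correlation_result` for `Z1`, `Z2`, `ant_amp`, `post_amp`), `truth`,
#'   `calibration` (the solved constants), and `noise_sd`.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL) {
  cfg <- validate_config(unclass(cfg))
  obj <- config_objects(cfg)
  sim <- simulate_experiment(obj$calib, obj$tspec, obj$aspec,
                             iops = cfg$analysis$iops)
  features <- extract_features(sim, cfg$analysis$min_separation,
                               cfg$analysis$window_frac)
  setup <- reflection_setup(Z0 = obj$calib$Z0, Z3 = obj$calib$Z3,
                            A0 = obj$calib$A0,
                            posterior_gain = obj$calib$posterior_gain)
  impedances <- invert_feature_table(features, setup)
  per_feat <- aggregate_features(features)
  per_imp <- aggregate_impedances(impedances)
  correlations <- list(
    Z1 = correlate_with_iop(per_imp$iop_mmHg, per_imp$Z1_mean_MRayl, "Z1"),
    Z2 = correlate_with_iop(per_imp$iop_mmHg, per_imp$Z2_mean_MRayl, "Z2"),
    ant_amp = correlate_with_iop(per_feat$iop_mmHg, per_feat$ant_amp_mean,
                                 "ant_amp"),
    post_amp = correlate_with_iop(per_feat$iop_mmHg, per_feat$post_amp_mean,
                                  "post_amp"))
  result <- list(features = features, impedances = impedances,
                 per_iop_features = per_feat, per_iop_impedances = per_imp,
                 correlations = correlations, truth = sim$truth,
                 calibration = list(Z0 = obj$calib$Z0, Z3 = obj$calib$Z3,
                                    A0 = obj$calib$A0,
                                    posterior_gain = obj$calib$posterior_gain),
                 noise_sd = sim$noise_sd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    wt(features, "features.tsv")
    wt(impedances, "impedances.tsv")
    wt(per_feat, "per_iop_features.tsv")
    wt(per_imp, "per_iop_impedances.tsv")
    summary <- list(
      seed = cfg$seed,
      n_iop_levels = length(unique(features$iop_mmHg)),
      calibration = result$calibration,
      noise_sd = sim$noise_sd,
      correlations = lapply(correlations, function(cr)
        cr[c("quantity", "r", "n", "t_stat", "df", "p_two_sided",
             "slope", "intercept")]))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
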