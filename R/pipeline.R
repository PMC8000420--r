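#' Full pipeline run configuration
#'
#' Bundles every knob of the simulate -> sample -> analyze -> report
#' workflow. All concentrations are ug/mL, times hours, flows mL/min.
#'
#' @param arms Arms to run, subset of [arm_names()].
#' @param volume Reactor volume, mL.
#' @param duration Run duration, hours.
#' @param solver_step_min Integration step, minutes.
#' @param initial_cap Initial (capped) pump flow, mL/min.
#' @param trendline A [drainage_trendline()].
#' @param sampling_times Effluent sampling times, hours.
#' @param lod Assay detection limit, ug/mL.
#' @param noise_sigma Measurement noise SD on the log10 scale.
#' @param censor_to Censored-value convention, `"lod"` or `"zero"`.
#' @param n_replicates Replicates per arm.
#' @param windows AUC window ends, hours.
#' @param band A [threshold_band()].
#' @param seed Master seed; all stage randomness derives from it.
#' @param out_dir Output directory for [run_pipeline()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(arms = arm_names(), volume = 75, duration = 48,
                       solver_step_min = 0.1, initial_cap = 3.5,
                       trendline = drainage_trendline(),
                       sampling_times = default_sampling_times(),
                       lod = 0.98, noise_sigma = 0.15,
                       censor_to = c("lod", "zero"), n_replicates = 3,
                       windows = c(2, 12, 24, 48), band = threshold_band(),
                       seed = 1, out_dir = tempfile("kneeflow_run_")) {
  structure(list(arms = arms, volume = volume, duration = duration,
                 solver_step_min = solver_step_min,
                 initial_cap = initial_cap, trendline = trendline,
                 sampling_times = sampling_times, lod = lod,
                 noise_sigma = noise_sigma,
                 censor_to = match.arg(censor_to),
                 n_replicates = n_replicates, windows = windows,
                 band = band, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every invariant of the referenced sub-configurations and returns
#' the violations as data (an empty character vector means the configuration
#' is valid); nothing is thrown.
#'
#' @param config A [run_config()].
#' @return Character vector of violation messages, each naming the offending
#'   key.
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(msg) v <<- c(v, msg)
  if (!is.numeric(config$volume) || length(config$volume) != 1L ||
      !is.finite(config$volume) || config$volume <= 0) {
    say("volume: must be a positive number (mL)")
  }
  if (!is.numeric(config$duration) || config$duration <= 0) {
    say("duration: must be positive (hours)")
  }
  if (!is.numeric(config$solver_step_min) || config$solver_step_min <= 0) {
    say("solver_step_min: must be positive (minutes)")
  }
  if (!is.numeric(config$initial_cap) || config$initial_cap <= 0) {
    say("initial_cap: must be positive (mL/min)")
  }
  if (!inherits(config$trendline, "drainage_trendline")) {
    say("trendline: must be a drainage_trendline")
  }
  if (!length(config$arms) || !all(config$arms %in% arm_names())) {
    say(paste0("arms: must be a non-empty subset of {",
               paste(arm_names(), collapse = ", "), "}"))
  }
  if (!is.numeric(config$sampling_times) || !length(config$sampling_times) ||
      any(config$sampling_times <= 0) ||
      any(diff(config$sampling_times) <= 0)) {
    say("sampling_times: must be strictly increasing and positive")
  } else if (is.numeric(config$duration) && config$duration > 0 &&
             max(config$sampling_times) > config$duration) {
    say("sampling_times: last sampling time exceeds duration")
  }
  if (!is.numeric(config$lod) || config$lod <= 0) {
    say("lod: must be positive (ug/mL)")
  }
  if (!is.numeric(config$noise_sigma) || config$noise_sigma < 0) {
    say("noise_sigma: must be >= 0")
  }
  if (!is.numeric(config$n_replicates) || config$n_replicates < 1) {
    say("n_replicates: must be >= 1")
  }
  if (!is.numeric(config$windows) || !length(config$windows) ||
      any(config$windows <= 0)) {
    say("windows: must be positive window ends (hours)")
  } else if (is.numeric(config$duration) &&
             any(config$windows > config$duration)) {
    say("windows: AUC window exceeds duration")
  }
  if (!inherits(config$band, "threshold_band")) {
    say("band: must be a threshold_band")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      !is.finite(config$seed)) {
    say("seed: must be a single finite number")
  }
  v
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full simulation and analysis pipeline
#'
#' Orchestrates, for each configured arm: schedule construction, reactor
#' simulation, synthetic effluent sampling, exposure analysis, and predicted
#' zone-of-inhibition summaries, writing each product as CSV plus a JSON run
#' manifest (seed, package version, configuration echo). Outputs are
#' byte-identical across runs with the same configuration and seed. Stage
#' progress is logged to stderr.
#'
#' Files written to `config$out_dir`: `schedule.csv`,
#' `simulation_<arm>.csv`, `measured_dataset.csv`, `log_summary.csv`,
#' `auc.csv`, `threshold.csv`, `zoi.csv`, `manifest.json`, and — when both
#' spacer arms are configured — `log_difference.csv` and `tests.csv`.
#'
#' @param config A [run_config()]; must pass [validate_config()].
#' @return Invisibly, a list with the in-memory products (`schedule`, `sims`,
#'   `dataset`, `exposure`, `zoi`) and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- list()
  wpath <- function(f) file.path(out_dir, f)

  stage_log("schedule", "building stepwise schedule (cap %g mL/min, %g h)",
            config$initial_cap, config$duration)
  sched <- build_stepwise_schedule(config$trendline,
                                   boundaries = config$sampling_times,
                                   initial_cap = config$initial_cap,
                                   duration = config$duration)
  paths$schedule <- write_schedule_csv(sched, wpath("schedule.csv"))

  samp <- sampling_schedule(config$sampling_times)
  meas <- measurement_model(config$lod, config$noise_sigma,
                            config$censor_to)
  arm_seeds <- derive_seeds(config$seed, length(config$arms))

  sims <- list()
  datasets <- list()
  for (i in seq_along(config$arms)) {
    arm <- config$arms[i]
    stage_log("simulate", "arm %s", arm)
    cfg <- reactor_config(default_depots(arm), sched,
                          volume = config$volume,
                          duration = config$duration,
                          solver_step_min = config$solver_step_min,
                          arm = arm)
    sims[[arm]] <- simulate_reactor(cfg)
    paths[[paste0("simulation_", arm)]] <-
      write_simulation_csv(sims[[arm]], wpath(paste0("simulation_", arm,
                                                     ".csv")),
                           every_h = 1 / 60)
    stage_log("fixtures", "sampling arm %s (%d replicates)", arm,
              config$n_replicates)
    datasets[[arm]] <- sample_effluent(sims[[arm]]$series, samp, meas,
                                       config$n_replicates,
                                       seed = arm_seeds[i])
  }
  dataset <- do.call(rbind, datasets)
  rownames(dataset) <- NULL
  paths$dataset <- write_dataset_csv(dataset, wpath("measured_dataset.csv"))

  stage_log("analyze", "exposure summaries (windows: %s h)",
            paste(config$windows, collapse = ", "))
  expo <- exposure_summary(dataset, windows = config$windows,
                           band = config$band, lod = config$lod,
                           censor_to = config$censor_to)
  utils::write.csv(expo$log_summary, wpath("log_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(expo$auc, wpath("auc.csv"), row.names = FALSE)
  utils::write.csv(expo$threshold, wpath("threshold.csv"),
                   row.names = FALSE)
  paths$log_summary <- wpath("log_summary.csv")
  paths$auc <- wpath("auc.csv")
  paths$threshold <- wpath("threshold.csv")
  if (!is.null(expo$log_diff)) {
    utils::write.csv(expo$log_diff, wpath("log_difference.csv"),
                     row.names = FALSE)
    utils::write.csv(expo$tests, wpath("tests.csv"), row.names = FALSE)
    paths$log_diff <- wpath("log_difference.csv")
    paths$tests <- wpath("tests.csv")
  }

  stage_log("zoi", "predicting potency against reference organisms")
  zoi <- do.call(rbind, lapply(reference_organisms(), function(org) {
    potency_series(dataset, org)
  }))
  rownames(zoi) <- NULL
  paths$zoi <- write_zoi_csv(zoi, wpath("zoi.csv"))

  manifest <- list(
    package = "kneeflow",
    version = as.character(utils::packageVersion("kneeflow")),
    seed = config$seed,
    config = list(
      arms = config$arms, volume = config$volume,
      duration = config$duration,
      solver_step_min = config$solver_step_min,
      initial_cap = config$initial_cap,
      trendline = list(coefficient = config$trendline$coefficient,
                       exponent = config$trendline$exponent,
                       time_unit = config$trendline$time_unit),
      sampling_times = config$sampling_times, lod = config$lod,
      noise_sigma = config$noise_sigma, censor_to = config$censor_to,
      n_replicates = config$n_replicates, windows = config$windows,
      band = unclass(config$band)
    )
  )
  jsonlite::write_json(manifest, wpath("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$manifest <- wpath("manifest.json")
  stage_log("done", "outputs in %s", out_dir)
  invisible(list(schedule = sched, sims = sims, dataset = dataset,
                 exposure = expo, zoi = zoi, paths = paths))
}
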