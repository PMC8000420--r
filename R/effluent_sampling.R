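#' Effluent sampling schedule
#'
#' Times at which 2.5 mL effluent samples are drawn for assay.
#'
#' @param times Strictly increasing sampling times, hours. Default:
#'   [default_sampling_times()].
#' @param sample_volume_ml Withdrawn volume per sample, mL. Default 2.5.
#'   Carried for documentation; withdrawals are not modelled as volume loss.
#' @return An object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(times = default_sampling_times(),
                              sample_volume_ml = 2.5) {
  stopifnot(is.numeric(times), length(times) >= 1L,
            all(is.finite(times)), all(times > 0),
            is.numeric(sample_volume_ml), sample_volume_ml > 0)
  if (any(diff(times) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, sample_volume_ml = sample_volume_ml),
            class = "sampling_schedule")
}

#' Effluent measurement model
#'
#' The concentration assay: multiplicative lognormal noise on the log10 scale
#' and a lower limit of detection (LOD). Values below the LOD are censored
#' and, by default, recorded at the LOD — so that log10 of a censored value is
#' log10(0.98) = -0.01 (2 dp), the reporting convention for non-detects.
#' Zero-substitution is available as a sensitivity alternative.
#'
#' @param lod Limit of detection, ug/mL. Default 0.98.
#' @param noise_sigma Standard deviation of the measurement noise on the
#'   log10 scale (>= 0). Default 0.15.
#' @param censor_to How censored values are recorded: `"lod"` (default) or
#'   `"zero"`.
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(lod = 0.98, noise_sigma = 0.15,
                              censor_to = c("lod", "zero")) {
  stopifnot(is.numeric(lod), length(lod) == 1L, lod > 0,
            is.numeric(noise_sigma), length(noise_sigma) == 1L,
            noise_sigma >= 0)
  structure(list(lod = lod, noise_sigma = noise_sigma,
                 censor_to = match.arg(censor_to)),
            class = "measurement_model")
}

#' Floor concentrations at the detection limit
#'
#' Values below `lod` are replaced by `lod` (or 0 with
#' `censor_to = "zero"`). Idempotent, and order-preserving above the LOD.
#'
#' @param values Concentrations, ug/mL.
#' @param lod Limit of detection, ug/mL.
#' @param censor_to `"lod"` or `"zero"`.
#' @return Censored values.
#' @export
lod_floor <- function(values, lod = 0.98, censor_to = c("lod", "zero")) {
  censor_to <- match.arg(censor_to)
  ifelse(values < lod, if (censor_to == "lod") lod else 0, values)
}

# Deterministically derive k substream seeds from a master seed.
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, k))
}

#' Draw measured effluent samples from a simulated concentration series
#'
#' Emulates the assay: the true concentration at each sampling time is
#' perturbed by independent multiplicative lognormal noise
#' (`measured = true * 10^N(0, sigma)`), then censored at the detection
#' limit. Each replicate uses its own RNG substream derived from `seed`, so
#' datasets are reproducible and replicates independent.
#'
#' @param series A [concentration_series()] covering all sampling times.
#' @param schedule A [sampling_schedule()].
#' @param meas A [measurement_model()].
#' @param n_replicates Number of replicate runs to emulate. Default 3.
#' @param seed Integer seed for the measurement noise.
#' @return A measured dataset: data frame with columns `arm`, `replicate`,
#'   `time_h`, `antibiotic`, `conc_ug_ml`, `censored` (0/1).
#' @export
sample_effluent <- function(series, schedule = sampling_schedule(),
                            meas = measurement_model(), n_replicates = 3,
                            seed = 1) {
  stopifnot(inherits(series, "concentration_series"),
            inherits(schedule, "sampling_schedule"),
            inherits(meas, "measurement_model"),
            n_replicates >= 1L)
  if (max(schedule$times) > max(series$time_h) ||
      min(schedule$times) < min(series$time_h)) {
    stop("sampling times fall outside the simulated series", call. = FALSE)
  }
  abs <- colnames(series$conc)
  times <- schedule$times
  true_mat <- vapply(abs, function(ab) conc_at(series, times, ab),
                     numeric(length(times)))
  true_mat <- matrix(true_mat, nrow = length(times),
                     dimnames = list(NULL, abs))
  rep_seeds <- derive_seeds(seed, n_replicates)
  arm <- if (is.null(series$arm)) NA_character_ else series$arm
  out <- lapply(seq_len(n_replicates), function(r) {
    noise <- withr::with_seed(
      rep_seeds[r],
      matrix(10^stats::rnorm(length(true_mat), sd = meas$noise_sigma),
             nrow = nrow(true_mat)))
    measured <- true_mat * noise
    do.call(rbind, lapply(abs, function(ab) {
      m <- measured[, ab]
      cens <- m < meas$lod
      data.frame(arm = arm, replicate = r, time_h = times, antibiotic = ab,
                 conc_ug_ml = lod_floor(m, meas$lod, meas$censor_to),
                 censored = as.integer(cens), row.names = NULL)
    }))
  })
  do.call(rbind, out)
}

#' Generate the standard synthetic effluent dataset
#'
#' Forward-simulates each requested arm with the reference depot
#' parameterization under the default drainage schedule, then emulates the
#' assay with [sample_effluent()]. This is the package's stand-in for the
#' bench LCMS measurements; it reproduces the qualitative arm behaviors
#' (spacer arms dip then rise as drainage declines; the bead-augmented arm
#' dominates the spacer alone) but not bench-specific effects such as
#' incomplete mixing.
#'
#' @param arms Subset of [arm_names()]. Default: all three.
#' @param n_replicates Replicates per arm. Default 3.
#' @param seed Master seed; each arm gets a derived substream.
#' @param meas A [measurement_model()]; set `noise_sigma = 0` for the
#'   deterministic (noise-free) fixture.
#' @param schedule A [sampling_schedule()].
#' @param volume Reactor volume, mL.
#' @param duration Simulated duration, hours.
#' @param solver_step_min Integration step, minutes.
#' @return Measured dataset (see [sample_effluent()]) covering all arms.
#' @export
generate_arm_fixtures <- function(arms = arm_names(), n_replicates = 3,
                                  seed = 1, meas = measurement_model(),
                                  schedule = sampling_schedule(),
                                  volume = 75, duration = 48,
                                  solver_step_min = 0.1) {
  arms <- match.arg(arms, arm_names(), several.ok = TRUE)
  pump <- build_stepwise_schedule(drainage_trendline(), duration = duration)
  arm_seeds <- derive_seeds(seed, length(arms))
  out <- lapply(seq_along(arms), function(i) {
    cfg <- reactor_config(default_depots(arms[i]), pump, volume = volume,
                          duration = duration,
                          solver_step_min = solver_step_min, arm = arms[i])
    sim <- simulate_reactor(cfg)
    sample_effluent(sim$series, schedule, meas, n_replicates,
                    seed = arm_seeds[i])
  })
  do.call(rbind, out)
}

#' Write a measured dataset to CSV
#'
#' Columns `arm`, `replicate`, `time_h`, `antibiotic`, `conc_ug_ml`,
#' `censored` — also the interchange schema for real assay exports.
#'
#' @param dataset Measured dataset data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(check_dataset(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Read a measured dataset from CSV
#'
#' @param path CSV path with the [write_dataset_csv()] schema.
#' @return Measured dataset data frame.
#' @export
read_dataset_csv <- function(path) {
  check_dataset(utils::read.csv(path))
}

# Validate the measured-dataset schema.
check_dataset <- function(dataset) {
  req <- c("arm", "replicate", "time_h", "antibiotic", "conc_ug_ml",
           "censored")
  if (!is.data.frame(dataset) || !all(req %in% names(dataset))) {
    stop("measured dataset must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  dataset
}
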