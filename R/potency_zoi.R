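#' Organism susceptibility profile
#'
#' Minimum inhibitory concentrations (MIC) per antibiotic for a reference
#' organism. An MIC reported as a bound (e.g. "> 64 ug/mL") is carried with
#' an open-above flag and read conservatively: no inhibition unless the
#' concentration exceeds the bound.
#'
#' @param name Organism name.
#' @param mic Named numeric vector of MICs, ug/mL (> 0), names from
#'   [antibiotic_names()].
#' @param open_above Named logical vector (same names), `TRUE` where the MIC
#'   is a "greater than" bound. Defaults to all `FALSE`.
#' @return An object of class `organism_profile`.
#' @export
organism_profile <- function(name, mic, open_above = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.numeric(mic),
            !is.null(names(mic)), all(mic > 0))
  if (!all(names(mic) %in% antibiotic_names())) {
    stop("MIC names must be known antibiotics", call. = FALSE)
  }
  if (is.null(open_above)) {
    open_above <- stats::setNames(rep(FALSE, length(mic)), names(mic))
  }
  stopifnot(is.logical(open_above), setequal(names(open_above), names(mic)))
  structure(list(name = name, mic = mic,
                 open_above = open_above[names(mic)]),
            class = "organism_profile")
}

#' Reference organisms for the potency assay
#'
#' The two strains used to corroborate effluent concentrations:
#' *Pseudomonas aeruginosa* PAO1 (MIC 1.5 ug/mL tobramycin, > 64 ug/mL
#' vancomycin) and *Staphylococcus aureus* UAMS-1 (MIC 2 ug/mL tobramycin,
#' 2 ug/mL vancomycin).
#'
#' @return Named list of [organism_profile()] objects (`pao1`, `uams1`).
#' @export
reference_organisms <- function() {
  list(
    pao1 = organism_profile(
      "Pseudomonas aeruginosa PAO1",
      mic = c(tobramycin = 1.5, vancomycin = 64),
      open_above = c(tobramycin = FALSE, vancomycin = TRUE)),
    uams1 = organism_profile(
      "Staphylococcus aureus UAMS-1",
      mic = c(tobramycin = 2, vancomycin = 2))
  )
}

#' Zone-of-inhibition calibration
#'
#' Log-linear disc-diffusion calibration: the predicted zone diameter grows
#' by `slope` mm per doubling of concentration above the MIC, starting from
#' the disc diameter (a zone equal to the disc means growth up to its edge,
#' i.e. no potency). The default slope is a model choice (standard
#' disc-diffusion theory gives diameter roughly linear in log concentration);
#' predicted diameters are comparable in shape and ordering, not absolute mm.
#'
#' @param disc_diameter_mm Filter disc diameter, mm. Default 7.
#' @param slope_mm_per_log2 Diameter gain per doubling above MIC, mm
#'   (>= 0). Default 2.
#' @return An object of class `zoi_calibration`.
#' @export
zoi_calibration <- function(disc_diameter_mm = 7, slope_mm_per_log2 = 2) {
  stopifnot(is.numeric(disc_diameter_mm), disc_diameter_mm > 0,
            is.numeric(slope_mm_per_log2), slope_mm_per_log2 >= 0)
  structure(list(disc_diameter_mm = disc_diameter_mm,
                 slope_mm_per_log2 = slope_mm_per_log2),
            class = "zoi_calibration")
}

#' Predict a zone-of-inhibition diameter
#'
#' Per agent: `disc + slope * log2(C / MIC)` when `C > MIC`, otherwise the
#' disc diameter (no inhibition beyond the disc). Agents with an open-above
#' MIC bound inhibit only when the concentration exceeds the bound. The
#' combined diameter is the maximum over agents (independent action, no
#' synergy), so adding an agent at zero concentration never changes the
#' prediction.
#'
#' @param concentrations Named numeric vector of concentrations, ug/mL
#'   (>= 0), names from [antibiotic_names()].
#' @param organism An [organism_profile()].
#' @param calib A [zoi_calibration()].
#' @return Predicted zone diameter, mm (always >= the disc diameter).
#' @export
#' @examples
#' uams1 <- reference_organisms()$uams1
#' predict_zoi(c(vancomycin = 8), uams1, zoi_calibration()) # 7 + 2*log2(4)
predict_zoi <- function(concentrations, organism, calib = zoi_calibration()) {
  stopifnot(inherits(organism, "organism_profile"),
            inherits(calib, "zoi_calibration"),
            is.numeric(concentrations), !is.null(names(concentrations)),
            all(concentrations >= 0))
  disc <- calib$disc_diameter_mm
  agents <- intersect(names(concentrations), names(organism$mic))
  d <- disc
  for (ab in agents) {
    C <- concentrations[[ab]]
    mic <- organism$mic[[ab]]
    if (C > mic) {
      d <- max(d, disc + calib$slope_mm_per_log2 * log2(C / mic))
    }
  }
  d
}

#' Predicted potency time course of a measured dataset
#'
#' Applies [predict_zoi()] to every replicate measurement (censored values
#' enter at their recorded value), then summarises the zone diameter as mean
#' with standard error per (arm, time).
#'
#' @param dataset Measured dataset (see [sample_effluent()]).
#' @param organism An [organism_profile()].
#' @param calib A [zoi_calibration()].
#' @return Data frame with columns `organism`, `arm`, `time_h`,
#'   `mean_zoi_mm`, `se_mm`, `n`.
#' @export
potency_series <- function(dataset, organism, calib = zoi_calibration()) {
  dataset <- check_dataset(dataset)
  stopifnot(inherits(organism, "organism_profile"))
  key <- interaction(dataset$arm, dataset$replicate, dataset$time_h,
                     drop = TRUE)
  per_rep <- do.call(rbind, lapply(split(dataset, key), function(g) {
    conc <- stats::setNames(g$conc_ug_ml, g$antibiotic)
    data.frame(arm = g$arm[1L], replicate = g$replicate[1L],
               time_h = g$time_h[1L],
               zoi_mm = predict_zoi(conc, organism, calib), row.names = NULL)
  }))
  key2 <- interaction(per_rep$arm, per_rep$time_h, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_rep, key2), function(g) {
    n <- nrow(g)
    data.frame(organism = organism$name, arm = g$arm[1L],
               time_h = g$time_h[1L], mean_zoi_mm = mean(g$zoi_mm),
               se_mm = if (n > 1L) stats::sd(g$zoi_mm) / sqrt(n) else 0,
               n = n, row.names = NULL)
  }))
  out <- out[order(out$arm, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a zone-of-inhibition summary to CSV
#'
#' Columns `organism`, `arm`, `time_h`, `mean_zoi_mm`, `se_mm`, `n`; measured
#' zone data in the same schema can be read back for side-by-side comparison.
#'
#' @param zoi Output of [potency_series()] (rows from several organisms may
#'   be combined).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_zoi_csv <- function(zoi, path) {
  req <- c("organism", "arm", "time_h", "mean_zoi_mm", "se_mm", "n")
  stopifnot(is.data.frame(zoi), all(req %in% names(zoi)))
  utils::write.csv(zoi, path, row.names = FALSE)
  invisible(path)
}
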