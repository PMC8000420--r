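#' Geometric-mean summary of a measured dataset
#'
#' Per (arm, time, antibiotic): the mean and standard error of log10
#' concentrations (the geometric mean on the log scale), after flooring
#' values at the detection limit. Groups with a single replicate get
#' `log10_se = 0` and `se_degenerate = TRUE`.
#'
#' @param dataset Measured dataset (see [sample_effluent()]).
#' @param lod Detection limit used for flooring, ug/mL.
#' @return Data frame with columns `arm`, `time_h`, `antibiotic`,
#'   `log10_mean`, `log10_se`, `n`, `se_degenerate`.
#' @export
#' @examples
#' d <- data.frame(arm = "a", replicate = 1:2, time_h = 1,
#'                 antibiotic = "vancomycin", conc_ug_ml = c(1, 100),
#'                 censored = 0)
#' summarize_log(d)$log10_mean # 1 -> geometric mean 10 ug/mL
summarize_log <- function(dataset, lod = 0.98) {
  dataset <- check_dataset(dataset)
  vals <- lod_floor(dataset$conc_ug_ml, lod)
  if (any(vals <= 0)) {
    stop("all concentrations must be positive after LOD flooring",
         call. = FALSE)
  }
  key <- interaction(dataset$arm, dataset$time_h, dataset$antibiotic,
                     drop = TRUE)
  groups <- split(data.frame(log10_c = log10(vals),
                             arm = dataset$arm, time_h = dataset$time_h,
                             antibiotic = dataset$antibiotic), key)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(arm = g$arm[1L], time_h = g$time_h[1L],
               antibiotic = g$antibiotic[1L],
               log10_mean = mean(g$log10_c),
               log10_se = if (n > 1L) stats::sd(g$log10_c) / sqrt(n) else 0,
               n = n, se_degenerate = n == 1L, row.names = NULL)
  }))
  out <- out[order(out$arm, out$antibiotic, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trapezoidal area under a concentration curve
#'
#' AUC on the linear scale over `[first sample, window_end]`, by the
#' trapezoidal rule on the observed times. If `window_end` falls between
#' samples the curve is linearly interpolated there; it must not exceed the
#' last sample.
#'
#' @param time_h Strictly increasing sampling times, hours.
#' @param conc Concentrations at those times, ug/mL (linear scale).
#' @param window_end Window end, hours (e.g. 2, 12, 24, 48).
#' @return AUC, ug*h/mL.
#' @export
auc_trapezoid <- function(time_h, conc, window_end) {
  stopifnot(is.numeric(time_h), is.numeric(conc),
            length(time_h) == length(conc),
            is.numeric(window_end), length(window_end) == 1L)
  if (any(diff(time_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (window_end > max(time_h)) {
    stop("AUC window extends beyond the last sample", call. = FALSE)
  }
  keep <- time_h <= window_end
  tt <- time_h[keep]
  cc <- conc[keep]
  if (max(tt) < window_end) {
    tt <- c(tt, window_end)
    cc <- c(cc, stats::approx(time_h, conc, xout = window_end)$y)
  }
  if (length(tt) < 2L) {
    stop("need at least 2 points inside the AUC window", call. = FALSE)
  }
  pracma::trapz(tt, cc)
}

#' Per-replicate AUC exposure windows
#'
#' Computes [auc_trapezoid()] for every (arm, replicate, antibiotic) at each
#' window end, on LOD-floored linear concentrations (censored values
#' contribute at the detection limit unless `censor_to = "zero"`).
#'
#' @param dataset Measured dataset.
#' @param windows Window ends, hours. Default `c(2, 12, 24, 48)`.
#' @param lod Detection limit, ug/mL.
#' @param censor_to `"lod"` (default) or `"zero"` substitution for censored
#'   values; exposed as a sensitivity option.
#' @return Data frame with columns `arm`, `replicate`, `antibiotic`,
#'   `window_h`, `auc_ug_h_ml`.
#' @export
auc_windows <- function(dataset, windows = c(2, 12, 24, 48), lod = 0.98,
                        censor_to = c("lod", "zero")) {
  dataset <- check_dataset(dataset)
  censor_to <- match.arg(censor_to)
  dataset$conc_ug_ml <- lod_floor(dataset$conc_ug_ml, lod, censor_to)
  key <- interaction(dataset$arm, dataset$replicate, dataset$antibiotic,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(dataset, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    do.call(rbind, lapply(windows, function(w) {
      data.frame(arm = g$arm[1L], replicate = g$replicate[1L],
                 antibiotic = g$antibiotic[1L], window_h = w,
                 auc_ug_h_ml = auc_trapezoid(g$time_h, g$conc_ug_ml, w),
                 row.names = NULL)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Log10 difference between two arm summaries
#'
#' Subtracts `summary_b`'s log10 means from `summary_a`'s per (time,
#' antibiotic) — the log difference between administration methods. The two
#' summaries must cover identical (time, antibiotic) grids.
#'
#' @param summary_a,summary_b Outputs of [summarize_log()], each for a single
#'   arm.
#' @return Data frame with columns `time_h`, `antibiotic`, `log10_diff`,
#'   `se` (propagated as the root sum of squared SEs).
#' @export
log_difference <- function(summary_a, summary_b) {
  for (s in list(summary_a, summary_b)) {
    stopifnot(is.data.frame(s),
              all(c("time_h", "antibiotic", "log10_mean") %in% names(s)))
  }
  if (length(unique(summary_a$arm)) > 1L ||
      length(unique(summary_b$arm)) > 1L) {
    stop("each summary must cover a single arm", call. = FALSE)
  }
  a <- summary_a[order(summary_a$antibiotic, summary_a$time_h), ]
  b <- summary_b[order(summary_b$antibiotic, summary_b$time_h), ]
  if (nrow(a) != nrow(b) || !all(a$time_h == b$time_h) ||
      !all(a$antibiotic == b$antibiotic)) {
    stop("summaries are on mismatched (time, antibiotic) grids",
         call. = FALSE)
  }
  data.frame(time_h = a$time_h, antibiotic = a$antibiotic,
             log10_diff = a$log10_mean - b$log10_mean,
             se = sqrt(a$log10_se^2 + b$log10_se^2), row.names = NULL)
}

#' Biofilm-eradication threshold band
#'
#' Concentration band that must be sustained to eradicate biofilm — the
#' reported minimal biofilm eradication concentration for a 1:1
#' vancomycin:tobramycin combination is 100–750 ug/mL held for at least 24 h.
#'
#' @param low Lower bound, ug/mL. Default 100.
#' @param high Upper bound, ug/mL. Default 750.
#' @param duration_h Required continuous coverage, hours. Default 24.
#' @return An object of class `threshold_band`.
#' @export
threshold_band <- function(low = 100, high = 750, duration_h = 24) {
  stopifnot(is.numeric(low), low > 0, is.numeric(high), high >= low,
            is.numeric(duration_h), duration_h > 0)
  structure(list(low = low, high = high, duration_h = duration_h),
            class = "threshold_band")
}

#' Time spent above a threshold concentration
#'
#' Total time the (combined) concentration is at or above `band$low`, with
#' crossing times located by linear interpolation between observations. The
#' `satisfied` flag is `TRUE` iff coverage is continuous from the first
#' sample through `band$duration_h`.
#'
#' @param time_h Strictly increasing times, hours.
#' @param conc Concentrations, ug/mL — for the 1:1 combination threshold,
#'   pass the summed vancomycin + tobramycin concentration (see
#'   [combined_concentration()]).
#' @param band A [threshold_band()].
#' @return List with `hours_above` and `satisfied`.
#' @export
time_above_threshold <- function(time_h, conc, band = threshold_band()) {
  stopifnot(inherits(band, "threshold_band"), is.numeric(time_h),
            is.numeric(conc), length(time_h) == length(conc))
  if (any(diff(time_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  lo <- band$low
  n <- length(time_h)
  hours <- 0
  first_below <- if (conc[1L] >= lo) NA_real_ else time_h[1L]
  for (i in seq_len(n - 1L)) {
    t1 <- time_h[i]; t2 <- time_h[i + 1L]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    dt <- t2 - t1
    if (c1 >= lo && c2 >= lo) {
      hours <- hours + dt
    } else if (c1 >= lo) { # falls through lo inside the interval
      tc <- t1 + dt * (c1 - lo) / (c1 - c2)
      hours <- hours + (tc - t1)
      if (is.na(first_below)) first_below <- tc
    } else if (c2 >= lo) { # rises through lo inside the interval
      tc <- t1 + dt * (lo - c1) / (c2 - c1)
      hours <- hours + (t2 - tc)
    }
  }
  covered_until <- if (is.na(first_below)) time_h[n] else first_below
  list(hours_above = hours,
       satisfied = conc[1L] >= lo && covered_until >= band$duration_h)
}

#' Combined 1:1 antibiotic concentration
#'
#' Sums the per-antibiotic concentrations of a series (for the combination
#' threshold, which is defined for the vancomycin + tobramycin mixture).
#'
#' @param series A [concentration_series()].
#' @return A [concentration_series()] with a single column `combined`.
#' @export
combined_concentration <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  conc <- matrix(rowSums(series$conc), ncol = 1L,
                 dimnames = list(NULL, "combined"))
  concentration_series(series$time_h, conc, arm = series$arm)
}

#' Equal-variance two-sample t-test
#'
#' Unpaired two-tailed Student's t-test with pooled variance, as used to
#' compare administration arms on log10 concentrations.
#'
#' @param group_a,group_b Numeric vectors (log10 values), each of length
#'   >= 2.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
students_t <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(c(group_a - mean(group_a), group_b - mean(group_b))) == 0) {
    stop("zero pooled variance: t statistic is degenerate", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Per-timepoint arm comparison
#'
#' Runs [students_t()] on LOD-floored log10 replicate concentrations of
#' `arm_a` vs `arm_b` at every shared (time, antibiotic). No multiple-testing
#' correction is applied by default, matching the per-timepoint reporting
#' convention; `adjust = "holm"` is available and flagged in the output.
#'
#' @param dataset Measured dataset containing both arms.
#' @param arm_a,arm_b Arm labels to compare (difference direction `a - b`).
#' @param lod Detection limit, ug/mL.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame with columns `time_h`, `antibiotic`, `t`, `p`, and
#'   `p_adj` when `adjust != "none"`; attribute `adjust` records the choice.
#' @export
compare_arms <- function(dataset, arm_a, arm_b, lod = 0.98,
                         adjust = c("none", "holm")) {
  dataset <- check_dataset(dataset)
  adjust <- match.arg(adjust)
  dataset <- dataset[dataset$arm %in% c(arm_a, arm_b), , drop = FALSE]
  if (!all(c(arm_a, arm_b) %in% dataset$arm)) {
    stop("both arms must be present in the dataset", call. = FALSE)
  }
  dataset$logc <- log10(lod_floor(dataset$conc_ug_ml, lod))
  key <- interaction(dataset$time_h, dataset$antibiotic, drop = TRUE)
  out <- do.call(rbind, lapply(split(dataset, key), function(g) {
    a <- g$logc[g$arm == arm_a]
    b <- g$logc[g$arm == arm_b]
    res <- tryCatch(students_t(a, b),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    data.frame(time_h = g$time_h[1L], antibiotic = g$antibiotic[1L],
               t = res$statistic, p = res$p_value, row.names = NULL)
  }))
  out <- out[order(out$antibiotic, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, method = "holm")
  attr(out, "adjust") <- adjust
  out
}

#' Exposure summary for a measured dataset
#'
#' Bundles the analysis pipeline outputs: log-scale summaries per arm, AUC
#' windows per replicate, per-replicate combined time above the threshold
#' band, and (when both spacer arms are present) the log-difference series
#' and per-timepoint t-tests for the bead-augmented arm vs the spacer alone.
#'
#' @param dataset Measured dataset.
#' @param windows AUC window ends, hours.
#' @param band A [threshold_band()].
#' @param lod Detection limit, ug/mL.
#' @param censor_to Censored-value substitution for linear-scale AUC.
#' @return List with elements `log_summary`, `auc`, `threshold`, and (if
#'   applicable) `log_diff`, `tests`.
#' @export
exposure_summary <- function(dataset, windows = c(2, 12, 24, 48),
                             band = threshold_band(), lod = 0.98,
                             censor_to = c("lod", "zero")) {
  dataset <- check_dataset(dataset)
  censor_to <- match.arg(censor_to)
  logsum <- summarize_log(dataset, lod)
  auc <- auc_windows(dataset, windows, lod, censor_to)
  # combined VAN+TOB time above threshold, per (arm, replicate)
  floored <- dataset
  floored$conc_ug_ml <- lod_floor(floored$conc_ug_ml, lod, censor_to)
  key <- interaction(floored$arm, floored$replicate, drop = TRUE)
  thresh <- do.call(rbind, lapply(split(floored, key), function(g) {
    comb <- stats::aggregate(conc_ug_ml ~ time_h, data = g, FUN = sum)
    res <- time_above_threshold(comb$time_h, comb$conc_ug_ml, band)
    data.frame(arm = g$arm[1L], replicate = g$replicate[1L],
               hours_above = res$hours_above, satisfied = res$satisfied,
               row.names = NULL)
  }))
  rownames(thresh) <- NULL
  out <- list(log_summary = logsum, auc = auc, threshold = thresh)
  if (all(c("csb_plus_spacer", "spacer_only") %in% dataset$arm)) {
    sa <- logsum[logsum$arm == "csb_plus_spacer", ]
    sb <- logsum[logsum$arm == "spacer_only", ]
    out$log_diff <- log_difference(sa, sb)
    out$tests <- compare_arms(dataset, "csb_plus_spacer", "spacer_only", lod)
  }
  out
}
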