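# Microplate screening statistics for the geraniol dehydrogenase (GeDH)
# assay: geraniol in culture supernatant is oxidized by GeDH with 1:1
# reduction of NAD+ to NADH, read as OD340 gain over a 30-min kinetic run.
# The module converts well time series into delta-OD340 signals, calibrates
# them against geraniol standards, calls high-yield hits relative to the
# starting strain, and computes specific enzyme activity from kinetic slopes.

#' Simulate a kinetic OD340 screening plate
#'
#' Generates long-format plate-reader data: each well ramps linearly from a
#' baseline to `baseline + delta` over `duration` minutes with Gaussian
#' reading noise. Following the assay protocol, each well is read
#' `n_replicates` times (default 3) and the recorded OD340 is the replicate
#' mean, so the effective reading noise is `noise_sd / sqrt(n_replicates)`.
#' Standards follow `delta = slope * conc + intercept`; samples are scaled
#' from the reference delta by their relative yield, with `spike_wells`
#' wells spiked at `spike_fold` (the planted hits).
#'
#' @param n_samples Number of sample wells (default 90).
#' @param n_reference Reference (starting-strain) wells (default 3).
#' @param standards_conc Geraniol standard concentrations in mg/l assayed
#'   (default 0-8 mg/l).
#' @param slope,intercept Calibration truth (delta-OD340 per mg/l).
#' @param reference_conc Assay-well geraniol concentration of the starting
#'   strain (mg/l).
#' @param yield_sd SD of the non-spiked samples' relative yield around 1.
#' @param spike_wells Number of spiked high-yield wells (default 3).
#' @param spike_fold Relative yield of spiked wells (default 2).
#' @param noise_sd Per-reading OD noise SD (before replicate averaging).
#' @param n_replicates Replicate reads averaged per recorded value (default 3).
#' @param n_timepoints,duration Readings per well and run length (minutes).
#' @param n_blank Medium-only blank wells (default 0).
#' @param seed Optional RNG seed.
#' @return Long `data.frame` with columns `well`, `strain`, `role`, `conc`,
#'   `time_min`, `od340`; the spiked well ids are in
#'   `attr(x, "spiked_wells")` and per-well truth in `attr(x, "truth")`.
#' @export
simulate_plate <- function(n_samples = 90L, n_reference = 3L,
                           standards_conc = c(0, 1, 2, 4, 6, 8),
                           slope = 0.04, intercept = 0,
                           reference_conc = 0.6, yield_sd = 0.05,
                           spike_wells = 3L, spike_fold = 2,
                           noise_sd = 0.002, n_replicates = 3L,
                           n_timepoints = 61L,
                           duration = 30, n_blank = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, length.out = n_timepoints)
  mk <- function(well, strain, role, conc, delta) {
    base <- 0.05
    noise <- rowMeans(matrix(stats::rnorm(length(t) * n_replicates, 0, noise_sd),
                             nrow = length(t)))
    data.frame(well = well, strain = strain, role = role, conc = conc,
               time_min = t,
               od340 = base + delta * t / duration + noise,
               stringsAsFactors = FALSE)
  }
  rel <- abs(stats::rnorm(n_samples, 1, yield_sd))
  spiked <- sample.int(n_samples, min(spike_wells, n_samples))
  rel[spiked] <- spike_fold
  ref_delta <- slope * reference_conc + intercept
  out <- list()
  for (i in seq_along(standards_conc)) {
    out[[length(out) + 1L]] <- mk(sprintf("STD%02d", i), "standard", "standard",
                                  standards_conc[i],
                                  slope * standards_conc[i] + intercept)
  }
  for (i in seq_len(n_reference)) {
    out[[length(out) + 1L]] <- mk(sprintf("REF%02d", i), "start_strain",
                                  "reference", NA_real_, ref_delta)
  }
  for (i in seq_len(n_samples)) {
    out[[length(out) + 1L]] <- mk(sprintf("S%03d", i), sprintf("scr%03d", i),
                                  "sample", NA_real_, ref_delta * rel[i])
  }
  for (i in seq_len(n_blank)) {
    out[[length(out) + 1L]] <- mk(sprintf("BLK%02d", i), "medium", "blank",
                                  NA_real_, 0)
  }
  plate <- do.call(rbind, out)
  attr(plate, "spiked_wells") <- sprintf("S%03d", sort(spiked))
  attr(plate, "truth") <- data.frame(well = sprintf("S%03d", seq_len(n_samples)),
                                     relative_yield = rel)
  plate
}

# Per-well delta OD340: endpoint difference (last - first reading), or the
# maximum sliding-window OLS slope times the run length for kinetic-phase
# data. Returns a named numeric vector.
well_delta_od <- function(plate, method = c("endpoint", "max_slope"),
                          window_points = 5L) {
  method <- match.arg(method)
  vapply(split(plate, plate$well), function(w) {
    w <- w[order(w$time_min), , drop = FALSE]
    if (nrow(w) < 2L) stop("well '", w$well[1L], "' has fewer than 2 readings")
    if (any(diff(w$time_min) <= 0)) stop("timestamps must be strictly increasing")
    if (method == "endpoint") {
      w$od340[nrow(w)] - w$od340[1L]
    } else {
      k <- min(window_points, nrow(w))
      slopes <- vapply(seq_len(nrow(w) - k + 1L), function(s) {
        seg <- w[s:(s + k - 1L), ]
        stats::cov(seg$time_min, seg$od340) / stats::var(seg$time_min)
      }, numeric(1))
      max(slopes) * (max(w$time_min) - min(w$time_min))
    }
  }, numeric(1))
}

#' Calibrate delta-OD340 against geraniol standards
#'
#' Blank-corrects (if blank wells are present), computes per-well
#' delta-OD340, and fits an ordinary least-squares line of delta-OD against
#' standard concentration. The model refuses to predict outside the
#' concentration span of the standards.
#'
#' @param plate Long plate `data.frame` (see [simulate_plate()] for columns).
#' @param method Signal summary passed to the delta computation.
#' @param window_points Sliding-window width for `method = "max_slope"`.
#' @return A `calibration_model` list: `slope`, `intercept`, `r_squared`,
#'   `range` (mg/l), `n_standards`.
#' @export
fit_calibration <- function(plate, method = c("endpoint", "max_slope"),
                            window_points = 5L) {
  method <- match.arg(method)
  std <- plate[plate$role == "standard", , drop = FALSE]
  if (!nrow(std)) stop("no standard wells in plate")
  deltas <- well_delta_od(std, method, window_points)
  conc <- vapply(split(std, std$well), function(w) w$conc[1L], numeric(1))
  blanks <- plate[plate$role == "blank", , drop = FALSE]
  blank_delta <- if (nrow(blanks)) mean(well_delta_od(blanks, method, window_points)) else 0
  deltas <- deltas - blank_delta
  if (length(unique(conc)) < 3L) stop("need standards at >= 3 distinct concentrations")
  if (diff(range(conc)) == 0) stop("standard concentrations have zero spread")
  fit <- stats::lm(deltas ~ conc)
  ss_tot <- sum((deltas - mean(deltas))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 range = range(conc),
                 n_standards = length(conc),
                 blank_delta = blank_delta),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> dOD340 = %.5g * conc + %.5g (R2 = %.4f, range %g-%g mg/l, %d standards)\n",
              x$slope, x$intercept, x$r_squared, x$range[1], x$range[2],
              x$n_standards))
  invisible(x)
}

#' Invert a calibration to estimate geraniol concentration
#'
#' @param model A `calibration_model`.
#' @param delta_od Delta-OD340 value(s).
#' @param allow_extrapolation Return `NA` instead of erroring outside the
#'   calibrated range (default `FALSE` errors).
#' @return Concentration(s) in mg/l.
#' @export
predict_concentration <- function(model, delta_od, allow_extrapolation = FALSE) {
  conc <- (delta_od - model$intercept) / model$slope
  out <- conc < model$range[1] - 1e-9 | conc > model$range[2] + 1e-9
  if (any(out, na.rm = TRUE)) {
    if (!allow_extrapolation) {
      stop("delta-OD implies concentration outside the calibrated range [",
           model$range[1], ", ", model$range[2], "] mg/l")
    }
    conc[out] <- NA_real_
  }
  conc
}

#' Call high-yield hits from a screening plate
#'
#' Computes each sample well's delta-OD340 relative to the mean of the
#' reference (starting-strain) wells and calls a hit when the relative signal
#' is at least `fold_threshold` (boundary inclusive). With a calibration
#' model, assay concentrations are estimated and multiplied by
#' `broth_dilution_factor` (the 1:1 broth:buffer assay dilution) to report
#' broth concentrations.
#'
#' @param plate Long plate `data.frame`.
#' @param fold_threshold Relative delta-OD hit threshold (default 1.5).
#' @param calibration Optional `calibration_model`.
#' @param method,window_points Signal summary (see [fit_calibration()]).
#' @param broth_dilution_factor Concentration factor from assay well to broth
#'   (default 2 for the 1:1 mix).
#' @return `data.frame` with one row per sample well: `well`, `strain`,
#'   `delta_od`, `relative_delta`, `hit`, and `geraniol_mgl` (broth) when a
#'   calibration is supplied.
#' @export
call_hits <- function(plate, fold_threshold = 1.5, calibration = NULL,
                      method = c("endpoint", "max_slope"), window_points = 5L,
                      broth_dilution_factor = 2) {
  method <- match.arg(method)
  refs <- plate[plate$role == "reference", , drop = FALSE]
  if (!nrow(refs)) stop("no reference wells in plate")
  blanks <- plate[plate$role == "blank", , drop = FALSE]
  blank_delta <- if (nrow(blanks)) mean(well_delta_od(blanks, method, window_points)) else 0
  ref_mean <- mean(well_delta_od(refs, method, window_points)) - blank_delta
  if (ref_mean <= 0) stop("reference wells have non-positive delta-OD340 signal")
  samples <- plate[plate$role == "sample", , drop = FALSE]
  deltas <- well_delta_od(samples, method, window_points) - blank_delta
  strain <- vapply(split(samples, samples$well), function(w) w$strain[1L], "")
  out <- data.frame(well = names(deltas), strain = strain[names(deltas)],
                    delta_od = unname(deltas),
                    relative_delta = unname(deltas) / ref_mean,
                    stringsAsFactors = FALSE)
  out$hit <- out$relative_delta >= fold_threshold
  if (!is.null(calibration)) {
    out$geraniol_mgl <- predict_concentration(calibration, out$delta_od,
                                              allow_extrapolation = TRUE) *
      broth_dilution_factor
  }
  rownames(out) <- NULL
  out[order(out$well), , drop = FALSE]
}

#' Specific enzyme activity from a kinetic OD340 slope
#'
#' Converts an NADH formation rate (Beer-Lambert, 1:1 NADH:geraniol
#' stoichiometry) into specific activity:
#' `activity = slope / (extinction * path) * volume * 1e6 / mass` in
#' umol min^-1 mg^-1 (U/mg).
#'
#' @param slope_od_per_min Kinetic slope (delta-OD340 per minute, >= 0).
#' @param extinction_coefficient NADH molar extinction at 340 nm in
#'   M^-1 cm^-1 (default 6220).
#' @param path_length_cm Optical path length (cm).
#' @param reaction_volume_l Reaction volume (liters).
#' @param enzyme_mass_mg Enzyme mass (mg).
#' @return Specific activity in U/mg.
#' @export
specific_activity <- function(slope_od_per_min, extinction_coefficient = 6220,
                              path_length_cm = 1, reaction_volume_l,
                              enzyme_mass_mg) {
  if (slope_od_per_min < 0) stop("kinetic slope must be >= 0")
  if (extinction_coefficient <= 0 || path_length_cm <= 0 ||
      reaction_volume_l <= 0 || enzyme_mass_mg <= 0) {
    stop("extinction coefficient, path length, volume and mass must be positive")
  }
  slope_od_per_min / (extinction_coefficient * path_length_cm) *
    reaction_volume_l * 1e6 / enzyme_mass_mg
}

#' Write a plate as long-format CSV
#'
#' @param plate Long plate `data.frame`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format plate CSV
#'
#' @param path Input CSV with columns `well`, `strain`, `role`, `conc`,
#'   `time_min`, `od340`.
#' @return Long plate `data.frame`.
#' @export
read_plate_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well", "strain", "role", "time_min", "od340")
  if (!all(req %in% names(x))) {
    stop("plate CSV must have columns: ", paste(req, collapse = ", "))
  }
  if (!"conc" %in% names(x)) x$conc <- NA_real_
  x
}
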