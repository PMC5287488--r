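#' Pipeline configuration constants
#'
#' Bundles every numeric constant used by the processing chain in a single
#' validated object, so that sensitivity analyses can override any of them
#' while the defaults reproduce the standard large-cohort wrist protocol:
#' stationary windows of 10 s with a 13 mg per-axis SD ceiling, a +-300 mg
#' calibration range requirement, +-8 g clipping, 100 Hz resampling with a
#' 5 s interrupt rule, a 4th-order 20 Hz low-pass, 5 s epochs, 60 min
#' non-wear episodes, 1 min imputation slots, and the 72 h / 24-bin
#' inclusion rule.
#'
#' @param stationary_window_s Window length for stationary detection (s).
#' @param stationary_sd_threshold_mg Per-axis SD ceiling for a window to
#'   count as stationary (mg).
#' @param calib_range_mg Per-axis range the stationary means must span on
#'   both sides of zero for a self-calibration to be attempted (mg).
#' @param calib_min_windows Minimum number of stationary windows required
#'   for a self-fit.
#' @param clip_limit_g Sensor dynamic range; values at or beyond are clips (g).
#' @param resample_rate_hz Target uniform sampling rate (Hz).
#' @param max_gap_s Longest raw-sample gap bridged by linear interpolation
#'   (s); longer gaps are interrupts and become missing data.
#' @param filter_order Butterworth order for the noise filter.
#' @param filter_cutoff_hz Low-pass cutoff for machine-noise removal (Hz).
#'   Must be below the Nyquist frequency of `resample_rate_hz`.
#' @param highpass_cutoff_hz Cutoff of the high-pass gravity-removal
#'   variant (Hz).
#' @param epoch_s Epoch length for aggregation (s).
#' @param nonwear_min_minutes Minimum stationary run length classed as
#'   non-wear (min).
#' @param impute_granularity_min Time-of-day slot width for imputation (min).
#' @param impute_widen_min Half-width of the widened slot pool used when a
#'   minute slot has no worn data on any other day (min).
#' @param min_wear_h Minimum worn hours for inclusion.
#' @param hourly_coverage_bins Number of hour-of-day bins that must each
#'   contain worn data for inclusion.
#' @param gravity_mg One gravitational unit in mg.
#' @param ecdf_max_mg Top breakpoint of the intensity grid (mg); epochs above
#'   it are top-coded into the final bin.
#' @param ecdf_step_mg Spacing of the intensity grid (mg).
#' @param ecdf_include_imputed Logical; include imputed epochs in the
#'   intensity distribution (the default) or worn epochs only.
#'
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$filter_cutoff_hz
#' # scaled-down configuration for fast low-rate simulations
#' pipeline_config(resample_rate_hz = 25, filter_cutoff_hz = 5)
pipeline_config <- function(stationary_window_s = 10,
                            stationary_sd_threshold_mg = 13,
                            calib_range_mg = 300,
                            calib_min_windows = 10,
                            clip_limit_g = 8,
                            resample_rate_hz = 100,
                            max_gap_s = 5,
                            filter_order = 4,
                            filter_cutoff_hz = 20,
                            highpass_cutoff_hz = 0.2,
                            epoch_s = 5,
                            nonwear_min_minutes = 60,
                            impute_granularity_min = 1,
                            impute_widen_min = 30,
                            min_wear_h = 72,
                            hourly_coverage_bins = 24,
                            gravity_mg = 1000,
                            ecdf_max_mg = 2000,
                            ecdf_step_mg = 5,
                            ecdf_include_imputed = TRUE) {
  cfg <- list(
    stationary_window_s = stationary_window_s,
    stationary_sd_threshold_mg = stationary_sd_threshold_mg,
    calib_range_mg = calib_range_mg,
    calib_min_windows = calib_min_windows,
    clip_limit_g = clip_limit_g,
    resample_rate_hz = resample_rate_hz,
    max_gap_s = max_gap_s,
    filter_order = filter_order,
    filter_cutoff_hz = filter_cutoff_hz,
    highpass_cutoff_hz = highpass_cutoff_hz,
    epoch_s = epoch_s,
    nonwear_min_minutes = nonwear_min_minutes,
    impute_granularity_min = impute_granularity_min,
    impute_widen_min = impute_widen_min,
    min_wear_h = min_wear_h,
    hourly_coverage_bins = hourly_coverage_bins,
    gravity_mg = gravity_mg,
    ecdf_max_mg = ecdf_max_mg,
    ecdf_step_mg = ecdf_step_mg,
    ecdf_include_imputed = ecdf_include_imputed
  )
  num <- cfg[!names(cfg) %in% "ecdf_include_imputed"]
  bad <- names(num)[!vapply(num, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("pipeline_config: not a strictly positive scalar: ",
         paste(bad, collapse = ", "))
  if (filter_cutoff_hz >= resample_rate_hz / 2)
    stop("pipeline_config: filter_cutoff_hz must be below the Nyquist ",
         "frequency (resample_rate_hz / 2)")
  if (!is.logical(ecdf_include_imputed) || length(ecdf_include_imputed) != 1L)
    stop("pipeline_config: ecdf_include_imputed must be a single logical")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   argument names.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("read_config: unknown configuration keys: ",
         paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Intensity distribution breakpoints
#'
#' @param config A `pipeline_config`.
#' @return Ascending numeric vector of mg breakpoints (0, 5, ..., 2000 by
#'   default).
#' @keywords internal
ecdf_grid <- function(config) {
  seq(0, config$ecdf_max_mg, by = config$ecdf_step_mg)
}
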