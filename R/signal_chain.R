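# Calibrated raw samples -> uniform grid -> Euclidean norm -> low-pass
# noise removal -> gravity removal. The norm is taken before filtering
# (machine noise is removed from the scalar magnitude), and all filtering
# is zero-phase so epoch boundaries are not smeared by group delay.

new_uniform_signal <- function(start, utc_offset_s, rate_hz, values,
                               missing, interrupts = NA_integer_) {
  structure(list(start = start, utc_offset_s = as.integer(utc_offset_s),
                 rate_hz = rate_hz, values = values, missing = missing,
                 interrupts = as.integer(interrupts)),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  n <- if (is.matrix(x$values)) nrow(x$values) else length(x$values)
  cat(sprintf(
    "<uniform_signal> %d samples @ %g Hz (%s), %d missing, %s interrupt(s)\n",
    n, x$rate_hz, if (is.matrix(x$values)) "triaxial" else "scalar",
    sum(x$missing), x$interrupts))
  invisible(x)
}

#' Resample a recording to a uniform grid
#'
#' Linear interpolation onto an exact grid (10 ms steps at the default
#' 100 Hz) anchored at the first sample. Grid points falling strictly
#' inside a raw-sample gap longer than `max_gap_s` are marked missing
#' rather than interpolated; each such gap counts as one interrupt.
#'
#' @param rec A (calibrated) [raw_recording()].
#' @param config A [pipeline_config()].
#' @return A triaxial `uniform_signal` (values: n x 3 matrix in g) with a
#'   missing mask and the interrupt count.
#' @export
resample_with_gaps <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  if (nrow(rec$data) < 2L)
    stop("resample_with_gaps: need at least two samples")
  step <- 1 / config$resample_rate_hz
  t <- as.numeric(rec$data$time) - as.numeric(rec$start_time)
  n_grid <- floor(t[length(t)] / step) + 1L
  grid <- (seq_len(n_grid) - 1L) * step
  vals <- matrix(NA_real_, n_grid, 3L, dimnames = list(NULL, AXES))
  for (i in 1:3)
    vals[, i] <- approx(t, rec$data[[AXES[i]]], xout = grid,
                        method = "linear", rule = 2)$y
  gaps <- diff(t)
  long <- which(gaps > config$max_gap_s)
  miss <- rep(FALSE, n_grid)
  for (j in long) {
    inside <- grid > t[j] & grid < t[j + 1L]
    miss[inside] <- TRUE
  }
  vals[miss, ] <- NA_real_
  new_uniform_signal(rec$start_time, rec$utc_offset_s,
                     config$resample_rate_hz, vals, miss,
                     interrupts = length(long))
}

#' Euclidean norm of a triaxial signal
#'
#' @param signal A triaxial `uniform_signal`.
#' @return A scalar `uniform_signal` of per-sample vector magnitudes (g);
#'   a sample is missing if any channel is missing.
#' @export
vector_magnitude <- function(signal) {
  stopifnot(inherits(signal, "uniform_signal"), is.matrix(signal$values))
  vm <- sqrt(rowSums(signal$values^2))
  new_uniform_signal(signal$start, signal$utc_offset_s, signal$rate_hz,
                     vm, signal$missing, signal$interrupts)
}

# Zero-phase IIR filtering with steady-state initial conditions at both
# ends (the filter is assumed settled at the first/last sample value).
# DC response is then exact; the response at the cutoff is the squared
# single-pass magnitude (0.5 for Butterworth) because of the double pass.
# `dc_gain` is the filter's own DC response (1 for low-pass, 0 for
# high/band-pass) and fixes the steady-state output history.
zerophase_filter <- function(x, b, a, dc_gain = 1) {
  one_pass <- function(v) {
    v0 <- v[1L]
    as.numeric(signal::filter(
      b, a, v,
      init.x = rep(v0, length(b) - 1L),
      init = rep(v0 * dc_gain, length(a) - 1L)))
  }
  rev(one_pass(rev(one_pass(x))))
}

# apply fn per contiguous non-missing run; runs shorter than min_len are
# passed through untouched (caller warns)
map_segments <- function(values, missing, min_len, fn) {
  out <- values
  r <- rle(!missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  short <- FALSE
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    if (length(idx) < min_len) { short <- TRUE; next }
    out[idx] <- fn(values[idx])
  }
  attr(out, "short_segment") <- short
  out
}

#' Remove machine noise with a zero-phase Butterworth low-pass
#'
#' A 4th-order low-pass at 20 Hz (defaults), applied forward and backward
#' per contiguous non-missing segment; missing runs are never bridged.
#' The double pass keeps DC gain exactly 1 and attenuates the cutoff
#' frequency to amplitude 0.5 (the squared -3 dB point). Segments shorter
#' than three filter orders are passed through unfiltered with a warning.
#'
#' @param signal A scalar `uniform_signal` (vector magnitude in g).
#' @param config A [pipeline_config()].
#' @return The filtered scalar `uniform_signal`.
#' @export
lowpass_noise_filter <- function(signal, config = pipeline_config()) {
  stopifnot(inherits(signal, "uniform_signal"), !is.matrix(signal$values))
  if (config$filter_cutoff_hz >= signal$rate_hz / 2)
    stop("lowpass_noise_filter: cutoff at or above Nyquist for this signal")
  bf <- signal::butter(config$filter_order,
                       config$filter_cutoff_hz / (signal$rate_hz / 2),
                       type = "low")
  out <- signal
  filt <- map_segments(signal$values, signal$missing,
                       min_len = 3L * config$filter_order,
                       fn = function(v) zerophase_filter(v, bf$b, bf$a, 1))
  if (isTRUE(attr(filt, "short_segment")))
    warning("lowpass_noise_filter: segment(s) shorter than 3 x filter ",
            "order passed through unfiltered")
  attr(filt, "short_segment") <- NULL
  out$values <- filt
  out
}

#' Separate activity from gravity in the vector magnitude
#'
#' Three variants of gravity removal, all reported in mg:
#' \describe{
#'   \item{`enmo_trunc`}{Euclidean norm minus one, negatives truncated to
#'     zero: `max(VM - 1, 0) * 1000`. The primary activity metric.}
#'   \item{`enmo_abs`}{Absolute deviation from one: `|VM - 1| * 1000`.}
#'   \item{`highpass_vm`}{VM high-pass filtered (4th-order zero-phase
#'     Butterworth, 0.2 Hz default cutoff), rectified.}
#' }
#' Missing samples propagate unchanged.
#'
#' @param vm_signal Scalar `uniform_signal` of vector magnitude in g.
#' @param mode One of `"enmo_trunc"`, `"enmo_abs"`, `"highpass_vm"`.
#' @param config A [pipeline_config()].
#' @return A scalar `uniform_signal` in mg.
#' @export
remove_gravity <- function(vm_signal, mode = c("enmo_trunc", "enmo_abs",
                                               "highpass_vm"),
                           config = pipeline_config()) {
  stopifnot(inherits(vm_signal, "uniform_signal"),
            !is.matrix(vm_signal$values))
  mode <- match.arg(mode)
  g_mg <- config$gravity_mg
  out <- vm_signal
  out$values <- switch(
    mode,
    enmo_trunc = pmax(vm_signal$values - 1, 0) * g_mg,
    enmo_abs = abs(vm_signal$values - 1) * g_mg,
    highpass_vm = {
      bf <- signal::butter(config$filter_order,
                           config$highpass_cutoff_hz /
                             (vm_signal$rate_hz / 2),
                           type = "high")
      hp <- map_segments(vm_signal$values, vm_signal$missing,
                         min_len = 3L * config$filter_order,
                         fn = function(v)
                           zerophase_filter(v, bf$b, bf$a, 0))
      attr(hp, "short_segment") <- NULL
      abs(hp) * g_mg
    })
  out
}
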