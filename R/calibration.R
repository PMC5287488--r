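# Gravity autocalibration: during stationary periods the measured vector
# should have unit norm. Per-axis offset and gain (plus optional linear
# temperature terms) are estimated by iterated least squares: project each
# stationary mean onto the unit sphere, regress corrected onto projected
# per axis, repeat to convergence.

#' Find stationary windows in a raw recording
#'
#' Scans non-overlapping windows (10 s by default), aligned to the
#' recording start, and keeps those whose per-axis standard deviation is
#' below the stationary threshold on all three axes. Windows that are not
#' fully sampled (interrupt gaps) or that contain clipped readings are
#' skipped: clipped rest geometry is not trustworthy.
#'
#' @param rec A [raw_recording()].
#' @param config A [pipeline_config()].
#' @return `data.table` with one row per stationary window: `widx` (window
#'   index from recording start), `start`, per-axis means `mx,my,mz` (g),
#'   SDs `sdx,sdy,sdz` (mg), and mean `temperature` when present.
#' @export
find_stationary_windows <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  win_s <- config$stationary_window_s
  lim <- config$clip_limit_g
  expected <- round(rec$nominal_rate_hz * win_s)
  dat <- rec$data
  t0 <- as.numeric(rec$start_time)
  w <- floor((as.numeric(dat$time) - t0) / win_s)
  has_temp <- "temperature" %in% names(dat)
  clip <- abs(dat$x) >= lim | abs(dat$y) >= lim | abs(dat$z) >= lim
  g <- dat[, .(widx = w, x, y, z,
               temperature = if (has_temp) temperature else NA_real_,
               clip = clip)]
  agg <- g[, .(n_in = .N, n_clip = sum(clip),
               mx = mean(x), my = mean(y), mz = mean(z),
               sdx = sd(x) * 1e3, sdy = sd(y) * 1e3, sdz = sd(z) * 1e3,
               temperature = mean(temperature)), by = widx]
  thr <- config$stationary_sd_threshold_mg
  keep <- agg[n_in == expected & n_clip == 0L &
                sdx < thr & sdy < thr & sdz < thr]
  out <- keep[, .(widx,
                  start = as.POSIXct(t0 + widx * win_s,
                                     origin = "1970-01-01", tz = "UTC"),
                  mx, my, mz, sdx, sdy, sdz, temperature)]
  setorder(out, widx)
  out[]
}

#' Check whether stationary windows support calibration
#'
#' A self-calibration requires each axis's stationary means to include
#' values on both sides of zero beyond the configured range (+-300 mg by
#' default), i.e. the device rested in sufficiently varied orientations.
#'
#' @param windows Output of [find_stationary_windows()].
#' @param config A [pipeline_config()].
#' @return List with `ok` (logical) and `range`, a 3 x 2 matrix of per-axis
#'   min/max stationary means in g.
#' @export
check_calibratable <- function(windows, config = pipeline_config()) {
  need <- config$calib_range_mg / 1e3
  if (nrow(windows) == 0L) {
    rng <- matrix(NA_real_, 3, 2, dimnames = list(AXES, c("min", "max")))
    return(list(ok = FALSE, range = rng))
  }
  m <- as.matrix(windows[, .(mx, my, mz)])
  rng <- cbind(min = apply(m, 2, min), max = apply(m, 2, max))
  rownames(rng) <- AXES
  list(ok = all(rng[, "min"] < -need) && all(rng[, "max"] > need),
       range = rng)
}

uncalibratable <- function(msg) {
  stop(structure(class = c("wristpa_uncalibratable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

new_calibration_model <- function(offset, gain, temp_coeff = NULL,
                                  mean_temp_c = NA_real_,
                                  rmse_before_mg = NA_real_,
                                  rmse_after_mg = NA_real_,
                                  n_windows = 0L, source = "identity",
                                  fitted_at = NA) {
  structure(list(offset = offset, gain = gain, temp_coeff = temp_coeff,
                 mean_temp_c = mean_temp_c,
                 rmse_before_mg = rmse_before_mg,
                 rmse_after_mg = rmse_after_mg,
                 n_windows = as.integer(n_windows), source = source,
                 fitted_at = fitted_at),
            class = "calibration_model")
}

#' Identity calibration model
#'
#' @param fitted_at Optional timestamp recorded with the model.
#' @return A `calibration_model` with zero offset and unit gain,
#'   `source = "identity"`.
#' @export
identity_calibration <- function(fitted_at = NA) {
  new_calibration_model(offset = c(0, 0, 0), gain = c(1, 1, 1),
                        rmse_before_mg = NA_real_, rmse_after_mg = NA_real_,
                        source = "identity", fitted_at = fitted_at)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> source=%s, n_windows=%d\n",
              x$source, x$n_windows))
  cat(sprintf("  offset (mg): %s\n",
              paste(sprintf("%+.2f", x$offset * 1e3), collapse = " ")))
  cat(sprintf("  gain:        %s\n",
              paste(sprintf("%.5f", x$gain), collapse = " ")))
  if (!is.null(x$temp_coeff))
    cat(sprintf("  temp coeff (mg/degC): %s (ref %.1f degC)\n",
                paste(sprintf("%+.3f", x$temp_coeff * 1e3), collapse = " "),
                x$mean_temp_c))
  cat(sprintf("  stationary RMSE: %.2f -> %.2f mg\n",
              x$rmse_before_mg, x$rmse_after_mg))
  invisible(x)
}

sphere_rmse_mg <- function(m) {
  sqrt(mean((sqrt(rowSums(m^2)) - 1)^2)) * 1e3
}

#' Fit per-axis offset and gain to the unit gravity sphere
#'
#' Iteratively re-projected least squares: each stationary mean is
#' projected to its nearest point on the unit sphere, the corrected value
#' is regressed per axis onto the projection (with a linear temperature
#' term when a temperature channel is present), and the linear maps are
#' composed until the coefficient change falls below `tol`. A single OLS
#' pass cannot fit a sphere; the iteration converges to the standard
#' autocalibration solution.
#'
#' @param windows Output of [find_stationary_windows()]; at least
#'   `config$calib_min_windows` rows spanning the required range.
#' @param config A [pipeline_config()].
#' @param use_temperature Include temperature terms when the windows carry
#'   a temperature channel.
#' @param tol Convergence tolerance on coefficient change.
#' @param max_iter Iteration cap.
#' @return A `calibration_model` with `source = "self"`, stationary-sphere
#'   RMSE before/after in mg, and the window count.
#' @export
fit_calibration <- function(windows, config = pipeline_config(),
                            use_temperature = TRUE,
                            tol = 1e-9, max_iter = 1000L) {
  if (nrow(windows) < config$calib_min_windows)
    uncalibratable(sprintf(
      "only %d stationary windows (need >= %d)", nrow(windows),
      config$calib_min_windows))
  chk <- check_calibratable(windows, config)
  if (!chk$ok)
    uncalibratable(sprintf(
      "stationary means do not span +-%g mg on every axis",
      config$calib_range_mg))
  X <- as.matrix(windows[, .(mx, my, mz)])
  n <- nrow(X)
  has_temp <- use_temperature && "temperature" %in% names(windows) &&
    all(is.finite(windows$temperature))
  Tc <- if (has_temp) windows$temperature - mean(windows$temperature)
  # linear form: corrected = raw * scale + icept (+ tcoef * (T - Tbar))
  scale <- rep(1, 3); icept <- rep(0, 3); tcoef <- rep(0, 3)
  rmse_before <- sphere_rmse_mg(X)
  for (it in seq_len(max_iter)) {
    curr <- sweep(X, 2, scale, "*")
    curr <- sweep(curr, 2, icept, "+")
    if (has_temp) curr <- curr + outer(Tc, tcoef)
    norms <- sqrt(rowSums(curr^2))
    target <- curr / norms
    d_max <- 0
    for (a in 1:3) {
      D <- if (has_temp) cbind(1, curr[, a], Tc) else cbind(1, curr[, a])
      cf <- stats::lm.fit(D, target[, a])$coefficients
      new_scale <- cf[2L] * scale[a]
      new_icept <- cf[1L] + cf[2L] * icept[a]
      new_tcoef <- if (has_temp) cf[2L] * tcoef[a] + cf[3L] else 0
      d_max <- max(d_max, abs(new_scale - scale[a]),
                   abs(new_icept - icept[a]), abs(new_tcoef - tcoef[a]))
      scale[a] <- new_scale; icept[a] <- new_icept; tcoef[a] <- new_tcoef
    }
    if (d_max < tol) break
  }
  if (any(scale <= 0.5) || any(scale >= 2))
    uncalibratable(sprintf(
      "fitted gain outside (0.5, 2): %s",
      paste(sprintf("%.3f", scale), collapse = " ")))
  corrected <- sweep(sweep(X, 2, scale, "*"), 2, icept, "+")
  if (has_temp) corrected <- corrected + outer(Tc, tcoef)
  rmse_after <- sphere_rmse_mg(corrected)
  new_calibration_model(
    offset = -icept / scale, gain = scale,
    temp_coeff = if (has_temp) tcoef,
    mean_temp_c = if (has_temp) mean(windows$temperature) else NA_real_,
    rmse_before_mg = rmse_before, rmse_after_mg = min(rmse_after, rmse_before),
    n_windows = n, source = "self",
    fitted_at = if (nrow(windows)) windows$start[1L] else NA)
}

#' Apply a calibration model to a raw recording
#'
#' Each sample is corrected per axis as `(raw - offset) * gain`, plus
#' `temp_coeff * (T - Tref)` when both the model and the recording carry
#' temperature. Clips are re-counted (and re-clamped) after correction.
#'
#' @param rec A [raw_recording()].
#' @param model A `calibration_model`.
#' @param config A [pipeline_config()].
#' @return A calibrated [raw_recording()] with `clips_after_calib` filled
#'   in and the model attached as attribute `"calibration"`.
#' @export
apply_calibration <- function(rec, model, config = pipeline_config()) {
  stopifnot(inherits(rec, "raw_recording"),
            inherits(model, "calibration_model"))
  dat <- copy(rec$data)
  has_temp <- !is.null(model$temp_coeff) && "temperature" %in% names(dat) &&
    is.finite(model$mean_temp_c)
  dT <- if (has_temp) dat$temperature - model$mean_temp_c
  for (i in 1:3) {
    a <- AXES[i]
    v <- (dat[[a]] - model$offset[i]) * model$gain[i]
    if (has_temp) v <- v + model$temp_coeff[i] * dT
    set(dat, j = a, value = v)
  }
  lim <- config$clip_limit_g
  clipped <- abs(dat$x) >= lim | abs(dat$y) >= lim | abs(dat$z) >= lim
  for (a in AXES) set(dat, j = a, value = pmin(pmax(dat[[a]], -lim), lim))
  out <- rec
  out$data <- dat
  out$quality$clips_after_calib <- sum(clipped)
  attr(out, "calibration") <- model
  out
}

#' Resolve a calibration model for a recording
#'
#' Tries a self-fit first. If the recording has too few stationary windows
#' or insufficient orientation range, coefficients are borrowed from the
#' same device's registry: the most recent prior model, else the next one.
#' With no usable registry entry an identity model is used and a warning
#' emitted.
#'
#' @param rec A [raw_recording()].
#' @param registry A calibration registry (see [read_registry()]): a named
#'   list, `device_id` to chronological list of models. May be `NULL`.
#' @param config A [pipeline_config()].
#' @param use_temperature Passed to [fit_calibration()].
#' @return A `calibration_model` whose `source` records its provenance
#'   (`self`, `borrowed_previous`, `borrowed_next` or `identity`).
#' @export
resolve_calibration <- function(rec, registry = NULL,
                                config = pipeline_config(),
                                use_temperature = TRUE) {
  win <- find_stationary_windows(rec, config)
  model <- tryCatch(
    fit_calibration(win, config, use_temperature = use_temperature),
    wristpa_uncalibratable = function(e) NULL)
  if (!is.null(model)) {
    model$fitted_at <- rec$start_time
    return(model)
  }
  entries <- registry[[rec$device_id]]
  if (length(entries)) {
    at <- vapply(entries, function(m) as.numeric(as.POSIXct(m$fitted_at)),
                 numeric(1))
    t0 <- as.numeric(rec$start_time)
    prior <- which(at <= t0)
    pick <- if (length(prior)) prior[which.max(at[prior])] else which.min(at)
    model <- entries[[pick]]
    model$source <- if (length(prior)) "borrowed_previous" else "borrowed_next"
    return(model)
  }
  warning("resolve_calibration: recording uncalibratable and no registry ",
          "entry for device '", rec$device_id, "'; using identity model")
  identity_calibration(fitted_at = rec$start_time)
}

#' Read a calibration registry from JSON
#'
#' The registry maps `device_id` to a chronological list of models, each
#' with `fitted_at`, `offset`, `gain`, optional `temp_coeff` and
#' `mean_temp_c`, `rmse_after_mg` and `source`.
#'
#' @param path JSON registry path.
#' @return Named list of lists of `calibration_model`s; empty list if the
#'   file does not exist.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) return(list())
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(entries) lapply(entries, function(e) {
    new_calibration_model(
      offset = as.numeric(unlist(e$offset)),
      gain = as.numeric(unlist(e$gain)),
      temp_coeff = if (!is.null(e$temp_coeff))
        as.numeric(unlist(e$temp_coeff)),
      mean_temp_c = e$mean_temp_c %||% NA_real_,
      rmse_before_mg = e$rmse_before_mg %||% NA_real_,
      rmse_after_mg = e$rmse_after_mg %||% NA_real_,
      n_windows = e$n_windows %||% 0L,
      source = e$source %||% "self",
      fitted_at = parse_iso(e$fitted_at))
  }))
}

#' Write a calibration registry to JSON
#'
#' @param registry Named list as returned by [read_registry()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  ser <- lapply(registry, function(entries) lapply(entries, function(m) {
    list(fitted_at = fmt_iso(as.POSIXct(m$fitted_at, origin = "1970-01-01",
                                        tz = "UTC"), 0L),
         offset = m$offset, gain = m$gain, temp_coeff = m$temp_coeff,
         mean_temp_c = m$mean_temp_c, rmse_before_mg = m$rmse_before_mg,
         rmse_after_mg = m$rmse_after_mg, n_windows = m$n_windows,
         source = m$source)
  }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Append a model to a registry
#'
#' Entries for each device are kept sorted by `fitted_at`.
#'
#' @param registry Named list registry.
#' @param device_id Device the model belongs to.
#' @param model A `calibration_model`.
#' @return The updated registry.
#' @export
add_to_registry <- function(registry, device_id, model) {
  entries <- c(registry[[device_id]], list(model))
  at <- vapply(entries, function(m) as.numeric(as.POSIXct(m$fitted_at)),
               numeric(1))
  registry[[device_id]] <- entries[order(at)]
  registry
}
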