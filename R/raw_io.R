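# Raw-recording container and on-disk formats.
#
# All acceleration is stored in g in memory and on disk; summaries report mg.
# Timestamps on disk are ISO-8601 with a numeric UTC offset; in memory they
# are POSIXct in UTC plus a stored local offset, because every time-of-day
# construct (epoch alignment, imputation slots, hourly coverage, quadrants)
# is a wall-clock phenomenon.

AXES <- c("x", "y", "z")

fmt_offset <- function(offset_s) {
  sgn <- if (offset_s < 0) "-" else "+"
  a <- abs(as.integer(offset_s))
  sprintf("%s%02d%02d", sgn, a %/% 3600L, (a %% 3600L) %/% 60L)
}

parse_offset <- function(stamp) {
  # accepts ...+0100, ...+01:00 or ...Z
  if (grepl("Z$", stamp)) return(0L)
  m <- regmatches(stamp, regexpr("[+-][0-9]{2}:?[0-9]{2}$", stamp))
  if (!length(m)) return(0L)
  m <- gsub(":", "", m)
  sgn <- if (substr(m, 1, 1) == "-") -1L else 1L
  sgn * (as.integer(substr(m, 2, 3)) * 3600L + as.integer(substr(m, 4, 5)) * 60L)
}

fmt_iso <- function(t_utc, offset_s) {
  # millisecond precision, rendered in local clock time with explicit offset
  tt <- as.POSIXct(round(as.numeric(t_utc) * 1e3) / 1e3,
                   origin = "1970-01-01", tz = "UTC")
  paste0(format(tt + offset_s, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
         fmt_offset(offset_s))
}

parse_iso <- function(stamps) {
  s <- sub("Z$", "+0000", stamps)
  s <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", s)
  as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
}

#' Construct a raw triaxial recording
#'
#' Values beyond the sensor dynamic range are clamped to `+-clip_limit_g`
#' and counted as clips (a clipped reading is flagged, not dropped).
#'
#' @param time POSIXct (UTC), strictly increasing.
#' @param x,y,z Numeric acceleration per axis, in g.
#' @param temperature Optional per-sample temperature (degrees C).
#' @param device_id Device identifier string.
#' @param nominal_rate_hz Nominal sampling rate (Hz).
#' @param utc_offset_s Local-clock offset from UTC in seconds; all
#'   time-of-day logic downstream uses local time.
#' @param config A [pipeline_config()].
#' @param error_readings Count of unreadable/non-finite source rows already
#'   dropped upstream (bookkeeping only).
#' @return An object of class `raw_recording`: a list with `device_id`,
#'   `start_time`, `utc_offset_s`, `nominal_rate_hz`, `duration_days`,
#'   `data` (a `data.table` with columns `time`, `x`, `y`, `z` and
#'   optionally `temperature`) and `quality` (clip/interrupt/error counts).
#' @export
raw_recording <- function(time, x, y, z, temperature = NULL,
                          device_id = "unknown", nominal_rate_hz = 100,
                          utc_offset_s = 0L, config = pipeline_config(),
                          error_readings = 0L) {
  n <- length(time)
  stopifnot(length(x) == n, length(y) == n, length(z) == n,
            nominal_rate_hz > 0)
  if (n == 0L) stop("raw_recording: empty recording")
  dt_num <- diff(as.numeric(time))
  if (any(dt_num <= 0)) {
    bad <- which(dt_num <= 0)[1L] + 1L
    stop("raw_recording: timestamps not strictly increasing at row ", bad)
  }
  dat <- data.table(time = time, x = as.numeric(x), y = as.numeric(y),
                    z = as.numeric(z))
  if (!is.null(temperature)) dat[, temperature := as.numeric(temperature)]
  lim <- config$clip_limit_g
  clipped <- dat$x >= lim | dat$x <= -lim | dat$y >= lim | dat$y <= -lim |
    dat$z >= lim | dat$z <= -lim
  for (a in AXES) set(dat, j = a, value = pmin(pmax(dat[[a]], -lim), lim))
  rec <- list(
    device_id = device_id,
    start_time = time[1L],
    utc_offset_s = as.integer(utc_offset_s),
    nominal_rate_hz = nominal_rate_hz,
    duration_days = (as.numeric(time[n]) - as.numeric(time[1L])) / 86400,
    data = dat,
    quality = list(n_samples = n,
                   clips_before_calib = sum(clipped),
                   clips_after_calib = NA_integer_,
                   interrupts = NA_integer_,
                   error_readings = as.integer(error_readings))
  )
  structure(rec, class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  q <- x$quality
  cat(sprintf(
    "<raw_recording> device %s: %d samples @ %g Hz nominal, %.2f days\n",
    x$device_id, q$n_samples, x$nominal_rate_hz, x$duration_days))
  cat(sprintf("  start %s (UTC offset %+d s)\n",
              format(x$start_time, "%Y-%m-%d %H:%M:%OS2", tz = "UTC"),
              x$utc_offset_s))
  cat(sprintf("  clips before/after calibration: %s / %s; errors: %d\n",
              q$clips_before_calib, q$clips_after_calib, q$error_readings))
  invisible(x)
}

#' Read a raw acceleration CSV
#'
#' Expects a header `time,x,y,z` with optional `temperature`; acceleration
#' in g; timestamps ISO-8601 with offset. Gzipped files are detected by the
#' `.gz` extension. Rows with unparseable timestamps or non-finite
#' acceleration are dropped and counted as error readings; values beyond
#' the dynamic range are clamped and counted as clips.
#'
#' @param path CSV or CSV.gz file.
#' @param config A [pipeline_config()].
#' @param device_id Device id; defaults to the file name stem.
#' @param nominal_rate_hz Nominal sampling rate (Hz); when `NULL` it is
#'   inferred from the median sample spacing.
#' @return A [raw_recording()].
#' @export
read_raw_csv <- function(path, config = pipeline_config(),
                         device_id = NULL, nominal_rate_hz = NULL) {
  if (!file.exists(path)) stop("read_raw_csv: no such file: ", path)
  dat <- fread_maybe_gz(path, colClasses = list(character = "time"))
  need <- c("time", AXES)
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop("read_raw_csv: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  offset_s <- parse_offset(dat$time[1L])
  tm <- parse_iso(dat$time)
  ok <- !is.na(tm) & is.finite(dat$x) & is.finite(dat$y) & is.finite(dat$z)
  n_err <- sum(!ok)
  if (!all(ok)) {
    dat <- dat[ok]
    tm <- tm[ok]
  }
  if (nrow(dat) == 0L) stop("read_raw_csv: no valid rows in ", path)
  dtm <- diff(as.numeric(tm))
  if (any(dtm <= 0)) {
    bad <- which(dtm <= 0)[1L] + 1L
    stop("read_raw_csv: timestamps not strictly increasing at row ", bad)
  }
  if (is.null(nominal_rate_hz)) {
    est <- 1 / median(dtm)
    # snap to an integer rate when within rounding slack of one
    nominal_rate_hz <- if (abs(est - round(est)) / est < 0.05) round(est)
                       else signif(est, 6)
  }
  raw_recording(
    time = tm, x = dat$x, y = dat$y, z = dat$z,
    temperature = if ("temperature" %in% names(dat)) dat$temperature,
    device_id = device_id %||%
      sub("\\.csv(\\.gz)?$", "", basename(path)),
    nominal_rate_hz = nominal_rate_hz,
    utc_offset_s = offset_s, config = config, error_readings = n_err)
}

#' Write a raw recording to CSV
#'
#' Inverse of [read_raw_csv()]; timestamps are written in local clock time
#' with the recording's UTC offset at millisecond precision.
#'
#' @param rec A [raw_recording()].
#' @param path Output path; `.gz` suffix gives gzip compression.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  out <- copy(rec$data)
  out[, time := fmt_iso(time, rec$utc_offset_s)]
  fwrite(out, path, compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Write an epoch series to CSV
#'
#' Columns: `epoch_start` (ISO-8601 local with offset), `vm_mg`,
#' `wear_flag`, `imputed_flag`, plus `fallback_flag` and `valid_fraction`
#' so the series round-trips exactly through [read_epochs()].
#'
#' @param series An `epoch_series` (see [make_epochs()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"), nrow(series) > 0L)
  off <- attr(series, "utc_offset_s")
  out <- data.table(
    epoch_start = fmt_iso(series$start, off),
    vm_mg = series$vm_mg,
    wear_flag = as.integer(series$wear),
    imputed_flag = as.integer(series$imputed),
    fallback_flag = as.integer(series$fallback),
    valid_fraction = series$valid_fraction)
  fwrite(out, path)
  invisible(path)
}

#' Read an epoch series written by [write_epochs()]
#'
#' @param path Epoch CSV path.
#' @param epoch_s Epoch length in seconds (must match the writer's).
#' @return An `epoch_series`.
#' @export
read_epochs <- function(path, epoch_s = 5) {
  if (!file.exists(path)) stop("read_epochs: no such file: ", path)
  dat <- fread(path, colClasses = list(character = "epoch_start"))
  need <- c("epoch_start", "vm_mg", "wear_flag", "imputed_flag")
  if (length(setdiff(need, names(dat))))
    stop("read_epochs: missing required column(s)")
  off <- parse_offset(dat$epoch_start[1L])
  es <- data.table(
    start = parse_iso(dat$epoch_start),
    vm_mg = dat$vm_mg,
    wear = dat$wear_flag == 1L,
    imputed = dat$imputed_flag == 1L,
    fallback = if ("fallback_flag" %in% names(dat))
      dat$fallback_flag == 1L else FALSE,
    valid_fraction = if ("valid_fraction" %in% names(dat))
      dat$valid_fraction else as.numeric(dat$wear_flag))
  as_epoch_series(es, epoch_s = epoch_s, utc_offset_s = off)
}

as_epoch_series <- function(dt, epoch_s, utc_offset_s) {
  setattr(dt, "epoch_s", epoch_s)
  setattr(dt, "utc_offset_s", as.integer(utc_offset_s))
  setattr(dt, "class", c("epoch_series", class(data.table())))
  dt
}

#' Write a participant summary to JSON
#'
#' Units are documented in the key names (mg, hours). Numeric fields
#' round-trip through [read_summary()] at full double precision.
#'
#' @param summary A `participant_summary` (see [summarize_participant()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "participant_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a participant summary written by [write_summary()]
#'
#' @param path JSON path.
#' @return A `participant_summary` list.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop("read_summary: no such file: ", path)
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(s, class = "participant_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gzipped CSVs are decompressed through a base connection so no optional
# helper package is needed on the read side
fread_maybe_gz <- function(path, ...) {
  if (!grepl("\\.gz$", path)) return(fread(path, ...))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  fread(text = readLines(con), ...)
}
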