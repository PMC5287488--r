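# Synthetic raw-data generator with known ground truth.
#
# A participant's week alternates rest bouts (fixed random orientation on
# the unit sphere plus sensor noise) with activity bouts (slow orientation
# random walk plus a rectified band-limited activity component scaled so
# each hour's mean activity hits a target diurnal profile). Because the
# orientation stays on the unit sphere, the vector magnitude is exactly
# 1 + activity and the hourly targets are exact by construction before
# sensor noise. Miscalibration is embedded invertibly (divide by gain,
# add offset), so applying the true model restores unit-norm rest.

#' Default 24-hour activity profile
#'
#' Hourly mean activity targets (mg) shaped like a typical adult wrist
#' week: near-still nights, a morning rise, an afternoon peak and an
#' evening decline. The six-hour quadrant means are 4.4, 38.6, 44.3 and
#' 26.4 mg (overall 28.4 mg), matching large-cohort wrist summaries.
#'
#' @return Numeric vector of 24 hourly means (mg).
#' @export
default_diurnal_profile <- function() {
  c(3, 2, 2, 2, 5, 12.4,
    25, 35, 42, 45, 44, 40.6,
    46, 47, 46, 44, 43, 39.8,
    36, 32, 28, 24, 20, 18.4)
}

#' Simulation scenario
#'
#' Collects every knob of the raw-data generator. Intervals are given in
#' seconds relative to the recording start. Defaults describe a compliant
#' seven-day wrist recording with mild miscalibration and realistic
#' sensor noise.
#'
#' @param seed RNG seed.
#' @param days Recording length (days).
#' @param rate_hz Sampling rate (Hz); 100 for full fidelity, lower for
#'   fast tests.
#' @param start_time Recording start (POSIXct UTC).
#' @param utc_offset_s Local-clock offset (s).
#' @param diurnal_profile 24-vector of target hourly mean activity (mg).
#' @param rest_fraction Fraction of each wear hour spent at rest (a single
#'   mid-hour rest block, so stationary runs never reach the non-wear
#'   threshold).
#' @param offset_mg True per-axis calibration offset embedded in the
#'   stored signal (mg).
#' @param gain True per-axis gain.
#' @param noise_sd_mg Per-axis white sensor noise during wear (mg).
#' @param nonwear_noise_sd_mg Per-axis noise while the device lies still
#'   during non-wear (mg).
#' @param nonwear_intervals List of `c(start_s, end_s)` non-wear intervals.
#' @param interrupt_intervals List of `c(start_s, end_s)` recording gaps
#'   (samples deleted).
#' @param clip_rate Fraction of samples driven beyond the dynamic range.
#' @param device_id Device identifier.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 1L, days = 7, rate_hz = 100,
                         start_time = as.POSIXct("2014-03-10 10:00:00",
                                                 tz = "UTC"),
                         utc_offset_s = 0L,
                         diurnal_profile = default_diurnal_profile(),
                         rest_fraction = 0.5,
                         offset_mg = c(20, -15, 10),
                         gain = c(1.02, 0.98, 1.01),
                         noise_sd_mg = 5,
                         nonwear_noise_sd_mg = 3,
                         nonwear_intervals = list(),
                         interrupt_intervals = list(),
                         clip_rate = 0,
                         device_id = "SIM001") {
  stopifnot(length(diurnal_profile) == 24L, all(diurnal_profile >= 0),
            rest_fraction >= 0, rest_fraction <= 1,
            length(offset_mg) == 3L, length(gain) == 3L, all(gain > 0),
            days > 0, rate_hz > 0, clip_rate >= 0, clip_rate < 1)
  structure(as.list(environment()), class = "sim_scenario")
}

in_intervals <- function(t_rel, intervals) {
  out <- rep(FALSE, length(t_rel))
  for (iv in intervals) out <- out | (t_rel >= iv[1] & t_rel < iv[2])
  out
}

angles_to_xyz <- function(theta, phi) {
  st <- sin(theta)
  cbind(st * cos(phi), st * sin(phi), cos(theta))
}

#' Simulate one participant's raw recording
#'
#' See the package vignette for the generative model. Returns the stored
#' (miscalibrated, clipped, interrupted) recording plus the ground truth
#' needed for recovery tests: the embedded calibration parameters, the
#' injected non-wear intervals, and the intended overall and hourly
#' activity means.
#'
#' @param scenario A [sim_scenario()].
#' @param config A [pipeline_config()] (supplies the clip limit).
#' @return List with `recording` (a [raw_recording()]) and `truth` (list:
#'   `true_offset` (g), `true_gain`, `true_nonwear` (`data.table` of
#'   POSIXct `start`/`end`), `true_overall_mean_mg`, `true_hourly_mg`).
#' @export
simulate_participant <- function(scenario = sim_scenario(),
                                 config = pipeline_config()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  rate <- sc$rate_hz
  n <- round(sc$days * 86400 * rate)
  t_rel <- (seq_len(n) - 1L) / rate
  t0_local <- as.numeric(sc$start_time) + sc$utc_offset_s
  tl <- t0_local + t_rel
  hour <- as.integer(floor(tl / 3600) %% 24L)
  hour_id <- floor(tl / 3600)           # absolute hour for per-hour scaling
  pos_in_hour <- tl %% 3600

  rf <- sc$rest_fraction
  rest <- pos_in_hour >= (1 - rf) / 2 * 3600 &
    pos_in_hour < (1 + rf) / 2 * 3600
  nonwear <- in_intervals(t_rel, sc$nonwear_intervals)
  active <- !rest & !nonwear

  # orientation: smooth angle random walk during activity, frozen during
  # rest bouts and non-wear (unit norm throughout, so VM = 1 + activity)
  ang_step <- 0.002 * sqrt(100 / rate)
  theta <- cumsum(rnorm(n, 0, ang_step)) + runif(1, 0, pi)
  phi <- cumsum(rnorm(n, 0, ang_step)) + runif(1, 0, 2 * pi)
  freeze_id <- ifelse(rest & !nonwear, hour_id, NA_real_)
  # each hour's rest bout holds the angles of its first sample
  nz <- which(!is.na(freeze_id))
  if (length(nz)) {
    grp <- data.table(i = nz, id = freeze_id[nz])
    firsts <- grp[, .(i0 = i[1L]), by = id]
    grp[firsts, on = "id", i0 := i.i0]
    theta[nz] <- theta[grp$i0]
    phi[nz] <- phi[grp$i0]
  }
  # one fixed orientation per whole non-wear interval
  for (iv in sc$nonwear_intervals) {
    idx <- which(t_rel >= iv[1] & t_rel < iv[2])
    if (length(idx)) {
      theta[idx] <- runif(1, 0, pi)
      phi[idx] <- runif(1, 0, 2 * pi)
    }
  }

  # band-limited activity component, rescaled per absolute hour so the
  # realized hourly mean over wear time equals the diurnal target exactly
  a <- numeric(n)
  if (any(active) && rf < 1) {
    hi <- min(10, 0.8 * rate / 2)
    bf <- signal::butter(4, c(0.5, hi) / (rate / 2), type = "pass")
    b <- abs(zerophase_filter(rnorm(n), bf$b, bf$a, 0))
    targ <- sc$diurnal_profile[hour + 1L] / 1000 / (1 - rf)
    dtb <- data.table(i = which(active), b = b[active],
                      hid = hour_id[active], targ = targ[active])
    dtb[, a := b * (targ[1L] / mean(b)), by = hid]
    a[dtb$i] <- dtb$a
  }

  eps_sd <- ifelse(nonwear, sc$nonwear_noise_sd_mg, sc$noise_sd_mg) / 1000
  u <- angles_to_xyz(theta, phi)
  acc <- u * (1 + a) + matrix(rnorm(3 * n, 0, rep(eps_sd, 3L)), n, 3L)

  # embed miscalibration invertibly: stored = true / gain + offset
  off_g <- sc$offset_mg / 1000
  for (j in 1:3) acc[, j] <- acc[, j] / sc$gain[j] + off_g[j]

  if (sc$clip_rate > 0) {
    n_clip <- round(sc$clip_rate * n)
    if (n_clip > 0) {
      ci <- sample.int(n, n_clip)
      cj <- sample.int(3L, n_clip, replace = TRUE)
      acc[cbind(ci, cj)] <- sample(c(-1, 1), n_clip, replace = TRUE) *
        (config$clip_limit_g + 0.5)
    }
  }

  keep <- !in_intervals(t_rel, sc$interrupt_intervals)
  tm <- sc$start_time + t_rel
  rec <- raw_recording(
    time = tm[keep], x = acc[keep, 1L], y = acc[keep, 2L],
    z = acc[keep, 3L], device_id = sc$device_id,
    nominal_rate_hz = rate, utc_offset_s = sc$utc_offset_s,
    config = config)

  wearable <- rf < 1
  truth <- list(
    true_offset = off_g,
    true_gain = sc$gain,
    true_nonwear = if (length(sc$nonwear_intervals)) data.table(
      start = sc$start_time + vapply(sc$nonwear_intervals, `[`, 0, 1L),
      end = sc$start_time + vapply(sc$nonwear_intervals, `[`, 0, 2L))
      else data.table(start = as.POSIXct(numeric(), origin = "1970-01-01",
                                         tz = "UTC"),
                      end = as.POSIXct(numeric(), origin = "1970-01-01",
                                       tz = "UTC")),
    true_overall_mean_mg = if (wearable) mean(sc$diurnal_profile) else 0,
    true_hourly_mg = if (wearable) sc$diurnal_profile else rep(0, 24),
    scenario = sc)
  list(recording = rec, truth = truth)
}

STRATUM_MEAN_MG <- c("45-54" = 31, "55-64" = 29, "65-74" = 26.5,
                     "75-79" = 23.5)
STRATUM_SD_MG <- 8

#' Simulate a cohort of raw recordings
#'
#' Per-participant overall activity is drawn from age-band-specific normal
#' distributions (means 31 / 29 / 26.5 / 23.5 mg for bands 45-54 through
#' 75-79, SD 8 mg), and the diurnal profile is scaled to match. Output is
#' reproducible under a fixed seed.
#'
#' @param n Number of participants.
#' @param seed RNG seed.
#' @param days,rate_hz Recording length and rate passed to each scenario.
#' @param config A [pipeline_config()].
#' @param ... Further [sim_scenario()] overrides applied to everyone.
#' @return List of `n` elements, each `list(recording, truth, meta)` where
#'   `meta` has `participant_id`, `sex`, `age`, `age_band` and the drawn
#'   `target_mean_mg`.
#' @export
simulate_cohort <- function(n, seed = 1L, days = 7, rate_hz = 100,
                            config = pipeline_config(), ...) {
  stopifnot(n >= 1)
  set.seed(seed)
  ages <- sample(45:79, n, replace = TRUE)
  sexes <- sample(c("F", "M"), n, replace = TRUE)
  bands <- as.character(age_band_of(ages))
  targets <- pmax(5, rnorm(n, STRATUM_MEAN_MG[bands], STRATUM_SD_MG))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  base_profile <- default_diurnal_profile()
  lapply(seq_len(n), function(i) {
    profile <- base_profile * targets[i] / mean(base_profile)
    sc <- sim_scenario(seed = seeds[i], days = days, rate_hz = rate_hz,
                       diurnal_profile = profile,
                       device_id = sprintf("SIMDEV%02d", (i %% 7L) + 1L),
                       ...)
    sim <- simulate_participant(sc, config)
    sim$meta <- list(participant_id = sprintf("P%04d", i), sex = sexes[i],
                     age = ages[i], age_band = bands[i],
                     target_mean_mg = targets[i])
    sim
  })
}

#' Simulate stationary calibration windows with known miscalibration
#'
#' Window-level shortcut for calibration recovery studies: true stationary
#' means are uniform orientations on the unit sphere; the stored means are
#' the invertible miscalibration of the truth plus measurement noise.
#'
#' @param n_windows Number of stationary windows.
#' @param offset_mg True offset (mg, 3-vector).
#' @param gain True gain (3-vector).
#' @param noise_sd_mg Per-axis noise SD on the window means (mg).
#' @param seed RNG seed.
#' @param temperature_range Optional `c(lo, hi)` degrees C; when given,
#'   windows carry temperatures (no temperature effect is embedded).
#' @return A windows `data.table` shaped like [find_stationary_windows()]
#'   output, with the truth attached as attribute `"truth"`.
#' @export
simulate_calibration_windows <- function(n_windows = 150,
                                         offset_mg = c(30, -20, 10),
                                         gain = c(1.03, 0.98, 1.01),
                                         noise_sd_mg = 2, seed = 1L,
                                         temperature_range = NULL) {
  set.seed(seed)
  z <- runif(n_windows, -1, 1)
  phi <- runif(n_windows, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  u <- cbind(r * cos(phi), r * sin(phi), z)
  off_g <- offset_mg / 1000
  stored <- sweep(sweep(u, 2, gain, "/"), 2, off_g, "+") +
    matrix(rnorm(3 * n_windows, 0, noise_sd_mg / 1000), n_windows, 3L)
  out <- data.table(
    widx = seq_len(n_windows) - 1L,
    start = as.POSIXct("2014-03-10 10:00:00", tz = "UTC") +
      (seq_len(n_windows) - 1L) * 10,
    mx = stored[, 1L], my = stored[, 2L], mz = stored[, 3L],
    sdx = noise_sd_mg, sdy = noise_sd_mg, sdz = noise_sd_mg,
    temperature = if (is.null(temperature_range)) NA_real_
      else runif(n_windows, temperature_range[1L], temperature_range[2L]))
  setattr(out, "truth", list(true_offset = off_g, true_gain = gain))
  out[]
}

#' Simulate an epoch-level cohort for reliability studies
#'
#' Generates fully worn epoch series directly at the epoch level (no raw
#' signal), with between-participant level differences, day-to-day
#' multiplicative variation and within-day gamma noise around the diurnal
#' profile. Used for the minimum-wear-time ICC simulation where only
#' epoch-scale structure matters.
#'
#' @param n Number of participants.
#' @param seed RNG seed.
#' @param days Days per participant.
#' @param epoch_s Epoch length (s).
#' @param profile 24-hour mean profile (mg).
#' @param between_sd_mg SD of participant overall levels around the
#'   profile mean (mg).
#' @param day_sd Log-scale SD of day-level multipliers.
#' @param epoch_shape Gamma shape of within-day epoch noise (CV =
#'   `1/sqrt(epoch_shape)`).
#' @param start_time,utc_offset_s Series start and local offset.
#' @return List of `n` `epoch_series`, fully worn, with each participant's
#'   drawn level in attribute `"target_mean_mg"`.
#' @export
simulate_epoch_cohort <- function(n, seed = 1L, days = 7, epoch_s = 5,
                                  profile = default_diurnal_profile(),
                                  between_sd_mg = 8, day_sd = 0.2,
                                  epoch_shape = 4,
                                  start_time = as.POSIXct(
                                    "2014-03-10 00:00:00", tz = "UTC"),
                                  utc_offset_s = 0L) {
  set.seed(seed)
  n_ep <- round(days * 86400 / epoch_s)
  t_rel <- (seq_len(n_ep) - 1L) * epoch_s
  hr <- as.integer(floor((as.numeric(start_time) + utc_offset_s + t_rel) /
                           3600) %% 24L)
  dayi <- floor(t_rel / 86400) + 1L
  levels_ <- pmax(5, rnorm(n, mean(profile), between_sd_mg))
  lapply(seq_len(n), function(i) {
    daymult <- exp(rnorm(ceiling(days), 0, day_sd) - day_sd^2 / 2)
    mu <- profile[hr + 1L] * (levels_[i] / mean(profile)) * daymult[dayi]
    vm <- rgamma(n_ep, shape = epoch_shape, rate = epoch_shape / mu)
    es <- data.table(start = start_time + t_rel, vm_mg = vm, wear = TRUE,
                     imputed = FALSE, fallback = FALSE, valid_fraction = 1)
    es <- as_epoch_series(es, epoch_s, utc_offset_s)
    setattr(es, "target_mean_mg", levels_[i])
    es
  })
}
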