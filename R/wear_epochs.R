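# Epoch aggregation, non-wear detection and diurnal imputation.
#
# Epochs are aligned to wall-clock (local) 5-s boundaries from midnight.
# Non-wear is a run of consecutive stationary 10-s windows lasting at
# least 60 minutes; such time is removed and refilled with the average of
# worn data at the same minute of day on the other measurement days, which
# corrects the diurnal bias a worn-only average would carry (the device is
# typically off at night, so a worn-only mean overestimates).

#' Aggregate an activity signal into epochs
#'
#' Epochs (5 s by default) are aligned to local wall-clock boundaries from
#' midnight; partial first/last epochs are dropped. Each epoch carries the
#' mean over its non-missing samples and the fraction of valid samples;
#' epochs with no valid samples get `vm_mg = NA` and start as non-wear.
#'
#' @param activity_signal Scalar `uniform_signal` in mg (see
#'   [remove_gravity()]).
#' @param config A [pipeline_config()].
#' @return An `epoch_series`: a `data.table` with columns `start` (POSIXct
#'   UTC; attribute `utc_offset_s` holds the local offset), `vm_mg`,
#'   `wear`, `imputed`, `fallback`, `valid_fraction`, and attribute
#'   `epoch_s`.
#' @export
make_epochs <- function(activity_signal, config = pipeline_config()) {
  stopifnot(inherits(activity_signal, "uniform_signal"),
            !is.matrix(activity_signal$values))
  ep_s <- config$epoch_s
  rate <- activity_signal$rate_hz
  per_epoch <- round(rate * ep_s)
  off <- activity_signal$utc_offset_s
  n <- length(activity_signal$values)
  t_local <- (as.numeric(activity_signal$start) + off) +
    (seq_len(n) - 1L) / rate
  dt <- data.table(eidx = floor(t_local / ep_s),
                   v = activity_signal$values)
  agg <- dt[, .(n_total = .N, n_valid = sum(!is.na(v)),
                vm_mg = if (any(!is.na(v))) mean(v, na.rm = TRUE)
                        else NA_real_),
            by = eidx]
  agg <- agg[n_total == per_epoch]  # drop partial boundary epochs
  setorder(agg, eidx)
  es <- agg[, .(
    start = as.POSIXct(eidx * ep_s - off, origin = "1970-01-01", tz = "UTC"),
    vm_mg,
    wear = n_valid > 0L,
    imputed = FALSE,
    fallback = FALSE,
    valid_fraction = n_valid / n_total)]
  as_epoch_series(es, epoch_s = ep_s, utc_offset_s = off)
}

#' Detect non-wear episodes from stationary windows
#'
#' Maximal runs of consecutive (gap-free) stationary windows spanning at
#' least `nonwear_min_minutes` (60 by default, boundary inclusive) become
#' non-wear episodes; shorter stationary runs are ordinary rest.
#'
#' @param stationary_windows Output of [find_stationary_windows()] on the
#'   calibrated recording.
#' @param config A [pipeline_config()].
#' @return `data.table` of half-open episodes: `start`, `end` (POSIXct),
#'   `duration_min`; zero rows when none qualify.
#' @export
detect_nonwear <- function(stationary_windows, config = pipeline_config()) {
  win_s <- config$stationary_window_s
  empty <- data.table(start = as.POSIXct(numeric(), origin = "1970-01-01",
                                         tz = "UTC"),
                      end = as.POSIXct(numeric(), origin = "1970-01-01",
                                       tz = "UTC"),
                      duration_min = numeric())
  if (nrow(stationary_windows) == 0L) return(empty)
  w <- sort(stationary_windows$widx)
  run_id <- cumsum(c(1L, diff(w) != 1L))
  t0 <- as.numeric(stationary_windows$start[1L]) -
    stationary_windows$widx[1L] * win_s
  runs <- data.table(widx = w, run = run_id)[
    , .(first = widx[1L], len = .N), by = run]
  runs[, duration_min := len * win_s / 60]
  runs <- runs[duration_min >= config$nonwear_min_minutes]
  if (nrow(runs) == 0L) return(empty)
  out <- runs[, .(
    start = as.POSIXct(t0 + first * win_s, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(t0 + (first + len) * win_s, origin = "1970-01-01",
                     tz = "UTC"),
    duration_min)]
  setorder(out, start)
  out[]
}

#' Flag epochs overlapping non-wear episodes
#'
#' Epochs overlapping any episode are marked `wear = FALSE`; all other
#' epochs with at least one valid sample are worn.
#'
#' @param epochs An `epoch_series`.
#' @param episodes Sorted, non-overlapping episodes from
#'   [detect_nonwear()].
#' @return The flagged `epoch_series` (a new object).
#' @export
flag_wear <- function(epochs, episodes) {
  stopifnot(inherits(epochs, "epoch_series"))
  ep_s <- attr(epochs, "epoch_s")
  es <- copy(epochs)
  es[, wear := valid_fraction > 0]
  if (!is.null(episodes) && nrow(episodes)) {
    s <- as.numeric(es$start)
    for (j in seq_len(nrow(episodes))) {
      a <- as.numeric(episodes$start[j]); b <- as.numeric(episodes$end[j])
      es[s < b & (s + ep_s) > a, wear := FALSE]
    }
  }
  as_epoch_series(es, ep_s, attr(epochs, "utc_offset_s"))
}

# local-time helpers on an epoch series
epoch_local_num <- function(epochs) {
  as.numeric(epochs$start) + attr(epochs, "utc_offset_s")
}
epoch_slot_day <- function(epochs, slot_min) {
  tl <- epoch_local_num(epochs)
  list(slot = (floor(tl / 60) %% 1440L) %/% slot_min,
       day = floor(tl / 86400))
}

#' Impute non-wear and missing epochs from other days
#'
#' Every non-worn epoch is refilled with the mean worn value observed in
#' the same time-of-day slot (1 min granularity by default) on the other
#' measurement days. When a slot is worn on no other day, the pool is
#' widened to +-`impute_widen_min` minutes around the slot (still other
#' days only); if still empty, the participant's overall worn mean is
#' used. Epochs filled by either fallback are flagged `fallback = TRUE`.
#' Worn epochs are never touched.
#'
#' @param epochs A wear-flagged `epoch_series` (see [flag_wear()]).
#' @param config A [pipeline_config()].
#' @return The imputed `epoch_series`.
#' @export
impute_nonwear <- function(epochs, config = pipeline_config()) {
  stopifnot(inherits(epochs, "epoch_series"))
  es <- copy(epochs)
  if (!any(es$wear)) stop("impute_nonwear: no worn epochs to impute from")
  slot_min <- config$impute_granularity_min
  sd_ <- epoch_slot_day(es, slot_min)
  es[, `:=`(slot = sd_$slot, day = sd_$day)]
  per_day <- es[wear == TRUE,
                .(s_worn = sum(vm_mg), n_worn = .N), by = .(slot, day)]
  per_slot <- per_day[, .(tot_s = sum(s_worn), tot_n = sum(n_worn)),
                      by = slot]
  es[per_slot, `:=`(tot_s = i.tot_s, tot_n = i.tot_n), on = "slot"]
  es[per_day, `:=`(s_worn = i.s_worn, n_worn = i.n_worn),
     on = c("slot", "day")]
  es[is.na(tot_s), `:=`(tot_s = 0, tot_n = 0L)]
  es[is.na(s_worn), `:=`(s_worn = 0, n_worn = 0L)]
  overall_worn <- es[wear == TRUE, mean(vm_mg)]
  targ <- which(!es$wear)
  oth_n <- es$tot_n[targ] - es$n_worn[targ]
  oth_mean <- ifelse(oth_n > 0,
                     (es$tot_s[targ] - es$s_worn[targ]) / oth_n, NA_real_)
  fb <- is.na(oth_mean)
  if (any(fb)) {
    n_slots <- (1440L %/% slot_min)
    half <- ceiling(config$impute_widen_min / slot_min)
    worn <- es[wear == TRUE, .(slot, day, vm_mg)]
    need <- unique(data.table(slot = es$slot[targ][fb],
                              day = es$day[targ][fb]))
    wide <- vapply(seq_len(nrow(need)), function(k) {
      ring <- (need$slot[k] + (-half:half)) %% n_slots
      pool <- worn[slot %in% ring & day != need$day[k], vm_mg]
      if (length(pool)) mean(pool) else NA_real_
    }, numeric(1))
    need[, value := wide]
    idx <- match(paste(es$slot[targ][fb], es$day[targ][fb]),
                 paste(need$slot, need$day))
    oth_mean[fb] <- need$value[idx]
    oth_mean[is.na(oth_mean)] <- overall_worn
  }
  es[targ, `:=`(vm_mg = oth_mean, imputed = TRUE, fallback = fb)]
  es[, c("slot", "day", "tot_s", "tot_n", "s_worn", "n_worn") := NULL]
  as_epoch_series(es, attr(epochs, "epoch_s"), attr(epochs, "utc_offset_s"))
}

#' Intensity distribution of epoch activity
#'
#' Cumulative hours spent at or below each breakpoint of the mg grid
#' (0, 5, ..., 2000 by default), over worn plus imputed epochs (worn only
#' when `config$ecdf_include_imputed` is `FALSE`). Epochs above the top
#' breakpoint are top-coded into the final bin so the curve saturates at
#' the total measured-plus-imputed time.
#'
#' @param epochs A flagged (and normally imputed) `epoch_series`.
#' @param config A [pipeline_config()].
#' @return List of class `intensity_ecdf` with `grid_mg` and `cum_time_h`.
#' @export
intensity_ecdf <- function(epochs, config = pipeline_config()) {
  stopifnot(inherits(epochs, "epoch_series"))
  use <- if (config$ecdf_include_imputed) epochs$wear | epochs$imputed
         else epochs$wear
  v <- epochs$vm_mg[use]
  grid <- ecdf_grid(config)
  ep_h <- attr(epochs, "epoch_s") / 3600
  cum <- if (length(v)) {
    f <- stats::ecdf(v)
    ct <- f(grid) * length(v) * ep_h
    ct[length(ct)] <- length(v) * ep_h  # top-code beyond the grid
    ct
  } else rep(0, length(grid))
  structure(list(grid_mg = grid, cum_time_h = cum),
            class = "intensity_ecdf")
}

#' Overall activity outcome
#'
#' The single summary exposure: mean epoch activity over all worn and
#' imputed epochs, in mg.
#'
#' @param epochs An imputed `epoch_series`.
#' @return Scalar mean vector magnitude (mg).
#' @export
overall_outcome <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_series"))
  use <- (epochs$wear | epochs$imputed) & !is.na(epochs$vm_mg)
  if (!any(use)) stop("overall_outcome: no usable (worn or imputed) epochs")
  mean(epochs$vm_mg[use])
}

#' Wear-time inclusion rule
#'
#' A participant is included when pre-imputation wear time reaches
#' `min_wear_h` (72 h) and every hour-of-day bin contains at least one
#' worn epoch on some day.
#'
#' @param epochs A wear-flagged `epoch_series` (imputation irrelevant:
#'   only `wear` counts).
#' @param config A [pipeline_config()].
#' @return List of class `inclusion_result`: `included`, `wear_hours`,
#'   `covered_hour_bins`, `reason`.
#' @export
check_inclusion <- function(epochs, config = pipeline_config()) {
  stopifnot(inherits(epochs, "epoch_series"))
  ep_s <- attr(epochs, "epoch_s")
  worn <- epochs$wear
  wear_hours <- sum(worn) * ep_s / 3600
  tl <- epoch_local_num(epochs)[worn]
  bins <- length(unique((floor(tl / 3600) %% 24L)))
  reasons <- character()
  if (wear_hours < config$min_wear_h)
    reasons <- c(reasons, sprintf("<%gh wear (%.2f h)",
                                  config$min_wear_h, wear_hours))
  if (bins < config$hourly_coverage_bins)
    reasons <- c(reasons, sprintf(
      "wear data in only %d of %d hour-of-day bins",
      bins, config$hourly_coverage_bins))
  structure(list(
    included = length(reasons) == 0L,
    wear_hours = wear_hours,
    covered_hour_bins = bins,
    reason = if (length(reasons)) paste(reasons, collapse = "; ") else "ok"),
    class = "inclusion_result")
}
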