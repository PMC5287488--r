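# Participant- and cohort-level descriptive summaries, effect sizes, and
# the minimum-wear-time reliability simulation.

season_of <- function(date) {
  # meteorological seasons, Spring starting 1 March
  m <- as.integer(format(date, "%m"))
  c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer", "Summer",
    "Summer", "Autumn", "Autumn", "Autumn", "Winter")[m]
}

#' Summarise a participant's epoch series
#'
#' Profile statistics (overall, hourly, six-hour quadrant, weekday/weekend)
#' are computed over worn plus imputed epochs; wear time and the inclusion
#' decision use worn epochs only. Season is assigned from the first worn
#' day's local date with meteorological boundaries (Spring = 1 March).
#'
#' @param epochs An imputed `epoch_series`.
#' @param meta List with at least `participant_id`; optional `sex`, `age`.
#' @param config A [pipeline_config()].
#' @param quality Optional quality-report list carried through from the
#'   raw recording.
#' @return A `participant_summary` list: `participant_id`,
#'   `overall_mean_mg`, `wear_hours`, `hourly_mean_mg` (24),
#'   `quadrant_mean_mg` (4: 00-05:59, 06-11:59, 12-17:59, 18-23:59),
#'   `weekday_mean_mg`, `weekend_mean_mg`, `season`, `included`, `reason`,
#'   `covered_hour_bins`, `ecdf` (grid and cumulative hours), `quality`.
#' @export
summarize_participant <- function(epochs, meta = list(),
                                  config = pipeline_config(),
                                  quality = NULL) {
  stopifnot(inherits(epochs, "epoch_series"))
  incl <- check_inclusion(epochs, config)
  use <- (epochs$wear | epochs$imputed) & !is.na(epochs$vm_mg)
  tl <- epoch_local_num(epochs)
  hr <- floor(tl / 3600) %% 24L
  # local civil date; weekday via the POSIXlt day-of-week of the local day
  day_num <- floor(tl / 86400)
  dow <- as.integer((day_num + 4L) %% 7L)  # 1970-01-01 was a Thursday (4)
  is_weekend <- dow %in% c(6L, 0L)         # Sat, Sun
  v <- epochs$vm_mg
  hourly <- vapply(0:23, function(h) {
    sel <- use & hr == h
    if (any(sel)) mean(v[sel]) else NA_real_
  }, numeric(1))
  quadrant <- vapply(0:3, function(q) {
    sel <- use & (hr %/% 6L) == q
    if (any(sel)) mean(v[sel]) else NA_real_
  }, numeric(1))
  worn_dates <- as.Date(as.POSIXct(tl[epochs$wear], origin = "1970-01-01",
                                   tz = "UTC"))
  season <- if (length(worn_dates)) season_of(min(worn_dates))
            else NA_character_
  structure(list(
    participant_id = meta$participant_id %||% NA_character_,
    sex = meta$sex %||% NA_character_,
    age = meta$age %||% NA_real_,
    overall_mean_mg = if (any(use)) mean(v[use]) else NA_real_,
    wear_hours = incl$wear_hours,
    hourly_mean_mg = hourly,
    quadrant_mean_mg = quadrant,
    weekday_mean_mg = if (any(use & !is_weekend))
      mean(v[use & !is_weekend]) else NA_real_,
    weekend_mean_mg = if (any(use & is_weekend))
      mean(v[use & is_weekend]) else NA_real_,
    season = season,
    included = incl$included,
    reason = incl$reason,
    covered_hour_bins = incl$covered_hour_bins,
    ecdf = unclass(intensity_ecdf(epochs, config)),
    quality = quality),
    class = "participant_summary")
}

#' @export
print.participant_summary <- function(x, ...) {
  cat(sprintf("<participant_summary> %s: %.2f mg overall, %.1f h wear, %s\n",
              x$participant_id, x$overall_mean_mg, x$wear_hours,
              if (isTRUE(x$included)) "included"
              else paste0("excluded (", x$reason, ")")))
  invisible(x)
}

#' Cohen's d standardised mean difference
#'
#' `(mean1 - mean2)` divided by the pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param mean1,sd1,n1 First group mean, SD and size.
#' @param mean2,sd2,n2 Second group mean, SD and size.
#' @return Scalar effect size.
#' @export
#' @examples
#' cohens_d(1, 1, 1000, 0, 1, 1000)  # ~1
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled <= 0) stop("cohens_d: pooled standard deviation is zero")
  (mean1 - mean2) / pooled
}

AGE_BANDS <- c("45-54", "55-64", "65-74", "75-79")

age_band_of <- function(age) {
  cut(age, breaks = c(45, 55, 65, 75, 80), labels = AGE_BANDS,
      right = FALSE, include.lowest = TRUE)
}

#' Cohort descriptive table and effect sizes
#'
#' Wear-time medians/IQRs and activity mean/SD per sex-by-age-band
#' stratum, over included participants, plus Cohen's d effect sizes for
#' sex within each band and for adjacent age bands within each sex.
#'
#' @param summaries List of `participant_summary` objects.
#' @param demographics `data.frame` with `participant_id`, `sex`
#'   (`"F"`/`"M"`), `age` (years). May be omitted if the summaries carry
#'   sex and age.
#' @return List of class `cohort_table`: `strata` (a `data.table`) and
#'   `effect_sizes` (a `data.table` of labelled Cohen's d values).
#' @export
cohort_table <- function(summaries, demographics = NULL) {
  dt <- rbindlist(lapply(summaries, function(s) data.table(
    participant_id = as.character(s$participant_id),
    sex = as.character(s$sex %||% NA_character_),
    age = as.numeric(s$age %||% NA_real_),
    overall_mean_mg = as.numeric(s$overall_mean_mg),
    wear_hours = as.numeric(s$wear_hours),
    included = isTRUE(s$included))))
  if (!is.null(demographics)) {
    dem <- as.data.table(demographics)
    dem[, participant_id := as.character(participant_id)]
    dt[dem, `:=`(sex = i.sex, age = i.age), on = "participant_id"]
  }
  dt <- dt[included == TRUE]
  dt[, age_band := age_band_of(age)]
  full <- CJ(sex = c("F", "M"), age_band = factor(AGE_BANDS,
                                                  levels = AGE_BANDS))
  strata <- dt[!is.na(sex) & !is.na(age_band),
               .(n = .N,
                 wear_median_h = median(wear_hours),
                 wear_iqr_lo_h = unname(quantile(wear_hours, 0.25)),
                 wear_iqr_hi_h = unname(quantile(wear_hours, 0.75)),
                 vm_mean_mg = mean(overall_mean_mg),
                 vm_sd_mg = if (.N >= 2) sd(overall_mean_mg) else NA_real_),
               by = .(sex, age_band)]
  strata <- strata[full, on = c("sex", "age_band")]
  strata[is.na(n), n := 0L]
  setorder(strata, sex, age_band)
  eff <- list()
  g <- function(sx, ab) strata[sex == sx & age_band == ab]
  for (ab in AGE_BANDS) {
    a <- g("F", ab); b <- g("M", ab)
    if (a$n >= 2 && b$n >= 2)
      eff[[length(eff) + 1L]] <- data.table(
        comparison = paste0("sex F-M ", ab),
        d = cohens_d(a$vm_mean_mg, a$vm_sd_mg, a$n,
                     b$vm_mean_mg, b$vm_sd_mg, b$n))
  }
  for (sx in c("F", "M")) for (k in seq_len(length(AGE_BANDS) - 1L)) {
    a <- g(sx, AGE_BANDS[k]); b <- g(sx, AGE_BANDS[k + 1L])
    if (a$n >= 2 && b$n >= 2)
      eff[[length(eff) + 1L]] <- data.table(
        comparison = sprintf("age %s-%s %s", AGE_BANDS[k],
                             AGE_BANDS[k + 1L], sx),
        d = cohens_d(a$vm_mean_mg, a$vm_sd_mg, a$n,
                     b$vm_mean_mg, b$vm_sd_mg, b$n))
  }
  structure(list(strata = strata[],
                 effect_sizes = if (length(eff)) rbindlist(eff)
                                else data.table(comparison = character(),
                                                d = numeric())),
            class = "cohort_table")
}

#' Intraclass correlation, two-way random, absolute agreement, single
#' measurement
#'
#' ICC(A,1) from the standard mean-square decomposition of an n x k
#' subjects-by-measurements table. With identical columns the ICC is 1.
#'
#' @param m Numeric matrix, subjects in rows, measurements in columns.
#' @return Scalar ICC in `[-1, 1]`.
#' @export
icc_agreement <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2, k >= 2, all(is.finite(m)))
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < .Machine$double.eps * max(1, abs(msr)))
    return(if (abs(msr - mse) < .Machine$double.eps) NA_real_ else 1)
  (msr - mse) / denom
}

#' Minimum-wear-time reliability curve
#'
#' For each candidate wear duration `h`, random contiguous `h`-hour
#' sub-windows are drawn from each fully compliant participant's week,
#' everything outside the window is marked non-wear, the outcome is
#' recomputed with the usual time-of-day imputation, and the ICC between
#' truncated and full-week outcomes across participants is averaged over
#' replicates. At the full duration the truncated outcome equals the full
#' outcome and the ICC is 1 by construction.
#'
#' @param cohort_epochs List of fully worn `epoch_series` (>= 10).
#' @param hours_grid Durations to evaluate (h).
#' @param n_reps Monte Carlo replicates per duration.
#' @param seed RNG seed.
#' @param config A [pipeline_config()].
#' @return `data.table` of class `reliability_curve`: `hours`, `icc`
#'   (mean over replicates), `mc_se` (SE of that mean).
#' @export
wear_reliability <- function(cohort_epochs,
                             hours_grid = c(24, 48, 72, 96, 120, 144, 168),
                             n_reps = 10L, seed = 1L,
                             config = pipeline_config()) {
  if (length(cohort_epochs) < 10L)
    stop("wear_reliability: need at least 10 fully compliant participants")
  set.seed(seed)
  ep_s <- attr(cohort_epochs[[1L]], "epoch_s")
  full <- vapply(cohort_epochs, overall_outcome, numeric(1))
  total_h <- vapply(cohort_epochs, function(e) nrow(e) * ep_s / 3600,
                    numeric(1))
  rows <- lapply(hours_grid, function(h) {
    iccs <- vapply(seq_len(n_reps), function(rep_) {
      trunc_out <- vapply(seq_along(cohort_epochs), function(i) {
        es <- cohort_epochs[[i]]
        n_ep <- nrow(es)
        keep_n <- min(n_ep, round(h * 3600 / ep_s))
        start_i <- if (keep_n >= n_ep) 1L
                   else sample.int(n_ep - keep_n + 1L, 1L)
        if (keep_n >= n_ep) return(full[i])
        sub <- copy(es)
        out_idx <- setdiff(seq_len(n_ep),
                           seq.int(start_i, start_i + keep_n - 1L))
        sub[out_idx, `:=`(wear = FALSE, imputed = FALSE)]
        sub <- as_epoch_series(sub, ep_s, attr(es, "utc_offset_s"))
        overall_outcome(impute_nonwear(sub, config))
      }, numeric(1))
      icc_agreement(cbind(full, trunc_out))
    }, numeric(1))
    data.table(hours = h, icc = mean(iccs),
               mc_se = if (n_reps > 1) sd(iccs) / sqrt(n_reps) else 0)
  })
  out <- rbindlist(rows)
  setattr(out, "class", c("reliability_curve", class(data.table())))
  out[]
}
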