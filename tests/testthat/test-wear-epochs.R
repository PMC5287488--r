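test_that("epoch aggregation means and alignment are exact", {
  sig <- make_signal(rep(40, 100), rate = 10)  # 10 s at 40 mg
  es <- make_epochs(sig, cfg10)
  expect_equal(nrow(es), 2L)
  expect_equal(es$vm_mg, c(40, 40))
  expect_equal(attr(es, "epoch_s"), 5)

  alt <- make_signal(rep(c(0, 100), 25), rate = 10)  # one epoch
  expect_equal(make_epochs(alt, cfg10)$vm_mg, 50)
})

test_that("partial boundary epochs are dropped and misalignment respected", {
  # start 2 s past an epoch boundary: first partial epoch dropped
  sig <- make_signal(rep(10, 100), rate = 10, start = T0 + 2)
  es <- make_epochs(sig, cfg10)
  expect_equal(nrow(es), 1L)
  expect_equal(as.numeric(es$start[1]) %% 5, 0)
})

test_that("epoch means match an independent groupby oracle", {
  sc <- sim_scenario(seed = 12, days = 0.05, rate_hz = 10)
  sim <- simulate_participant(sc, cfg10)
  sig <- resample_with_gaps(sim$recording, cfg10)
  act <- remove_gravity(lowpass_noise_filter(vector_magnitude(sig), cfg10),
                        "enmo_trunc", cfg10)
  es <- make_epochs(act, cfg10)
  t_local <- as.numeric(act$start) + (seq_along(act$values) - 1) / 10
  grp <- floor(t_local / 5)
  cnt <- tapply(act$values, grp, length)
  mns <- tapply(act$values, grp, mean)
  complete <- as.numeric(names(cnt))[cnt == 50]
  expect_equal(as.numeric(es$start), complete * 5)
  expect_equal(es$vm_mg, as.numeric(mns[as.character(complete)]),
               tolerance = 1e-9)
})

test_that("non-wear needs at least 60 consecutive stationary minutes", {
  mkwin <- function(widx) data.table::data.table(
    widx = widx, start = T0 + widx * 10, mx = 0, my = 0, mz = 1,
    sdx = 1, sdy = 1, sdz = 1, temperature = NA_real_)
  expect_equal(nrow(detect_nonwear(mkwin(0:419), cfg10)), 1L)  # 70 min
  expect_equal(nrow(detect_nonwear(mkwin(0:358), cfg10)), 0L)  # 59.83 min
  ep <- detect_nonwear(mkwin(0:359), cfg10)                    # exactly 60
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_min, 60)
  expect_equal(as.numeric(ep$end - ep$start, units = "mins"), 60)
  # a one-window gap splits the run below threshold
  expect_equal(nrow(detect_nonwear(mkwin(c(0:200, 202:400)), cfg10)), 0L)
})

test_that("wear flagging matches a brute-force interval-overlap oracle", {
  es <- build_epochs(rep(10, 24 * 720))  # one day of 5-s epochs
  flagged <- flag_wear(es, NULL)
  expect_true(all(flagged$wear))

  episodes <- data.table::data.table(
    start = T0 + 2 * 3600, end = T0 + 3 * 3600, duration_min = 60)
  flagged <- flag_wear(es, episodes)
  expect_equal(sum(!flagged$wear), 720L)  # 3600 s / 5 s

  set.seed(13)
  for (rep_ in 1:5) {
    n_ep <- sample(2:5, 1)
    starts <- sort(runif(n_ep, 0, 82800))
    eps <- data.table::data.table(
      start = T0 + starts, end = T0 + starts + runif(n_ep, 600, 7200))
    eps$duration_min <- as.numeric(eps$end - eps$start, units = "mins")
    got <- flag_wear(es, eps)
    s <- as.numeric(es$start); e <- s + 5
    oracle <- rep(TRUE, nrow(es))
    for (i in seq_len(nrow(es)))
      for (j in seq_len(n_ep))
        if (s[i] < as.numeric(eps$end[j]) && e[i] > as.numeric(eps$start[j]))
          oracle[i] <- FALSE
    expect_identical(got$wear, oracle)
  }
})

test_that("imputation fills a slot with the exact other-day worn mean", {
  # three days; minute slot 600-659 s missing on day 3 only
  n_day <- 17280L
  vm <- rep(10, 3 * n_day)
  day <- rep(1:3, each = n_day)
  slot_idx <- (seq_len(3 * n_day) - 1L) %% n_day
  in_slot <- slot_idx >= 120L & slot_idx < 132L  # epochs 600-660 s
  vm[in_slot & day == 1] <- 10
  vm[in_slot & day == 2] <- 20
  wear <- !(in_slot & day == 3)
  es <- build_epochs(vm, wear = wear)
  out <- impute_nonwear(es, cfg10)
  filled <- out[in_slot & day == 3]
  expect_true(all(filled$imputed))
  expect_false(any(filled$fallback))
  expect_equal(filled$vm_mg, rep(15, 12))
  # worn epochs untouched, bitwise
  expect_identical(out$vm_mg[wear], es$vm_mg[wear])
  # conservation: every epoch is worn or imputed afterwards
  expect_equal(sum(out$wear) + sum(out$imputed), nrow(out))
})

test_that("imputation is the identity when everything is worn", {
  es <- build_epochs(runif(2000, 0, 60))
  out <- impute_nonwear(es, cfg10)
  expect_identical(out$vm_mg, es$vm_mg)
  expect_false(any(out$imputed))
})

test_that("fallback pools widen to +-30 min, then the overall worn mean", {
  # two days; slot worn on no day -> widened pool; whole hour missing on
  # both days at 02:00 -> overall-mean fallback for the middle minutes
  n_day <- 17280L
  vm <- rep(30, 2 * n_day)
  slot_idx <- (seq_len(2 * n_day) - 1L) %% n_day
  hr2 <- slot_idx >= 2 * 720L & slot_idx < 3 * 720L
  wear <- !hr2
  es <- build_epochs(vm, wear = wear)
  out <- impute_nonwear(es, cfg10)
  expect_true(all(out$imputed[!wear]))
  expect_true(all(out$fallback[!wear]))
  expect_equal(unique(out$vm_mg[!wear]), 30)
})

test_that("diurnally biased non-wear is corrected by imputation", {
  cohort <- simulate_epoch_cohort(1, seed = 21, days = 7, epoch_s = 60)
  es <- cohort[[1]]
  truth <- mean(es$vm_mg)
  # remove nights (00:00-06:00) on days 2, 4, 6: worn-only mean is biased up
  tl <- as.numeric(es$start)
  hr <- floor(tl / 3600) %% 24
  dayi <- floor((tl - min(tl)) / 86400) + 1
  drop <- hr < 6 & dayi %in% c(2, 4, 6)
  biased <- data.table::copy(es)
  biased[drop, wear := FALSE]
  biased <- wristpa:::as_epoch_series(biased, 60, 0L)
  worn_only <- mean(biased$vm_mg[biased$wear])
  out <- impute_nonwear(biased, pipeline_config(epoch_s = 60))
  imputed_mean <- overall_outcome(out)
  expect_lt(abs(imputed_mean - truth) / truth, 0.02)
  expect_gt(abs(worn_only - truth), abs(imputed_mean - truth))
})

test_that("intensity ECDF counts time at or below each level", {
  cfg <- cfg10
  es <- build_epochs(rep(0, 720))
  e <- intensity_ecdf(es, cfg)
  expect_equal(e$cum_time_h[1], 720 * 5 / 3600)  # all time at 0 mg
  expect_true(all(diff(e$cum_time_h) >= 0))

  es2 <- build_epochs(c(rep(10, 360), rep(100, 360)))
  e2 <- intensity_ecdf(es2, cfg)
  at25 <- e2$cum_time_h[e2$grid_mg == 25]
  expect_equal(at25, 0.5 * 720 * 5 / 3600)
  expect_equal(e2$cum_time_h[length(e2$cum_time_h)], 720 * 5 / 3600)

  # top-coding: values beyond the grid still saturate the final bin
  es3 <- build_epochs(c(rep(10, 100), rep(2500, 10)))
  e3 <- intensity_ecdf(es3, cfg)
  expect_equal(e3$cum_time_h[length(e3$cum_time_h)], 110 * 5 / 3600)
})

test_that("ECDF matches a brute-force counting oracle on simulated epochs", {
  cohort <- simulate_epoch_cohort(1, seed = 22, days = 1, epoch_s = 5)
  es <- cohort[[1]]
  e <- intensity_ecdf(es, cfg10)
  for (b in c(0, 25, 100, 500)) {
    oracle <- sum(es$vm_mg <= b) * 5 / 3600
    expect_equal(e$cum_time_h[e$grid_mg == b], oracle, tolerance = 1e-12)
  }
})

test_that("the overall outcome is the mean of worn and imputed epochs", {
  expect_equal(overall_outcome(build_epochs(rep(30, 100))), 30)
  expect_equal(overall_outcome(build_epochs(c(rep(0, 50), rep(60, 50)))), 30)
  es <- build_epochs(rep(1, 10), wear = FALSE)
  expect_error(overall_outcome(es), "no usable")
})

test_that("inclusion requires 72 worn hours and full hourly coverage", {
  n_week <- 7L * 17280L
  full <- build_epochs(rep(20, n_week))
  incl <- check_inclusion(full, pipeline_config())
  expect_true(incl$included)
  expect_equal(incl$wear_hours, 168)
  expect_equal(incl$covered_hour_bins, 24L)

  # exactly 72.0 h in, 71.99 h out
  wear72 <- seq_len(n_week) <= 72 * 720
  r72 <- check_inclusion(build_epochs(rep(20, n_week), wear = wear72),
                         pipeline_config())
  expect_true(r72$included)
  wear7199 <- seq_len(n_week) <= round(71.99 * 720)
  r7199 <- check_inclusion(build_epochs(rep(20, n_week), wear = wear7199),
                           pipeline_config())
  expect_false(r7199$included)
  expect_match(r7199$reason, "72")

  # full wear except 03:00-03:59 every day: 23 of 24 bins
  tl <- as.numeric(T0) + (seq_len(n_week) - 1) * 5
  not3 <- (floor(tl / 3600) %% 24) != 3
  r23 <- check_inclusion(build_epochs(rep(20, n_week), wear = not3),
                         pipeline_config())
  expect_false(r23$included)
  expect_equal(r23$covered_hour_bins, 23L)
  expect_match(r23$reason, "23 of 24")
})
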