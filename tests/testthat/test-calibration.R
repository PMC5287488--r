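test_that("stationary windows are found in constant data with zero SD", {
  rec <- const_rec(30, c(0, 0, 1))
  w <- find_stationary_windows(rec, cfg10)
  expect_equal(nrow(w), 3L)
  expect_equal(w$mz, rep(1, 3))
  expect_equal(w$sdx + w$sdy + w$sdz, rep(0, 3))
})

test_that("noisy data above the SD threshold yields no stationary windows", {
  rec <- const_rec(30, c(0, 0, 1), noise_sd = 0.020, seed = 1)
  expect_equal(nrow(find_stationary_windows(rec, cfg10)), 0L)
})

test_that("window detection matches a brute-force re-scan", {
  sc <- sim_scenario(seed = 5, days = 0.1, rate_hz = 10, offset_mg = c(0, 0, 0),
                     gain = c(1, 1, 1))
  rec <- simulate_participant(sc, cfg10)$recording
  got <- find_stationary_windows(rec, cfg10)
  # independent O(n*w) oracle: loop over aligned 10-s windows
  t_rel <- as.numeric(rec$data$time) - as.numeric(rec$start_time)
  n_win <- floor(max(t_rel) / 10)
  expected <- 0L
  oracle_idx <- integer()
  for (k in 0:n_win) {
    sel <- t_rel >= k * 10 & t_rel < (k + 1) * 10
    if (sum(sel) != 100) next
    sds <- c(sd(rec$data$x[sel]), sd(rec$data$y[sel]), sd(rec$data$z[sel]))
    if (all(sds * 1000 < 13)) {
      expected <- expected + 1L
      oracle_idx <- c(oracle_idx, k)
    }
  }
  expect_equal(nrow(got), expected)
  expect_equal(got$widx, oracle_idx)
})

test_that("windows containing clipped samples are skipped", {
  rec <- const_rec(30, c(0, 0, 1))
  rec$data$x[55] <- 8  # clip inside the first window
  w <- find_stationary_windows(rec, cfg10)
  expect_equal(nrow(w), 2L)
  expect_false(0L %in% w$widx)
})

test_that("calibratability requires +-300 mg coverage on every axis", {
  near_z <- data.table::data.table(
    widx = 0:9, start = T0 + 0:9 * 10,
    mx = rep(c(0.01, -0.01), 5), my = rep(c(0.02, -0.02), 5),
    mz = rep(c(1, -1), 5), sdx = 1, sdy = 1, sdz = 1,
    temperature = NA_real_)
  expect_false(check_calibratable(near_z)$ok)

  six <- simulate_calibration_windows(60, offset_mg = c(0, 0, 0),
                                      gain = c(1, 1, 1), seed = 2)
  chk <- check_calibratable(six)
  # oracle: direct min/max on the means
  m <- as.matrix(six[, .(mx, my, mz)])
  expect_equal(chk$ok,
               all(apply(m, 2, min) < -0.3) && all(apply(m, 2, max) > 0.3))
  expect_true(chk$ok)
})

test_that("fitting windows already on the unit sphere returns identity", {
  w <- simulate_calibration_windows(80, offset_mg = c(0, 0, 0),
                                    gain = c(1, 1, 1), noise_sd_mg = 0,
                                    seed = 3)
  m <- fit_calibration(w, pipeline_config())
  expect_equal(m$offset, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(m$gain, c(1, 1, 1), tolerance = 1e-6)
  expect_lt(m$rmse_after_mg, 1e-3)
  expect_identical(m$source, "self")
})

test_that("known offset and gain are recovered from noisy windows", {
  w <- simulate_calibration_windows(150, offset_mg = c(30, -20, 10),
                                    gain = c(1.03, 0.98, 1.01),
                                    noise_sd_mg = 2, seed = 4)
  truth <- attr(w, "truth")
  m <- fit_calibration(w, pipeline_config())
  expect_lt(max(abs(m$offset - truth$true_offset)) * 1000, 3)
  expect_lt(max(abs(m$gain - truth$true_gain)), 0.005)
  expect_lt(m$rmse_after_mg, 5)
  expect_lte(m$rmse_after_mg, m$rmse_before_mg)
})

test_that("insufficient orientation range raises an uncalibratable error", {
  two <- data.table::data.table(
    widx = 0:19, start = T0 + 0:19 * 10,
    mx = 0, my = 0, mz = rep(c(1, -1), 10),
    sdx = 1, sdy = 1, sdz = 1, temperature = NA_real_)
  expect_error(fit_calibration(two, pipeline_config()),
               class = "wristpa_uncalibratable")
  expect_error(fit_calibration(two[1:5], pipeline_config()),
               class = "wristpa_uncalibratable")
})

test_that("fit is idempotent and never increases the stationary RMSE", {
  for (dev in 1:20) {
    w <- simulate_calibration_windows(
      100, offset_mg = runif(3, -60, 60), gain = runif(3, 0.95, 1.05),
      noise_sd_mg = 2, seed = 100 + dev)
    m <- fit_calibration(w, pipeline_config())
    expect_lte(m$rmse_after_mg, m$rmse_before_mg)
    # refit the corrected windows: should be the identity to ~noise level
    corr <- data.table::copy(w)
    cm <- as.matrix(corr[, .(mx, my, mz)])
    cm <- sweep(sweep(cm, 2, m$offset, "-"), 2, m$gain, "*")
    corr[, c("mx", "my", "mz") := .(cm[, 1], cm[, 2], cm[, 3])]
    m2 <- fit_calibration(corr, pipeline_config())
    expect_lt(max(abs(m2$offset)) * 1000, 1)
    expect_lt(max(abs(m2$gain - 1)), 1e-3)
  }
})

test_that("temperature coefficients are fitted only when a channel exists", {
  w <- simulate_calibration_windows(120, offset_mg = c(10, 5, -5),
                                    gain = c(1.01, 0.99, 1.0),
                                    noise_sd_mg = 1, seed = 6,
                                    temperature_range = c(15, 30))
  m <- fit_calibration(w, pipeline_config())
  expect_length(m$temp_coeff, 3L)  # 9-parameter model
  expect_lt(max(abs(m$temp_coeff)) * 1000, 1)  # no effect embedded
  w$temperature <- NA_real_
  m2 <- fit_calibration(w, pipeline_config())
  expect_null(m2$temp_coeff)  # 6-parameter model
})

test_that("calibration application is exact arithmetic and re-counts clips", {
  rec <- make_rec(0:1 / 10, x = c(1.1, 0), y = c(0, 0), z = c(0, 1))
  m <- identity_calibration()
  out <- apply_calibration(rec, m, cfg10)
  expect_equal(out$data$x, rec$data$x)
  expect_equal(out$quality$clips_after_calib, 0L)

  m$offset <- c(0.1, 0, 0)
  out <- apply_calibration(rec, m, cfg10)
  expect_equal(out$data$x[1], 1.0)

  # gain pushing a value past the limit is re-clamped and counted
  rec2 <- make_rec(0:1 / 10, x = c(7.9, 0), y = c(0, 0), z = c(0, 1))
  m2 <- identity_calibration(); m2$gain <- c(1.1, 1, 1)
  out2 <- apply_calibration(rec2, m2, cfg10)
  expect_equal(out2$data$x[1], 8)
  expect_equal(out2$quality$clips_after_calib, 1L)
})

test_that("applying the fitted model restores unit-norm rest geometry", {
  sc <- sim_scenario(seed = 7, days = 0.5, rate_hz = 10)
  sim <- simulate_participant(sc, cfg10)
  w <- find_stationary_windows(sim$recording, cfg10)
  m <- fit_calibration(w, cfg10)
  cal <- apply_calibration(sim$recording, m, cfg10)
  wc <- find_stationary_windows(cal, cfg10)
  norms <- sqrt(wc$mx^2 + wc$my^2 + wc$mz^2)
  expect_lt(abs(mean(norms) - 1) * 1000, 5)
})

test_that("calibration resolution prefers self, then registry, then identity", {
  sc <- sim_scenario(seed = 8, days = 0.5, rate_hz = 10)
  rec <- simulate_participant(sc, cfg10)$recording
  m <- resolve_calibration(rec, NULL, cfg10)
  expect_identical(m$source, "self")

  still <- const_rec(300, c(0, 0, 1))  # stationary but no range
  prior <- identity_calibration(fitted_at = T0 - 86400)
  prior$source <- "self"; prior$offset <- c(0.01, 0, 0)
  nxt <- identity_calibration(fitted_at = T0 + 86400)
  nxt$source <- "self"; nxt$offset <- c(0.02, 0, 0)
  reg <- list(unknown = list(prior, nxt))
  m <- resolve_calibration(still, reg, cfg10)
  expect_identical(m$source, "borrowed_previous")
  expect_equal(m$offset[1], 0.01)

  reg_next <- list(unknown = list(nxt))
  m <- resolve_calibration(still, reg_next, cfg10)
  expect_identical(m$source, "borrowed_next")

  expect_warning(m <- resolve_calibration(still, list(), cfg10),
                 "identity")
  expect_identical(m$source, "identity")
  expect_equal(m$offset, c(0, 0, 0))
  expect_equal(m$gain, c(1, 1, 1))
})

test_that("registries round-trip through JSON and stay chronological", {
  m1 <- identity_calibration(fitted_at = T0)
  m2 <- identity_calibration(fitted_at = T0 - 86400)
  m2$offset <- c(0.005, 0, 0)
  reg <- add_to_registry(list(), "devA", m1)
  reg <- add_to_registry(reg, "devA", m2)
  expect_equal(reg$devA[[1]]$offset[1], 0.005)  # sorted by fitted_at
  p <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, p)
  back <- read_registry(p)
  expect_equal(length(back$devA), 2L)
  expect_equal(back$devA[[1]]$offset, m2$offset)
  expect_equal(as.numeric(back$devA[[2]]$fitted_at), as.numeric(T0))
})
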