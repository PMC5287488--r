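# Shared fixture builders. Everything is generated in code at test time;
# low sampling rates keep the suite fast without changing any logic.

T0 <- as.POSIXct("2014-03-10 00:00:00", tz = "UTC")

# config scaled to a 10 Hz grid (cutoff kept at the same 0.4 x Nyquist
# fraction as the 100 Hz default)
cfg10 <- pipeline_config(resample_rate_hz = 10, filter_cutoff_hz = 2)
cfg25 <- pipeline_config(resample_rate_hz = 25, filter_cutoff_hz = 5)

# recording from explicit relative times (s) and per-axis values
make_rec <- function(t_rel, x, y, z, rate = 10, start = T0, offset = 0L,
                     config = cfg10, ...) {
  raw_recording(time = start + t_rel, x = x, y = y, z = z,
                nominal_rate_hz = rate, utc_offset_s = offset,
                config = config, ...)
}

# constant-orientation recording of given duration
const_rec <- function(duration_s, vec = c(0, 0, 1), rate = 10, start = T0,
                      noise_sd = 0, config = cfg10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * rate)
  t_rel <- (seq_len(n) - 1L) / rate
  noise <- function() if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  make_rec(t_rel, vec[1] + noise(), vec[2] + noise(), vec[3] + noise(),
           rate = rate, start = start, config = config)
}

# epoch series built directly (already flagged)
build_epochs <- function(vm, wear = TRUE, imputed = FALSE, epoch_s = 5,
                         start = T0, offset = 0L) {
  n <- length(vm)
  es <- data.table::data.table(
    start = start + (seq_len(n) - 1L) * epoch_s,
    vm_mg = vm,
    wear = rep_len(wear, n),
    imputed = rep_len(imputed, n),
    fallback = FALSE,
    valid_fraction = as.numeric(rep_len(wear, n)))
  wristpa:::as_epoch_series(es, epoch_s, offset)
}

# scalar uniform signal helper
make_signal <- function(values, rate = 10, start = T0, offset = 0L,
                        missing = NULL) {
  wristpa:::new_uniform_signal(
    start, offset, rate, values,
    missing %||% rep(FALSE, NROW(values)), 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
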