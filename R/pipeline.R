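#' Run the full processing pipeline on one recording
#'
#' Calibration (self-fit or borrowed), clip re-counting, resampling with
#' interrupt handling, Euclidean norm, low-pass noise removal, gravity
#' removal, epoch aggregation, non-wear detection and flagging, the
#' inclusion rule, time-of-day imputation, and the participant summary.
#'
#' @param rec A [raw_recording()] (or a path passed to [read_raw_csv()]).
#' @param config A [pipeline_config()].
#' @param registry Optional calibration registry for coefficient
#'   borrowing (see [read_registry()]).
#' @param mode Gravity-removal metric, see [remove_gravity()].
#' @param meta Participant metadata passed to [summarize_participant()].
#' @return List of class `pipeline_result`: `summary`
#'   (`participant_summary`), `epochs` (imputed `epoch_series`),
#'   `calibration` (`calibration_model`), `nonwear` (episode table),
#'   `inclusion`, `quality`.
#' @export
process_recording <- function(rec, config = pipeline_config(),
                              registry = NULL, mode = "enmo_trunc",
                              meta = list()) {
  if (is.character(rec)) rec <- read_raw_csv(rec, config)
  stopifnot(inherits(rec, "raw_recording"))
  if (is.null(meta$participant_id)) meta$participant_id <- rec$device_id

  model <- resolve_calibration(rec, registry, config)
  cal <- apply_calibration(rec, model, config)

  windows <- find_stationary_windows(cal, config)
  episodes <- detect_nonwear(windows, config)

  sig <- resample_with_gaps(cal, config)
  cal$quality$interrupts <- sig$interrupts
  vm <- vector_magnitude(sig)
  vm <- lowpass_noise_filter(vm, config)
  act <- remove_gravity(vm, mode, config)

  epochs <- make_epochs(act, config)
  epochs <- flag_wear(epochs, episodes)
  inclusion <- check_inclusion(epochs, config)
  epochs <- impute_nonwear(epochs, config)

  summary <- summarize_participant(epochs, meta, config,
                                   quality = cal$quality)
  structure(list(summary = summary, epochs = epochs, calibration = model,
                 nonwear = episodes, inclusion = inclusion,
                 quality = cal$quality),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$summary)
  print(x$calibration)
  cat(sprintf("  non-wear episodes: %d; interrupts: %s\n",
              nrow(x$nonwear), x$quality$interrupts))
  invisible(x)
}
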