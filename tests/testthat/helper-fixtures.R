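# Shared small fixtures, built once per test run (read-only).

.fixture_env <- new.env(parent = emptyenv())

# a small simulated dataset: 3 subjects, 12 trials, 250 Hz, snr 1.5
fx_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- simulate_dataset(
      motion_config(),
      synth_config(n_subjects = 3, sampling_rate = 250, snr = 1.5),
      n_trials = 12, seed = 42)
  }
  .fixture_env$ds
}

fx_preprocessed <- function() {
  if (is.null(.fixture_env$recs))
    .fixture_env$recs <- lapply(fx_dataset()$recordings, preprocess)
  .fixture_env$recs
}

fx_weights <- function() {
  if (is.null(.fixture_env$w)) {
    eps <- combine_epochs(lapply(fx_preprocessed(), epoch_recording,
                                 events = fx_dataset()$events_target))
    .fixture_env$w <- pca_weights(grand_average(eps))
  }
  .fixture_env$w
}

# a hand-built trial object: 4 items over an explicit position array
fx_manual_trial <- function(positions, frame_rate = 100, duration = NULL) {
  n_frames <- dim(positions)[2]
  if (is.null(duration)) duration <- (n_frames - 1) / frame_rate
  structure(list(positions = positions, frame_rate = frame_rate,
                 duration = duration, target_ids = 1:4,
                 trial_id = 1L, match_condition = 0L),
            class = "mot_trial")
}

# triangle A/B/C fixed, D moving along x = 2.2 through the BC edge
# (crossing height y = 2.7); returns a trial whose only dynamics are
# D's given y positions
fx_triangle_trial <- function(d_y, frame_rate = 100) {
  n <- length(d_y)
  pos <- array(NA_real_, c(4, n, 2))
  pos[1, , ] <- matrix(c(0, 0), n, 2, byrow = TRUE)
  pos[2, , ] <- matrix(c(4, 0), n, 2, byrow = TRUE)
  pos[3, , ] <- matrix(c(2, 3), n, 2, byrow = TRUE)
  pos[4, , 1] <- 2.2
  pos[4, , 2] <- d_y
  fx_manual_trial(pos, frame_rate = frame_rate)
}

# minimal synthetic recording built from explicit data
fx_recording <- function(data, channels, sampling_rate = 250,
                         trial_onsets = 1L, trial_ids = 1L,
                         trial_duration = (ncol(data) - 1) / sampling_rate) {
  rownames(data) <- channels
  structure(list(subject_id = 1L, data = data, channels = channels,
                 sampling_rate = sampling_rate,
                 trial_onsets = as.integer(trial_onsets),
                 trial_ids = as.integer(trial_ids),
                 trial_duration = trial_duration, preprocessed = FALSE),
            class = "eeg_recording")
}
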