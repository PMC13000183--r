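#' Standard 32-channel montage used by the synthetic EEG generator
#'
#' A 10-20/10-10 montage of 32 channels including the occipital row
#' (O9, O1, Oz, O2, O10) and the mastoid surrogates TP9/TP10 used for
#' offline re-referencing.
#'
#' @return character vector of 32 unique channel labels.
#' @export
topo_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "O9", "O1", "Oz", "O2", "O10")
}

#' Bilateral ventral-occipital scalp topography
#'
#' Unit-norm channel weight vector emulating a bilateral ventral
#' occipital source pattern (strongest over O9/O10 and O1/O2, weak at
#' the midline, negligible frontally). Used to spatially mix the
#' event-locked waveforms into the synthetic recording.
#'
#' @param channels channel labels (default [topo_channels()]).
#' @return An object of class `scalp_topography`: a named unit-norm
#'   numeric vector, one weight per channel.
#' @export
occipital_topography <- function(channels = topo_channels()) {
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  w <- stats::setNames(numeric(length(channels)), channels)
  pat <- c(O9 = 0.55, O10 = 0.55, O1 = 0.40, O2 = 0.40, Oz = 0.18,
           P7 = 0.15, P8 = 0.15, P3 = 0.05, P4 = 0.05)
  found <- intersect(names(pat), channels)
  w[found] <- pat[found]
  if (sum(w^2) == 0) stop("none of the topography channels are present")
  w <- w / sqrt(sum(w^2))
  class(w) <- "scalp_topography"
  w
}

#' Event-locked waveform kernels for the three transition types
#'
#' Smooth transient waveforms of distinct morphology per event type:
#' by default a biphasic Gaussian derivative for flips, a compact
#' 4.5 Hz cosine Gabor for concave transitions, and an 8 Hz sine
#' Gabor for convex transitions. The three shapes are mutually
#' discriminable (pairwise waveform correlation below 0.5, asserted at
#' construction), time-localized so that template windows centred off
#' the response capture distinctly less of its energy, and their
#' autocorrelations keep a positive mean over a ±50 ms window, so
#' decoding performance assessed at event occurrence does not
#' self-cancel. Each kernel carries a latency shift giving the centre
#' of its energy relative to the geometric event: by default the flip
#' response is anticipatory (-150 ms), the concave response lags the
#' event (+150 ms), and the convex response is synchronous -- the
#' ground truth the lag-map analysis is expected to recover.
#'
#' @param sampling_rate Hz (default 500).
#' @param support half-width of the kernel support in seconds
#'   (default 0.4).
#' @param shapes per-type waveform specification: a named list of
#'   lists with `family` (`"gauss"`, `"dgauss"`, `"ricker"`, or
#'   `"gabor"`), `sigma` (Gaussian width, seconds), and for `"gabor"`
#'   also `freq` (Hz) and `phase` (radians).
#' @param latency_shift named shifts in seconds (negative =
#'   anticipatory).
#' @return Named list of class `event_kernels`; each element has
#'   `event_type`, `tau` (time grid), `waveform` (peak amplitude 1 µV),
#'   and `latency_shift`.
#' @export
event_kernels <- function(sampling_rate = 500, support = 0.4,
                          shapes = list(
                            flip = list(family = "dgauss", sigma = 0.06),
                            concave = list(family = "gabor", sigma = 0.07,
                                           freq = 4.5, phase = 0),
                            convex = list(family = "gabor", sigma = 0.06,
                                          freq = 8, phase = -pi / 2)),
                          latency_shift = c(flip = -0.15, concave = 0.15,
                                            convex = 0)) {
  tau <- seq(-support, support, by = 1 / sampling_rate)
  shape_fun <- list(
    gauss = function(p) exp(-tau^2 / (2 * p$sigma^2)),
    dgauss = function(p) -tau * exp(-tau^2 / (2 * p$sigma^2)),
    ricker = function(p) (1 - tau^2 / p$sigma^2) * exp(-tau^2 / (2 * p$sigma^2)),
    gabor = function(p) cos(2 * pi * p$freq * tau + p$phase) *
      exp(-tau^2 / (2 * p$sigma^2)))
  ks <- lapply(event_types(), function(e) {
    spec <- shapes[[e]]
    fam <- match.arg(spec$family, names(shape_fun))
    wf <- shape_fun[[fam]](spec)
    wf <- wf / max(abs(wf))
    list(event_type = e, tau = tau, waveform = wf,
         latency_shift = latency_shift[[e]])
  })
  names(ks) <- event_types()
  cm <- stats::cor(cbind(ks$flip$waveform, ks$concave$waveform,
                         ks$convex$waveform))
  if (max(abs(cm[upper.tri(cm)])) >= 0.5)
    stop("kernel waveforms are not discriminable (pairwise |r| >= 0.5); ",
         "choose more distinct frequencies/phases")
  class(ks) <- c("event_kernels", "list")
  ks
}

#' Synthetic EEG generation parameters
#'
#' @param n_subjects number of simulated subjects (default 38, the
#'   size of the emulated study sample).
#' @param sampling_rate Hz (default 500).
#' @param snr amplitude ratio of kernel peak to noise SD (default 1).
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha
#'   channel noise (default 1).
#' @param channel_noise_corr pairwise spatial correlation of the noise
#'   across channels, 0-1 (default 0.2).
#' @param inter_trial_gap seconds of pure noise between trials
#'   (default 1).
#' @param seed optional integer seed used by [simulate_dataset()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 38, sampling_rate = 500, snr = 1,
                         noise_exponent = 1, channel_noise_corr = 0.2,
                         inter_trial_gap = 1, seed = NULL) {
  stopifnot(n_subjects >= 1, sampling_rate > 0, snr >= 0,
            noise_exponent >= 0,
            channel_noise_corr >= 0, channel_noise_corr < 1,
            inter_trial_gap >= 0)
  cfg <- list(n_subjects = as.integer(n_subjects),
              sampling_rate = sampling_rate, snr = snr,
              noise_exponent = noise_exponent,
              channel_noise_corr = channel_noise_corr,
              inter_trial_gap = inter_trial_gap, seed = seed)
  class(cfg) <- "synth_config"
  cfg
}

# 1/f^alpha Gaussian noise, one column per series, each standardized
# to mean 0 / SD 1. Synthesized directly in the frequency domain: the
# real part of a circularly-symmetric complex Gaussian spectrum with
# magnitude f^(-alpha/2) is real Gaussian noise with that power
# spectrum, so only one (inverse) FFT per series is needed.
.shaped_noise <- function(n_samples, n_series, alpha, sampling_rate) {
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  if (alpha == 0) {
    return(scale(w)[, , drop = FALSE])
  }
  z <- w + 1i * matrix(stats::rnorm(n_samples * n_series),
                       n_samples, n_series)
  k <- seq_len(n_samples) - 1L
  f <- pmin(k, n_samples - k) * sampling_rate / n_samples
  sc <- c(0, f[-1]^(-alpha / 2))   # DC removed
  out <- Re(stats::mvfft(z * sc, inverse = TRUE))
  scale(out)[, , drop = FALSE]
}

#' Generate multichannel 1/f noise
#'
#' Gaussian noise with a 1/f^alpha power spectrum per channel, unit
#' variance, and a controllable uniform pairwise correlation across
#' channels (implemented by mixing a shared shaped-noise series into
#' independent ones).
#'
#' @param n_channels number of channels.
#' @param n_samples number of samples.
#' @param alpha spectral exponent (0 = white, 1 = pink).
#' @param channel_corr target pairwise channel correlation in `[0, 1)`.
#' @param sampling_rate Hz (affects only the frequency axis of the
#'   shaping).
#' @return numeric matrix `n_channels x n_samples`.
#' @export
make_noise <- function(n_channels, n_samples, alpha = 1, channel_corr = 0,
                       sampling_rate = 500) {
  stopifnot(n_samples > 0, n_channels > 0)
  if (channel_corr > 0) {
    g <- .shaped_noise(n_samples, n_channels + 1L, alpha, sampling_rate)
    shared <- g[, 1L]
    out <- sqrt(channel_corr) * shared +
      sqrt(1 - channel_corr) * g[, -1L, drop = FALSE]
  } else {
    out <- .shaped_noise(n_samples, n_channels, alpha, sampling_rate)
  }
  t(out)
}

.new_recording <- function(subject_id, data, channels, sampling_rate,
                           trial_onsets, trial_ids, trial_duration) {
  rec <- list(subject_id = subject_id, data = data, channels = channels,
              sampling_rate = sampling_rate,
              trial_onsets = as.integer(trial_onsets),
              trial_ids = as.integer(trial_ids),
              trial_duration = trial_duration,
              preprocessed = FALSE)
  rownames(rec$data) <- channels
  class(rec) <- "eeg_recording"
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples at %g Hz, %d trials\n",
              as.character(x$subject_id), nrow(x$data), ncol(x$data),
              x$sampling_rate, length(x$trial_onsets)))
  invisible(x)
}

#' Number of samples in one trial's motion window
#' @param rec an `eeg_recording`.
#' @return integer sample count (`round(duration * fs) + 1`).
#' @export
trial_samples <- function(rec) {
  as.integer(round(rec$trial_duration * rec$sampling_rate)) + 1L
}

#' Embed event-locked waveforms into a recording
#'
#' Adds `snr * kernel` waveforms, spatially mixed by the topography, at
#' every event time (shifted by the kernel's latency shift). Kernels
#' whose support crosses the edge of the recording are truncated with a
#' warning.
#'
#' @param rec an `eeg_recording` (typically pure noise).
#' @param events a `topo_events` data frame; times are relative to the
#'   motion onset of their trial.
#' @param kernels an [event_kernels()] object.
#' @param topography a [occipital_topography()] vector, aligned with
#'   the recording's channels.
#' @param snr peak kernel amplitude in units of noise SD.
#' @return the recording with signal added and a `ground_truth`
#'   attribute (per-event sample index of the embedded kernel centre).
#' @export
embed_events <- function(rec, events, kernels, topography, snr) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!identical(names(topography), rec$channels))
    stop("topography channels do not match the recording")
  if (snr == 0 || nrow(events) == 0) {
    attr(rec, "ground_truth") <- events[0, ]
    return(rec)
  }
  fs <- rec$sampling_rate
  n <- ncol(rec$data)
  topo <- as.numeric(topography)
  gt_sample <- integer(nrow(events))
  truncated <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    k <- kernels[[as.character(ev$event_type)]]
    onset <- rec$trial_onsets[match(ev$trial_id, rec$trial_ids)]
    if (is.na(onset)) stop("event refers to unknown trial ", ev$trial_id)
    centre <- onset + round((ev$time + k$latency_shift) * fs)
    idx <- centre + round(k$tau * fs)
    keep <- idx >= 1L & idx <= n
    if (!all(keep)) truncated <- truncated + 1L
    rec$data[, idx[keep]] <- rec$data[, idx[keep]] +
      snr * topo %o% k$waveform[keep]
    gt_sample[i] <- centre
  }
  if (truncated > 0L)
    warning(truncated, " kernel(s) truncated at the recording edge")
  gt <- events
  gt$embedded_sample <- gt_sample
  attr(rec, "ground_truth") <- gt
  rec
}

#' Simulate one subject's continuous recording
#'
#' Lays the session's trials out on a continuous time axis separated
#' by `inter_trial_gap` seconds of pure noise, generates 1/f channel
#' noise, and embeds the event-locked kernels at the given events.
#'
#' @param session a `mot_session` (defines trial count and duration).
#' @param events events driving the embedded responses (normally the
#'   target-set events; distractor events drive nothing).
#' @param config a [synth_config()].
#' @param subject_id identifier stored in the recording.
#' @param kernels,topography see [embed_events()].
#' @return an `eeg_recording`.
#' @export
simulate_recording <- function(session, events, config, subject_id = 1L,
                               kernels = event_kernels(config$sampling_rate),
                               topography = occipital_topography()) {
  fs <- config$sampling_rate
  n_trials <- length(session$trials)
  dur <- session$config$duration
  tr_len <- as.integer(round(dur * fs)) + 1L
  gap <- as.integer(round(config$inter_trial_gap * fs))
  onsets <- gap + 1L + (seq_len(n_trials) - 1L) * (tr_len + gap)
  n_samples <- onsets[n_trials] + tr_len - 1L + gap
  channels <- names(topography)
  noise <- make_noise(length(channels), n_samples, config$noise_exponent,
                      config$channel_noise_corr, fs)
  rec <- .new_recording(subject_id, noise, channels, fs, onsets,
                        vapply(session$trials, function(tr) tr$trial_id, 0L),
                        dur)
  embed_events(rec, events, kernels, topography, config$snr)
}

#' Simulate a complete multi-subject dataset
#'
#' One shared trial set (and hence one shared event table) is used for
#' all subjects, mirroring a study in which every subject views the
#' same precomputed trajectories; noise is independent per subject.
#' Target-set events drive the embedded kernels; distractor-set events
#' drive nothing and therefore provide a built-in null control.
#'
#' @param motion_config a [motion_config()].
#' @param config a [synth_config()].
#' @param n_trials trials per subject (default 300).
#' @param seed integer seed; overrides `config$seed` when given.
#' @return An object of class `synth_dataset`: list with `session`,
#'   `events_target`, `events_distractor`, `recordings` (list of
#'   `eeg_recording`), `kernels`, `topography`, and the configs.
#' @export
#' @examples
#' ds <- simulate_dataset(motion_config(), synth_config(n_subjects = 2),
#'                        n_trials = 3, seed = 1)
#' length(ds$recordings)
simulate_dataset <- function(motion_config, config, n_trials = 300L,
                             seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  session <- generate_session(motion_config, n_trials = n_trials)
  ev_t <- detect_session_events(session, "target")
  ev_d <- detect_session_events(session, "distractor")
  kernels <- event_kernels(config$sampling_rate)
  topography <- occipital_topography()
  recordings <- lapply(seq_len(config$n_subjects), function(s)
    simulate_recording(session, ev_t, config, subject_id = s,
                       kernels = kernels, topography = topography))
  out <- list(session = session, events_target = ev_t,
              events_distractor = ev_d, recordings = recordings,
              kernels = kernels, topography = topography,
              motion_config = motion_config, synth_config = config)
  class(out) <- "synth_dataset"
  out
}
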