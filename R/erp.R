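#' Preprocess a continuous recording
#'
#' Applies a zero-phase Butterworth high-pass filter (order 2, applied
#' forwards and backwards) to remove slow drifts, then re-references
#' every channel to the mean of the two reference channels (mastoid
#' surrogates by default). Re-referencing is idempotent: the mean of
#' the reference pair is zero afterwards.
#'
#' @param rec an `eeg_recording`.
#' @param highpass cutoff in Hz (default 0.5); `NULL` or 0 skips the
#'   filter.
#' @param reference pair of channel labels used as reference (default
#'   `c("TP9", "TP10")`); must be present in the recording.
#' @return the filtered, re-referenced `eeg_recording`.
#' @export
preprocess <- function(rec, highpass = 0.5, reference = c("TP9", "TP10")) {
  stopifnot(inherits(rec, "eeg_recording"))
  miss <- setdiff(reference, rec$channels)
  if (length(miss))
    stop("reference channel(s) not in recording: ", paste(miss, collapse = ", "))
  if (!is.null(highpass) && highpass > 0) {
    bf <- signal::butter(2, highpass / (rec$sampling_rate / 2), type = "high")
    for (i in seq_len(nrow(rec$data)))
      rec$data[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  }
  ref <- colMeans(rec$data[reference, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref, "-")
  rec$preprocessed <- TRUE
  rec
}

#' Epoch a recording around transition events
#'
#' Cuts one `[tau_min, tau_max]` slice per event, time-locked to the
#' event (event times are snapped to the nearest sample of the
#' recording). Events whose window would cross the edge of the
#' recording are dropped and counted.
#'
#' @param rec an `eeg_recording`.
#' @param events a `topo_events` data frame (times relative to the
#'   motion onset of their trial).
#' @param tau_min,tau_max epoch window in seconds (defaults -0.4/+0.4).
#' @return An object of class `epoch_set`: list with `data` (array
#'   `n_events x n_channels x n_tau`, µV), `tau` (seconds), `channels`,
#'   `sampling_rate`, `info` (one row per kept event, with a `subject`
#'   column), and `n_dropped`.
#' @export
epoch_recording <- function(rec, events, tau_min = -0.4, tau_max = 0.4) {
  stopifnot(inherits(rec, "eeg_recording"), tau_min < tau_max)
  fs <- rec$sampling_rate
  offs <- seq.int(round(tau_min * fs), round(tau_max * fs))
  tau <- offs / fs
  onset <- rec$trial_onsets[match(events$trial_id, rec$trial_ids)]
  if (anyNA(onset)) stop("events refer to trials absent from the recording")
  centre <- onset + round(events$time * fs)
  ok <- centre + offs[1] >= 1L & centre + offs[length(offs)] <= ncol(rec$data)
  data <- array(NA_real_, c(sum(ok), nrow(rec$data), length(offs)))
  ki <- which(ok)
  for (j in seq_along(ki))
    data[j, , ] <- rec$data[, centre[ki[j]] + offs]
  info <- events[ok, , drop = FALSE]
  info$subject <- rec$subject_id
  rownames(info) <- NULL
  out <- list(data = data, tau = tau, channels = rec$channels,
              sampling_rate = fs, info = info, n_dropped = sum(!ok))
  class(out) <- "epoch_set"
  out
}

#' Combine epoch sets from several subjects
#'
#' @param ... `epoch_set` objects (or one list of them) on identical
#'   channel and tau grids.
#' @return a single pooled `epoch_set`.
#' @export
combine_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "epoch_set"))
    sets <- sets[[1]]
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$channels, ref$channels) || !isTRUE(all.equal(s$tau, ref$tau)))
      stop("epoch sets differ in channels or tau grid")
  }
  n <- vapply(sets, function(s) dim(s$data)[1], 0L)
  data <- array(NA_real_, c(sum(n), length(ref$channels), length(ref$tau)))
  at <- 0L
  for (s in sets) {
    if (dim(s$data)[1] > 0)
      data[at + seq_len(dim(s$data)[1]), , ] <- s$data
    at <- at + dim(s$data)[1]
  }
  out <- list(data = data, tau = ref$tau, channels = ref$channels,
              sampling_rate = ref$sampling_rate,
              info = do.call(rbind, lapply(sets, function(s) s$info)),
              n_dropped = sum(vapply(sets, function(s) s$n_dropped, 0L)))
  class(out) <- "epoch_set"
  out
}

#' Grand-average ERP per event type
#'
#' Pooled mean over *all* epochs of each type -- every event counts
#' once, regardless of how events are distributed over subjects and
#' trials (not a mean of per-subject means).
#'
#' @param epochs an `epoch_set` (typically combined across subjects).
#' @param types event types to average (default all three).
#' @return named list of `n_channels x n_tau` matrices.
#' @export
grand_average <- function(epochs, types = event_types()) {
  out <- lapply(types, function(e) {
    sel <- epochs$info$event_type == e
    if (!any(sel)) stop("no epochs of type ", e)
    m <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
    dimnames(m) <- list(epochs$channels, NULL)
    m
  })
  names(out) <- types
  out
}

#' Occipital window contrast of transition ERPs
#'
#' Mean amplitude per subject and event type over a set of channels
#' and a post-event time window (defaults: O1/Oz/O2, 84-128 ms), the
#' quantity entering the one-factor test for amplitude differences
#' between the three transition types.
#'
#' @param epochs an `epoch_set` with a `subject` column in its info.
#' @param channels channel labels to average (default O1, Oz, O2).
#' @param window two-element numeric window in seconds
#'   (default `c(0.084, 0.128)`).
#' @return data frame with columns `subject`, `event_type`,
#'   `amplitude` (µV).
#' @export
transition_window_contrast <- function(epochs, channels = c("O1", "Oz", "O2"),
                                       window = c(0.084, 0.128)) {
  chi <- match(channels, epochs$channels)
  if (anyNA(chi)) stop("channel(s) not present: ",
                       paste(channels[is.na(chi)], collapse = ", "))
  ti <- which(epochs$tau >= window[1] & epochs$tau <= window[2])
  if (!length(ti) || window[1] < min(epochs$tau) || window[2] > max(epochs$tau))
    stop("window lies outside the epoch tau grid")
  info <- epochs$info
  combos <- unique(info[, c("subject", "event_type")])
  amp <- mapply(function(s, e) {
    sel <- info$subject == s & info$event_type == e
    mean(epochs$data[sel, chi, ti])
  }, combos$subject, as.character(combos$event_type))
  data.frame(subject = combos$subject, event_type = combos$event_type,
             amplitude = as.numeric(amp), row.names = NULL)
}

#' PCA channel weights from grand-average ERPs
#'
#' Performs a covariance PCA of the grand-average ERP signal: the
#' observations are the time samples of all three event types
#' concatenated (3 x n_tau rows), the variables are the channels.
#' Channels are mean-centred, not rescaled, because the resulting
#' weights are applied directly to µV signals. The rows of the weight
#' matrix are the orthonormal loading vectors, ordered by decreasing
#' explained variance; each row's sign is fixed so its
#' largest-magnitude loading is positive, making the decomposition
#' deterministic.
#'
#' @param ga named list of per-type grand-average matrices from
#'   [grand_average()], on a common channel/tau grid.
#' @return An object of class `pca_weights`: list with `w`
#'   (`n_components x n_channels`), `explained_variance`, `channels`,
#'   and `n_valid` (number of non-degenerate components).
#' @export
pca_weights <- function(ga) {
  channels <- rownames(ga[[1]])
  X <- do.call(rbind, lapply(ga, t))   # (types * n_tau) x n_channels
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  w <- t(pc$rotation)                  # components x channels
  for (cidx in seq_len(nrow(w))) {
    j <- which.max(abs(w[cidx, ]))
    if (w[cidx, j] < 0) w[cidx, ] <- -w[cidx, ]
  }
  ev <- pc$sdev^2
  n_valid <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  # re-referencing always removes one dimension; warn only beyond that
  if (n_valid < length(channels) - 1L)
    warning("grand average is rank deficient: only ", n_valid,
            " informative components")
  colnames(w) <- channels
  rownames(w) <- paste0("C", seq_len(nrow(w)))
  out <- list(w = w, explained_variance = ev, channels = channels,
              n_valid = n_valid)
  class(out) <- "pca_weights"
  out
}

#' @export
print.pca_weights <- function(x, ...) {
  pv <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<pca_weights> %d components x %d channels; variance explained: %s...\n",
              nrow(x$w), length(x$channels),
              paste0(sprintf("%.1f%%", pv[seq_len(min(4, length(pv)))]),
                     collapse = ", ")))
  invisible(x)
}

#' Project multichannel data onto a principal component
#'
#' Computes the weighted channel sum `sum_n w_cn x_n(t)` for one
#' component. Works on a continuous recording (returns the component
#' time series), an epoch set (returns an events x tau matrix), or a
#' plain channels x samples matrix.
#'
#' @param x an `eeg_recording`, `epoch_set`, or numeric matrix with
#'   rownames matching the weight channels.
#' @param weights a [pca_weights()] object.
#' @param component component index (row of the weight matrix).
#' @return numeric vector (recording/matrix) or matrix (epoch set).
#' @export
project <- function(x, weights, component) {
  UseMethod("project")
}

.check_weights <- function(weights, channels, component) {
  if (!identical(weights$channels, channels))
    stop("channel labels/order do not match the PCA weights")
  if (component < 1 || component > nrow(weights$w))
    stop("component out of range")
  as.numeric(weights$w[component, ])
}

#' @rdname project
#' @export
project.eeg_recording <- function(x, weights, component) {
  wv <- .check_weights(weights, x$channels, component)
  as.numeric(wv %*% x$data)
}

#' @rdname project
#' @export
project.epoch_set <- function(x, weights, component) {
  wv <- .check_weights(weights, x$channels, component)
  d <- dim(x$data)
  m <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[2])
  matrix(wv %*% m, d[1], d[3])
}

#' @rdname project
#' @export
project.default <- function(x, weights, component) {
  wv <- .check_weights(weights, rownames(x), component)
  as.numeric(wv %*% x)
}
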