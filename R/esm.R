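#' Training/test split plans from probe-match conditions
#'
#' The probe-match condition (0-4) of each trial is decided at the end
#' of the trial, so it is independent of the tracking-phase EEG and
#' serves as a random selector: fixing a condition `m` makes the
#' trials probed with condition `m` the test set and all others the
#' training set. Five complementary plans result.
#'
#' @param trial_info data frame with columns `trial_id` and
#'   `match_condition`, or a `mot_session`.
#' @return list of 5 objects of class `split_plan`, each with `m`,
#'   `train` and `test` trial-id vectors.
#' @export
make_splits <- function(trial_info) {
  if (inherits(trial_info, "mot_session"))
    trial_info <- session_trial_info(trial_info)
  if (anyNA(trial_info$match_condition))
    stop("every trial needs a match_condition label")
  lapply(0:4, function(m) {
    sp <- list(m = m,
               train = trial_info$trial_id[trial_info$match_condition != m],
               test = trial_info$trial_id[trial_info$match_condition == m])
    class(sp) <- "split_plan"
    sp
  })
}

#' Event signature: mean component-space ERP over training events
#'
#' @param comp_epochs numeric matrix `n_events x n_tau` of
#'   component-projected epochs.
#' @param info data frame aligned with the epoch rows (needs
#'   `trial_id` and `event_type`).
#' @param type the training event type.
#' @param train_trials trial ids of the training set.
#' @return numeric vector over tau: the pooled mean of all training
#'   epochs of that type.
#' @export
build_signature <- function(comp_epochs, info, type, train_trials) {
  sel <- info$trial_id %in% train_trials & info$event_type == type
  if (!any(sel))
    stop("no training events of type '", type, "' in this split")
  colMeans(comp_epochs[sel, , drop = FALSE])
}

#' Sliding normalized cross-correlation of a signal with a signature
#'
#' For each time point `t` of the component time series, correlates
#' the signature (defined on the window `[tau_min, tau_max]` around an
#' event) with the signal slice `p(t + tau)`: both are demeaned over
#' that window and the product is normalized by both windowed standard
#' deviations, giving a Pearson-type value in `[-1, 1]`. Values are
#' undefined (`NA`) where the window would leave the series;
#' zero-variance windows yield 0 and are counted in the
#' `n_zero_variance` attribute rather than propagating `NaN`.
#'
#' @param p numeric vector, the component-projected signal of one
#'   trial.
#' @param signature numeric vector on the `[tau_min, tau_max]` grid
#'   (length `round(tau_max*fs) - round(tau_min*fs) + 1`).
#' @param sampling_rate Hz.
#' @param tau_min,tau_max signature window in seconds.
#' @return numeric vector of the same length as `p`, the
#'   event-similarity trace, with attribute `n_zero_variance`.
#' @export
esm_trace <- function(p, signature, sampling_rate, tau_min = -0.4,
                      tau_max = 0.4) {
  i0 <- round(tau_min * sampling_rate)
  i1 <- round(tau_max * sampling_rate)
  L <- i1 - i0 + 1L
  if (length(signature) != L)
    stop("signature length ", length(signature),
         " does not match the window (", L, " samples)")
  if (length(p) < L) {
    trace <- rep(NA_real_, length(p))
    attr(trace, "n_zero_variance") <- 0L
    return(trace)
  }
  tctx <- .trial_ctx(p, L)
  .trace_core(tctx, .sig_ctx(signature, tctx$N), i0)
}

# ---- FFT trace engine ------------------------------------------------
#
# The sliding dot products of a demeaned signature with all signal
# windows are computed by FFT cross-correlation. The per-trial pieces
# (padded FFT of the signal, cumulative sums for windowed mean/SD) are
# precomputed once and reused across signatures, permutations and lag
# windows; the per-signature FFT is reused across trials.

.next_pow2 <- function(x) 2^ceiling(log2(x))

.trial_ctx <- function(p, L_max) {
  n <- length(p)
  N <- .next_pow2(n + L_max)
  list(fp = stats::fft(c(p, numeric(N - n))),
       cs = cumsum(c(0, p)), cs2 = cumsum(c(0, p * p)), n = n, N = N)
}

.sig_ctx <- function(sig, N) {
  sc <- sig - mean(sig)
  list(fsc = stats::fft(c(sc, numeric(N - length(sc)))),
       ssc = sum(sc * sc), L = length(sc))
}

# trace over t (1-based sample index) given precomputed contexts;
# i0 = round(tau_min * fs), the window-start offset relative to t
.trace_core <- function(tctx, sctx, i0) {
  n <- tctx$n; L <- sctx$L
  trace <- rep(NA_real_, n)
  if (n < L) {
    attr(trace, "n_zero_variance") <- 0L
    return(trace)
  }
  conv <- Re(stats::fft(tctx$fp * Conj(sctx$fsc), inverse = TRUE)) / tctx$N
  j <- seq_len(n - L + 1L)
  dot <- conv[j]
  S1 <- tctx$cs[j + L] - tctx$cs[j]
  S2 <- tctx$cs2[j + L] - tctx$cs2[j]
  varx <- S2 - S1 * S1 / L
  varx[varx < 0] <- 0
  zero <- varx <= L * 1e-18 | sctx$ssc <= 1e-18
  r <- dot / sqrt(sctx$ssc * varx)
  r[zero] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  t_idx <- j - i0            # window start j corresponds to time index t
  valid <- t_idx >= 1L & t_idx <= n
  trace[t_idx[valid]] <- r[valid]
  attr(trace, "n_zero_variance") <- sum(zero[valid])
  trace
}

#' Event-locked average of an ESM trace
#'
#' Averages trace values around the given (test) events, pooled over
#' events; samples where the trace is undefined are excluded pairwise,
#' with the effective count per tau returned.
#'
#' @param traces named list of ESM traces, one per trial (names are
#'   trial ids).
#' @param events events to lock on (rows with `trial_id`, `time`).
#' @param sampling_rate Hz.
#' @param tau_w half-width of the locking window in seconds
#'   (default 0.5).
#' @return list with `values` (mean over events per tau), `tau`,
#'   `n_events`, and `n_defined` (per-tau effective counts).
#' @export
lock_esm <- function(traces, events, sampling_rate, tau_w = 0.5) {
  if (nrow(events) == 0) stop("no test events to lock on")
  offs <- seq.int(-round(tau_w * sampling_rate), round(tau_w * sampling_rate))
  acc <- numeric(length(offs)); cnt <- integer(length(offs))
  for (i in seq_len(nrow(events))) {
    tr <- traces[[as.character(events$trial_id[i])]]
    if (is.null(tr)) stop("no trace for trial ", events$trial_id[i])
    s <- round(events$time[i] * sampling_rate) + 1L
    idx <- s + offs
    v <- rep(NA_real_, length(offs))
    inb <- idx >= 1L & idx <= length(tr)
    v[inb] <- tr[idx[inb]]
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  list(values = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_),
       tau = offs / sampling_rate, n_events = nrow(events),
       n_defined = cnt)
}

# ---- internal pipeline machinery ------------------------------------

# Project one subject's recording to a component and slice it into
# per-trial series plus component-space epochs on the signature
# support grid. Epochs whose support window leaves the trial's motion
# window are dropped (counted in n_dropped).
.prep_subject <- function(rec, events, weights, component, support) {
  fs <- rec$sampling_rate
  pc <- project(rec, weights, component)
  tr_len <- trial_samples(rec)
  trials_pc <- lapply(rec$trial_onsets, function(o) pc[o + 0:(tr_len - 1L)])
  names(trials_pc) <- as.character(rec$trial_ids)
  offs <- seq.int(round(support[1] * fs), round(support[2] * fs))
  trials_ctx <- lapply(trials_pc, .trial_ctx, L_max = length(offs))
  within <- round(events$time * fs) + 1L
  ok <- within + offs[1] >= 1L & within + offs[length(offs)] <= tr_len
  ev <- events[ok, , drop = FALSE]
  ep <- matrix(NA_real_, nrow(ev), length(offs))
  wv <- within[ok]
  onset <- rec$trial_onsets[match(ev$trial_id, rec$trial_ids)]
  for (i in seq_len(nrow(ev)))
    ep[i, ] <- pc[onset[i] + wv[i] - 1L + offs]
  list(trials_pc = trials_pc, trials_ctx = trials_ctx, ep = ep, info = ev,
       fs = fs, sup_offs = offs, n_dropped = sum(!ok))
}

# recordings argument: a list of eeg_recording, or a generator
# function(subject_index) -> eeg_recording together with n_subjects
# (memory-safe at large subject counts: recordings are realized one at
# a time and discarded after projection)
.prep_all <- function(recordings, n_subjects, events, weights, component,
                      support) {
  if (is.function(recordings)) {
    stopifnot(!is.null(n_subjects))
    lapply(seq_len(n_subjects), function(s)
      .prep_subject(recordings(s), events, weights, component, support))
  } else {
    lapply(recordings, .prep_subject, events = events, weights = weights,
           component = component, support = support)
  }
}

# Signatures (list over event types) from training epochs, restricted
# to the signature window columns; labels may be permuted.
.signatures <- function(ep, labels, train_sel, cols) {
  lapply(stats::setNames(event_types(), event_types()), function(e) {
    sel <- train_sel & labels == e
    if (!any(sel))
      stop("no training events of type '", e, "' in this split")
    colMeans(ep[sel, cols, drop = FALSE])
  })
}

# Decompose one split's test events into plain vectors (per-trial
# sample indices and type indices), computed once per split and reused
# across all signature sets and permutations.
.prep_test_events <- function(prep, test_trials) {
  info <- prep$info
  sel <- info$trial_id %in% test_trials
  te <- info[sel, , drop = FALSE]
  fi_all <- match(as.character(te$event_type), event_types())
  s_all <- round(te$time * prep$fs) + 1L
  ids <- as.character(te$trial_id)
  lapply(unique(ids), function(tid) {
    k <- ids == tid
    list(trial = tid, s = s_all[k], fi = fi_all[k])
  })
}

# One split: locked ESM array [e, f, tau_lock] for a given signature
# set. Uses the precomputed per-trial FFT contexts; the signature FFT
# is computed once and shared across trials.
.split_locked <- function(sigs, prep, test_prep, tau_min, tau_max, tau_w) {
  fs <- prep$fs
  i0 <- round(tau_min * fs)
  offs <- seq.int(-round(tau_w * fs), round(tau_w * fs))
  n_off <- length(offs)
  acc <- array(0, c(3, 3, n_off))
  cnt <- array(0L, c(3, 3, n_off))
  N <- prep$trials_ctx[[1]]$N
  for (ei in 1:3) {
    sctx <- .sig_ctx(sigs[[ei]], N)
    for (b in test_prep) {
      tr <- .trace_core(prep$trials_ctx[[b$trial]], sctx, i0)
      n_tr <- length(tr)
      for (k in seq_along(b$s)) {
        idx <- b$s[k] + offs
        inb <- idx >= 1L & idx <= n_tr
        v <- tr[idx[inb]]
        ok <- !is.na(v)
        wj <- which(inb)[ok]
        fi <- b$fi[k]
        acc[ei, fi, wj] <- acc[ei, fi, wj] + v[ok]
        cnt[ei, fi, wj] <- cnt[ei, fi, wj] + 1L
      }
    }
  }
  list(mean = acc / pmax(cnt, 1L) * ifelse(cnt > 0, 1, NA), cnt = cnt)
}

#' Permutation baseline of the event-locked ESM
#'
#' Shuffles the three event-type labels among the training events of
#' one subject/split (a label permutation, preserving per-type
#' counts), recomputes signatures, traces, and the event-locked ESM,
#' and averages the result over `n_perm` shuffles. PCA weights and all
#' event *times* are untouched.
#'
#' @param prep internal subject preparation (see [esm_analysis()]); a
#'   list with `ep`, `info`, `trials_pc`, `fs`.
#' @param split a `split_plan`.
#' @param sig_cols column indices of the signature window within the
#'   epoch support grid.
#' @param tau_min,tau_max signature window in seconds.
#' @param tau_w locking half-width in seconds.
#' @param n_perm number of label shuffles (default 50).
#' @return array `[3 train types, 3 test types, n_tau]`, the mean
#'   locked ESM over permutations.
#' @export
permutation_baseline <- function(prep, split, sig_cols, tau_min, tau_max,
                                 tau_w = 0.5, n_perm = 50) {
  train_sel <- prep$info$trial_id %in% split$train
  test_prep <- .prep_test_events(prep, split$test)
  labels <- as.character(prep$info$event_type)
  acc <- 0
  idx_train <- which(train_sel)
  for (pp in seq_len(n_perm)) {
    lab_p <- labels
    lab_p[idx_train] <- labels[sample(idx_train)]
    sigs <- .signatures(prep$ep, lab_p, train_sel, sig_cols)
    acc <- acc + .split_locked(sigs, prep, test_prep,
                               tau_min, tau_max, tau_w)$mean
  }
  acc / n_perm
}

# core loop shared by esm_analysis (one signature window) and
# lag_esm_map (one window per lag): locked and baseline arrays
# [subject, split, e, f, tau]
.analysis_core <- function(preps, splits, sig_cols, tau_min, tau_max, tau_w,
                           n_perm) {
  n_s <- length(preps)
  fs <- preps[[1]]$fs
  n_tau <- 2L * round(tau_w * fs) + 1L
  locked <- array(NA_real_, c(n_s, length(splits), 3, 3, n_tau))
  baseline <- array(0, c(n_s, length(splits), 3, 3, n_tau))
  counts <- array(0L, c(n_s, length(splits), 3, 3))
  for (si in seq_len(n_s)) {
    prep <- preps[[si]]
    labels <- as.character(prep$info$event_type)
    for (mi in seq_along(splits)) {
      sp <- splits[[mi]]
      train_sel <- prep$info$trial_id %in% sp$train
      test_prep <- .prep_test_events(prep, sp$test)
      sigs <- .signatures(prep$ep, labels, train_sel, sig_cols)
      res <- .split_locked(sigs, prep, test_prep, tau_min, tau_max, tau_w)
      locked[si, mi, , , ] <- res$mean
      counts[si, mi, , ] <- res$cnt[, , (n_tau + 1L) %/% 2L]
      if (n_perm > 0)
        baseline[si, mi, , , ] <- permutation_baseline(
          prep, sp, sig_cols, tau_min, tau_max, tau_w, n_perm)
    }
  }
  list(locked = locked, baseline = baseline, counts = counts)
}

#' Baseline-corrected, aggregated ESM
#'
#' Subtracts the permutation baseline from the locked ESM, then takes
#' unweighted means first over the five splits and then over subjects
#' (per-subject curves are retained for group statistics). When cells
#' are undefined (no test events for a combination) they are dropped
#' from the means.
#'
#' @param locked,baseline arrays `[subject, split, e, f, tau]`.
#' @return list with `subject` (`[subject, e, f, tau]`) and `grand`
#'   (`[e, f, tau]`).
#' @export
corrected_esm <- function(locked, baseline) {
  d <- locked - baseline
  subj <- apply(d, c(1, 3, 4, 5), mean, na.rm = TRUE)
  grand <- apply(subj, c(2, 3, 4), mean, na.rm = TRUE)
  list(subject = subj, grand = grand)
}

#' Event-similarity decoding analysis
#'
#' Runs the full within-subject template-correlation decoding: for
#' every subject, split, and training event type it builds the event
#' signature from training trials, cross-correlates it (windowed,
#' demeaned, SD-normalized) with the component-projected signal of
#' every test trial, time-locks the resulting similarity trace around
#' the test events of every type, subtracts a label-permutation
#' baseline, and aggregates over splits and subjects.
#'
#' @param recordings list of (preprocessed) `eeg_recording`, one per
#'   subject, or a generator `function(subject_index)` returning one
#'   (with `n_subjects` given); the generator form keeps only one
#'   subject's raw data in memory at a time.
#' @param n_subjects number of subjects when `recordings` is a
#'   generator function.
#' @param events session-level `topo_events` (one item set).
#' @param trial_info data frame `trial_id`/`match_condition` (or a
#'   `mot_session`).
#' @param weights a [pca_weights()] object.
#' @param component component index to decode from.
#' @param tau_min,tau_max signature window in seconds (defaults
#'   -0.4/+0.4).
#' @param tau_w half-width of the event-locked window (default 0.5 s).
#' @param n_perm permutations for the baseline (default 50; 0 skips
#'   baseline correction).
#' @param seed optional seed for the permutation shuffles.
#' @return An object of class `esm_result`: list with `locked` and
#'   `baseline` (`[subject, split, e, f, tau]`), `corrected_subject`
#'   (`[subject, e, f, tau]`), `corrected` (`[e, f, tau]`), `tau`,
#'   `counts`, `component`, `n_perm`.
#' @export
esm_analysis <- function(recordings, events, trial_info, weights, component,
                         tau_min = -0.4, tau_max = 0.4, tau_w = 0.5,
                         n_perm = 50, seed = NULL, n_subjects = NULL) {
  if (!is.null(seed)) set.seed(seed)
  splits <- make_splits(trial_info)
  support <- c(tau_min, tau_max)
  preps <- .prep_all(recordings, n_subjects, events, weights, component,
                     support)
  sig_cols <- seq_along(preps[[1]]$sup_offs)
  core <- .analysis_core(preps, splits, sig_cols, tau_min, tau_max, tau_w,
                         n_perm)
  corr <- corrected_esm(core$locked, core$baseline)
  fs <- preps[[1]]$fs
  out <- list(locked = core$locked, baseline = core$baseline,
              corrected_subject = corr$subject, corrected = corr$grand,
              tau = seq.int(-round(tau_w * fs), round(tau_w * fs)) / fs,
              counts = core$counts, component = component, n_perm = n_perm)
  class(out) <- "esm_result"
  out
}

#' @export
print.esm_result <- function(x, ...) {
  cat(sprintf("<esm_result> component %d: %d subjects x %d splits, %d perms, tau %g..%g s\n",
              x$component, dim(x$locked)[1], dim(x$locked)[2], x$n_perm,
              min(x$tau), max(x$tau)))
  invisible(x)
}

#' Time-lag event-similarity map
#'
#' Repeats the decoding of [esm_analysis()] with the event signature
#' cropped to a sliding `window_len` window whose centre (the time
#' lag) moves across `lags`: negative lags probe signal *preceding*
#' the event, positive lags signal *following* it. Each lag is
#' baseline-corrected with its own label-permutation baseline; the
#' permutation random streams are restarted from the same seed at
#' every lag so that baseline noise is coupled across columns.
#'
#' @inheritParams esm_analysis
#' @param lags vector of window centres in seconds (default -0.3..0.3
#'   in 0.02 steps).
#' @param window_len cropped signature window length in seconds
#'   (default 0.4).
#' @return An object of class `lag_esm_map`: list with `grand`
#'   (`[e, f, tau, lag]`), `subject` (`[subject, e, f, tau, lag]`),
#'   `tau`, `lags`.
#' @export
lag_esm_map <- function(recordings, events, trial_info, weights, component,
                        lags = seq(-0.3, 0.3, by = 0.02), window_len = 0.4,
                        tau_w = 0.5, n_perm = 50, seed = NULL,
                        n_subjects = NULL) {
  splits <- make_splits(trial_info)
  support <- c(min(lags) - window_len / 2, max(lags) + window_len / 2)
  preps <- .prep_all(recordings, n_subjects, events, weights, component,
                     support)
  fs <- preps[[1]]$fs
  sup_offs <- preps[[1]]$sup_offs
  n_tau <- 2L * round(tau_w * fs) + 1L
  n_s <- length(preps)
  subj <- array(NA_real_, c(n_s, 3, 3, n_tau, length(lags)))
  for (li in seq_along(lags)) {
    tmin <- lags[li] - window_len / 2
    tmax <- lags[li] + window_len / 2
    cols <- which(sup_offs >= round(tmin * fs) & sup_offs <= round(tmax * fs))
    if (!is.null(seed)) set.seed(seed)
    core <- .analysis_core(preps, splits, cols, tmin, tmax, tau_w, n_perm)
    subj[, , , , li] <- corrected_esm(core$locked, core$baseline)$subject
  }
  grand <- apply(subj, c(2, 3, 4, 5), mean, na.rm = TRUE)
  out <- list(grand = grand, subject = subj,
              tau = seq.int(-round(tau_w * fs), round(tau_w * fs)) / fs,
              lags = lags, component = component, n_perm = n_perm)
  class(out) <- "lag_esm_map"
  out
}

#' Automatic decoding-component selection
#'
#' Scores candidate components by their training-set self-similarity:
#' signatures are built from all events, correlated with all trials,
#' and locked at events of the same type; the score is the mean locked
#' value at lag zero across the three types. The component with the
#' highest score is returned.
#'
#' @inheritParams esm_analysis
#' @param candidates component indices to score (default 1:8).
#' @return list with `component` (the argmax) and `scores`.
#' @export
select_component <- function(recordings, events, trial_info, weights,
                             candidates = 1:8, tau_min = -0.4, tau_max = 0.4) {
  candidates <- candidates[candidates <= nrow(weights$w)]
  all_trials <- if (inherits(trial_info, "mot_session"))
    session_trial_info(trial_info)$trial_id else trial_info$trial_id
  if (is.function(recordings))
    stop("select_component needs materialized recordings")
  scores <- vapply(candidates, function(comp) {
    val <- 0
    for (rec in recordings) {
      prep <- .prep_subject(rec, events, weights, comp, c(tau_min, tau_max))
      sigs <- .signatures(prep$ep, as.character(prep$info$event_type),
                          rep(TRUE, nrow(prep$info)),
                          seq_along(prep$sup_offs))
      res <- .split_locked(sigs, prep,
                           .prep_test_events(prep, unique(prep$info$trial_id)),
                           tau_min, tau_max, tau_w = 0.05)
      mid <- (dim(res$mean)[3] + 1L) %/% 2L
      val <- val + mean(diag(res$mean[, , mid]))
    }
    val / length(recordings)
  }, 0)
  list(component = candidates[which.max(scores)],
       scores = stats::setNames(scores, paste0("C", candidates)))
}
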