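test_that("splits partition the trials by probe-match condition", {
  ti <- data.frame(trial_id = 1:300,
                   match_condition = rep(0:4, each = 60)[sample(300)])
  sp <- make_splits(ti)
  expect_length(sp, 5)
  for (s in sp) {
    expect_length(s$test, 60)
    expect_length(s$train, 240)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), ti$trial_id)
    expect_true(all(ti$match_condition[match(s$test, ti$trial_id)] == s$m))
  }
  ti5 <- data.frame(trial_id = 1:5, match_condition = 0:4)
  sp5 <- make_splits(ti5)
  expect_equal(vapply(sp5, function(s) length(s$test), 0L), rep(1L, 5))
  expect_error(make_splits(data.frame(trial_id = 1, match_condition = NA)),
               "match_condition")
})

test_that("signatures are pooled means over training events", {
  set.seed(51)
  ep <- matrix(rnorm(8 * 21), 8, 21)
  info <- data.frame(trial_id = c(1, 1, 2, 2, 3, 3, 4, 4),
                     event_type = factor(
                       c("flip", "concave", "flip", "flip",
                         "convex", "flip", "concave", "flip"),
                       levels = event_types()))
  sig <- build_signature(ep, info, "flip", train_trials = c(1, 2, 3))
  rows <- c(1, 3, 4, 6)
  expect_equal(sig, colSums(ep[rows, ]) / 4)
  one <- build_signature(ep, info, "concave", train_trials = 1)
  expect_equal(one, ep[2, ])
  expect_error(build_signature(ep, info, "convex", train_trials = c(1, 2)),
               "convex")
})

test_that("esm_trace matches a naive sliding Pearson correlation", {
  set.seed(52)
  fs <- 250
  p <- as.numeric(stats::arima.sim(list(ar = 0.9), n = 1500))
  sig <- rnorm(101)   # -0.2..0.2 at 250 Hz
  tr <- esm_trace(p, sig, fs, -0.2, 0.2)
  naive <- rep(NA_real_, length(p))
  for (t in seq_along(p)) {
    idx <- t + (-50:50)
    if (min(idx) >= 1 && max(idx) <= length(p))
      naive[t] <- stats::cor(sig, p[idx])
  }
  expect_identical(is.na(tr), is.na(naive))
  expect_lt(max(abs(tr - naive), na.rm = TRUE), 1e-10)
  expect_true(all(abs(tr) <= 1, na.rm = TRUE))
  # asymmetric windows align the same way
  tr2 <- esm_trace(p, rnorm(76), fs, -0.1, 0.2)
  naive2 <- rep(NA_real_, 300)
  expect_identical(which(!is.na(tr2))[1], 1L + 25L)
})

test_that("a planted signature copy yields similarity one (and -1 negated)", {
  set.seed(53)
  fs <- 250
  sig <- rnorm(101)
  p <- rnorm(1200)
  p[600 + (-50:50)] <- 4 * sig + 2   # affine copy
  tr <- esm_trace(p, sig, fs, -0.2, 0.2)
  expect_equal(tr[600], 1)
  p[600 + (-50:50)] <- -sig
  expect_equal(esm_trace(p, sig, fs, -0.2, 0.2)[600], -1)
})

test_that("zero-variance windows are flagged and set to zero", {
  fs <- 250
  sig <- rnorm(51)
  p <- c(rep(0, 400), rnorm(200))
  tr <- esm_trace(p, sig, fs, -0.1, 0.1)
  expect_identical(tr[100], 0)
  expect_gt(attr(tr, "n_zero_variance"), 0)
})

test_that("esm_trace is shift-equivariant and scale-invariant", {
  set.seed(54)
  fs <- 250
  sig <- rnorm(101)
  p <- rnorm(900)
  d <- 13
  trA <- esm_trace(p, sig, fs, -0.2, 0.2)
  trB <- esm_trace(c(rnorm(d), p), sig, fs, -0.2, 0.2)
  expect_lt(max(abs(trA[100:800] - trB[100:800 + d])), 1e-12)
  trS <- esm_trace(2.7 * p, 0.3 * sig, fs, -0.2, 0.2)
  expect_lt(max(abs(trA - trS), na.rm = TRUE), 1e-10)
})

test_that("lock_esm pools trace values across events with edge handling", {
  fs <- 100
  traces <- list(`1` = c(rep(NA, 10), seq_len(300) / 100, rep(NA, 10)),
                 `2` = sin(seq_len(320) / 10))
  ev <- data.frame(trial_id = c(1L, 1L, 2L), time = c(1.0, 2.0, 0.3))
  out <- lock_esm(traces, ev, fs, tau_w = 0.5)
  expect_length(out$values, 101)
  # oracle: nested loop with pairwise NA exclusion
  offs <- -50:50
  acc <- numeric(101); cnt <- integer(101)
  for (i in 1:3) {
    tr <- traces[[as.character(ev$trial_id[i])]]
    idx <- round(ev$time[i] * fs) + 1L + offs
    v <- ifelse(idx >= 1 & idx <= length(tr), tr[pmax(pmin(idx, length(tr)), 1)],
                NA)
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]; cnt <- cnt + ok
  }
  expect_equal(out$values, ifelse(cnt > 0, acc / pmax(cnt, 1), NA))
  expect_equal(out$n_defined, cnt)
  # single event: the locked curve is just a trace slice
  one <- lock_esm(traces, ev[2, ], fs, tau_w = 0.2)
  expect_equal(one$values, traces[[1]][round(2 * fs) + 1 + (-20:20)])
  expect_error(lock_esm(traces, ev[0, ], fs), "no test events")
})

test_that("esm results are bounded, seeded, and analytically consistent", {
  ds <- fx_dataset()
  w <- fx_weights()
  ti <- session_trial_info(ds$session)
  res <- esm_analysis(fx_preprocessed(), ds$events_target, ti, w, 1,
                      n_perm = 3, seed = 99)
  expect_true(all(abs(res$locked) <= 1, na.rm = TRUE))
  res2 <- esm_analysis(fx_preprocessed(), ds$events_target, ti, w, 1,
                       n_perm = 3, seed = 99)
  expect_identical(res$baseline, res2$baseline)
  # corrected aggregation: subtracting the baseline then averaging over
  # splits and subjects, matching a direct computation
  d <- res$locked - res$baseline
  subj <- apply(d, c(1, 3, 4, 5), mean, na.rm = TRUE)
  expect_equal(res$corrected_subject, subj)
  expect_equal(res$corrected, apply(subj, c(2, 3, 4), mean, na.rm = TRUE))
  # baseline equal to locked would give exactly zero
  z <- corrected_esm(res$locked, res$locked)
  expect_true(all(z$grand[!is.na(z$grand)] == 0))
})

test_that("label permutation leaves locked ESM unchanged when kernels are identical", {
  # all three event types share one waveform, so labels are exchangeable
  # and the permutation baseline converges to the unpermuted curve
  ks <- event_kernels(250)
  ks$flip$waveform <- ks$concave$waveform <- ks$convex$waveform <-
    event_kernels(250)$concave$waveform
  ks$flip$latency_shift <- ks$convex$latency_shift <- 0.15
  ds <- fx_dataset()
  set.seed(60)
  rec <- simulate_recording(ds$session, ds$events_target,
                            synth_config(n_subjects = 1, sampling_rate = 250,
                                         snr = 3),
                            subject_id = 1, kernels = ks)
  rec <- preprocess(rec)
  w <- fx_weights()
  ti <- session_trial_info(ds$session)
  res <- esm_analysis(list(rec), ds$events_target, ti, w, 1,
                      n_perm = 40, seed = 7)
  dif <- res$locked - res$baseline
  # residual reflects signature sampling noise at 40 shuffles on a
  # 12-trial session; well below the locked-curve scale (~0.3)
  expect_lt(mean(abs(dif), na.rm = TRUE), 0.08)
  expect_lt(mean(dif, na.rm = TRUE), 0.04)
})

test_that("the lag map at lag zero equals the standard narrow-window analysis", {
  ds <- fx_dataset()
  w <- fx_weights()
  ti <- session_trial_info(ds$session)
  res <- esm_analysis(fx_preprocessed(), ds$events_target, ti, w, 1,
                      tau_min = -0.2, tau_max = 0.2, n_perm = 2, seed = 5)
  lm1 <- lag_esm_map(fx_preprocessed(), ds$events_target, ti, w, 1,
                     lags = 0, window_len = 0.4, n_perm = 2, seed = 5)
  expect_equal(lm1$grand[, , , 1], res$corrected)
  # each column equals an independent single-lag run
  lm2 <- lag_esm_map(fx_preprocessed(), ds$events_target, ti, w, 1,
                     lags = c(-0.1, 0.1), window_len = 0.4, n_perm = 2,
                     seed = 5)
  single <- lag_esm_map(fx_preprocessed(), ds$events_target, ti, w, 1,
                        lags = 0.1, window_len = 0.4, n_perm = 2, seed = 5)
  expect_equal(lm2$grand[, , , 2], single$grand[, , , 1])
})
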