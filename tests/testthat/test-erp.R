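test_that("preprocessing removes drift and is a proper high-pass", {
  fs <- 500
  n <- fs * 40
  tvec <- (seq_len(n) - 1) / fs
  ch <- topo_channels()
  data <- matrix(0, 32, n)
  data[1, ] <- 5 + sin(2 * pi * 0.05 * tvec)   # DC + sub-cutoff drift
  data[2, ] <- sin(2 * pi * 10 * tvec)         # passband
  rec <- fx_recording(data, ch, sampling_rate = fs, trial_duration = 39)
  out <- preprocess(rec)
  core <- (5 * fs):(35 * fs)   # avoid filter edge transients
  expect_lt(sd(out$data[1, core]) / sd(data[1, core] - 5), 10^(-20 / 20))
  expect_gt(sd(out$data[2, core]) / sd(data[2, core]), 10^(-1 / 20))
  expect_lt(mean(abs(out$data[1, core])), 0.05)
})

test_that("re-referencing subtracts the mastoid mean and is idempotent", {
  set.seed(41)
  ch <- topo_channels()
  data <- matrix(rnorm(32 * 500), 32, 500)
  rec <- fx_recording(data, ch)
  out <- preprocess(rec, highpass = NULL)
  ref <- colMeans(rec$data[c("TP9", "TP10"), ])
  expect_equal(out$data, rec$data - rep(ref, each = 32), ignore_attr = TRUE)
  out2 <- preprocess(out, highpass = NULL)
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  expect_error(preprocess(rec, reference = c("M1", "M2")), "M1")
})

test_that("epoching uses exact index arithmetic and drops edge events", {
  fs <- 500
  ch <- topo_channels()
  data <- matrix(rep(seq_len(2000), each = 32), 32, 2000)
  rec <- fx_recording(data, ch, sampling_rate = fs, trial_onsets = 1L,
                      trial_ids = 1L, trial_duration = 3.9)
  ev <- data.frame(trial_id = 1L, set_label = "target",
                   event_type = factor("flip", levels = event_types()),
                   time = 2, frame = 201L)
  ep <- epoch_recording(rec, ev)
  expect_equal(dim(ep$data), c(1, 32, 401))
  expect_equal(ep$data[1, 5, ], as.numeric(801:1201))
  expect_equal(ep$tau[c(1, 201, 401)], c(-0.4, 0, 0.4))
  # an event 100 ms from the recording start cannot host a -400 ms window
  ev2 <- ev; ev2$time <- 0.1
  ep2 <- epoch_recording(rec, rbind(ev, ev2))
  expect_identical(dim(ep2$data)[1], 1L)
  expect_identical(ep2$n_dropped, 1L)
})

test_that("grand averages pool over events, not over subject means", {
  set.seed(43)
  ch <- c("A", "B")
  mk_ep <- function(n_ev, subject) {
    d <- array(rnorm(n_ev * 2 * 5), c(n_ev, 2, 5))
    list(data = d, tau = seq(-0.004, 0.004, by = 0.002), channels = ch,
         sampling_rate = 500,
         info = data.frame(trial_id = seq_len(n_ev), set_label = "target",
                           event_type = factor(rep("flip", n_ev),
                                               levels = event_types()),
                           time = 1, frame = 1L, subject = subject),
         n_dropped = 0L) |> structure(class = "epoch_set")
  }
  e1 <- mk_ep(7, 1); e2 <- mk_ep(2, 2)   # unbalanced on purpose
  ga <- grand_average(combine_epochs(e1, e2), types = "flip")$flip
  # oracle: direct summation over every single epoch
  oracle <- (apply(e1$data, c(2, 3), sum) + apply(e2$data, c(2, 3), sum)) / 9
  expect_equal(unname(ga), oracle)
  naive <- (apply(e1$data, c(2, 3), mean) + apply(e2$data, c(2, 3), mean)) / 2
  expect_gt(max(abs(unname(ga) - naive)), 1e-3)
})

test_that("the occipital window contrast equals a plain sample mean", {
  ds <- fx_dataset()
  eps <- combine_epochs(lapply(fx_preprocessed(), epoch_recording,
                               events = ds$events_target))
  out <- transition_window_contrast(eps)
  chi <- match(c("O1", "Oz", "O2"), eps$channels)
  ti <- which(eps$tau >= 0.084 & eps$tau <= 0.128)
  for (r in sample(nrow(out), 3)) {
    sel <- eps$info$subject == out$subject[r] &
      eps$info$event_type == out$event_type[r]
    expect_equal(out$amplitude[r], mean(eps$data[sel, chi, ti]))
  }
  expect_error(transition_window_contrast(eps, window = c(0.3, 0.6)),
               "window")
  expect_error(transition_window_contrast(eps, channels = "Fp9"), "Fp9")
})

test_that("PCA weights are orthonormal, deterministic, and match eigen()", {
  ga <- grand_average(combine_epochs(lapply(fx_preprocessed(),
                                            epoch_recording,
                                            events = fx_dataset()$events_target)))
  w <- pca_weights(ga)
  G <- w$w %*% t(w$w)
  expect_lt(max(abs(G - diag(32))), 1e-8)
  expect_true(all(diff(w$explained_variance) <= 1e-12))
  # independent oracle: eigen-decomposition of the 32 x 32 covariance
  X <- do.call(rbind, lapply(ga, t))
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(w$explained_variance, eg$values, tolerance = 1e-8)
  for (k in 1:4)
    expect_equal(abs(w$w[k, ]), abs(eg$vectors[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading is positive
  for (k in 1:32) expect_gt(w$w[k, which.max(abs(w$w[k, ]))], 0)
})

test_that("a channel carrying all variance owns the first component", {
  tau <- seq(-0.1, 0.1, by = 0.004)
  ga <- lapply(stats::setNames(event_types(), event_types()), function(e) {
    m <- matrix(0, 4, length(tau), dimnames = list(c("A", "B", "C", "D"), NULL))
    m[2, ] <- sin(2 * pi * 5 * tau) * (1 + (e == "flip"))
    m
  })
  w <- suppressWarnings(pca_weights(ga))
  expect_equal(abs(w$w[1, ]), c(A = 0, B = 1, C = 0, D = 0), tolerance = 1e-10)
  expect_lt(w$n_valid, 4)
})

test_that("projection is the weighted channel sum and commutes with averaging", {
  ds <- fx_dataset()
  w <- fx_weights()
  rec <- fx_preprocessed()[[1]]
  pc <- project(rec, w, 3)
  expect_equal(pc, as.numeric(w$w[3, ] %*% rec$data))
  # identity weights return the corresponding channel
  wi <- w
  wi$w <- diag(32); colnames(wi$w) <- w$channels
  expect_equal(project(rec, wi, 5), unname(rec$data[5, ]))
  # averaging and projecting commute: grand-average then project equals
  # projecting epochs then averaging
  eps <- epoch_recording(rec, ds$events_target)
  ga <- grand_average(eps)
  pe <- project(eps, w, 2)
  for (e in event_types()) {
    sel <- eps$info$event_type == e
    expect_lt(max(abs(project(ga[[e]], w, 2) - colMeans(pe[sel, , drop = FALSE]))),
              1e-10)
  }
  expect_error(project(rec, w, 40), "component")
})

test_that("summing all back-projected components recovers the centred average", {
  ga <- grand_average(combine_epochs(lapply(fx_preprocessed(),
                                            epoch_recording,
                                            events = fx_dataset()$events_target)))
  w <- pca_weights(ga)
  X <- do.call(rbind, lapply(ga, t))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  scores <- Xc %*% t(w$w)
  expect_lt(max(abs(scores %*% w$w - Xc)), 1e-8)
})
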