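#' Full-pipeline configuration
#'
#' Bundles the per-stage configurations with the analysis parameters.
#' All defaults are the study-scale parameters: 300 trials, 38
#' subjects, 500 Hz, ±400 ms signature windows, 500 ms debounce and
#' boundary exclusions, 50 permutations, lags -300..300 ms in 20 ms
#' steps with 400 ms windows and a ±500 ms locking window. Reduce
#' `n_trials`/`n_subjects` (and optionally `lags`) for desk-scale
#' runs.
#'
#' @param motion a [motion_config()].
#' @param synth a [synth_config()].
#' @param n_trials trials per session (default 300).
#' @param component decoding component index, or `"auto"` to select by
#'   training-set self-similarity (see [select_component()]).
#' @param tau_min,tau_max signature window (seconds).
#' @param tau_w event-locked window half-width (seconds).
#' @param n_perm baseline permutations (default 50).
#' @param lags lag-map window centres in seconds; `NULL` skips the
#'   lag-map stage.
#' @param debounce,start_excl,end_excl event filtering parameters
#'   (seconds).
#' @param stats_alpha,stats_n_perm cluster-test level and permutation
#'   count.
#' @param seed global seed; per-stage seeds are derived from it by a
#'   fixed counter scheme so stages are independently reproducible.
#' @return An object of class `run_config`.
#' @export
run_config <- function(motion = motion_config(), synth = synth_config(),
                       n_trials = 300L, component = "auto",
                       tau_min = -0.4, tau_max = 0.4, tau_w = 0.5,
                       n_perm = 50L, lags = seq(-0.3, 0.3, by = 0.02),
                       debounce = 0.5, start_excl = 0.5, end_excl = 0.5,
                       stats_alpha = 0.05, stats_n_perm = 1000L,
                       seed = 1L) {
  cfg <- list(motion = motion, synth = synth, n_trials = as.integer(n_trials),
              component = component, tau_min = tau_min, tau_max = tau_max,
              tau_w = tau_w, n_perm = as.integer(n_perm), lags = lags,
              debounce = debounce, start_excl = start_excl,
              end_excl = end_excl, stats_alpha = stats_alpha,
              stats_n_perm = as.integer(stats_n_perm), seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

# deterministic per-stage seeds below 2^31
.stage_seed <- function(seed, k) (abs(seed) %% 1000003L) * 1000L + k

# content hash of any R object (used as cache key)
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# run `fun` unless a cached result for this key exists
.cached_stage <- function(cache_dir, stage, key, fun, verbose = TRUE) {
  path <- file.path(cache_dir, paste0(stage, "-", key, ".rds"))
  if (file.exists(path)) {
    if (verbose) message("[", stage, "] cached")
    return(readRDS(path))
  }
  if (verbose) message("[", stage, "] computing")
  val <- tryCatch(fun(), error = function(e)
    stop("stage '", stage, "' failed (inputs ", key, "): ",
         conditionMessage(e), call. = FALSE))
  saveRDS(val, path)
  val
}

#' Run the complete simulation and decoding pipeline
#'
#' Executes trajectory simulation, event detection, synthetic EEG
#' generation, preprocessing, grand averaging, PCA, component
#' selection, ESM decoding with permutation baseline, optional lag
#' maps, and group statistics, writing all artifacts plus a manifest
#' and a plain-text report into `out_dir`. Small stage outputs are
#' cached under `out_dir/cache` keyed by a content hash of their
#' configuration, so re-runs recompute only what changed; continuous
#' recordings are regenerated deterministically from their stage seed
#' instead of being stored.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return (invisibly) a list with the main products: `events`,
#'   `weights`, `component`, `esm`, `lagmap`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache <- file.path(out_dir, "cache")
  dir.create(cache, showWarnings = FALSE)
  sseed <- function(k) .stage_seed(config$seed, k)

  key_sess <- .hash_obj(list(config$motion, config$n_trials, sseed(1)))
  session <- .cached_stage(cache, "session", key_sess, function()
    generate_session(config$motion, config$n_trials, seed = sseed(1)),
    verbose)

  key_ev <- .hash_obj(list(key_sess, config$debounce, config$start_excl,
                           config$end_excl))
  events <- .cached_stage(cache, "events", key_ev, function() {
    list(target = detect_session_events(session, "target",
                                        debounce = config$debounce,
                                        start_excl = config$start_excl,
                                        end_excl = config$end_excl),
         distractor = detect_session_events(session, "distractor",
                                            debounce = config$debounce,
                                            start_excl = config$start_excl,
                                            end_excl = config$end_excl))
  }, verbose)
  write_event_table(events$target, file.path(out_dir, "events-target.csv"))
  write_event_table(events$distractor,
                    file.path(out_dir, "events-distractor.csv"))

  kernels <- event_kernels(config$synth$sampling_rate)
  topography <- occipital_topography()
  make_rec <- function(s) {
    set.seed(sseed(100L + s))
    rec <- simulate_recording(session, events$target, config$synth,
                              subject_id = s, kernels = kernels,
                              topography = topography)
    preprocess(rec)
  }

  # pass A: grand averages accumulated subject by subject (recordings
  # are regenerated rather than held in memory together)
  n_sub <- config$synth$n_subjects
  key_ga <- .hash_obj(list(key_ev, config$synth, config$tau_min,
                           config$tau_max, lapply(seq_len(n_sub), sseed)))
  ga <- .cached_stage(cache, "grand-average", key_ga, function() {
    sums <- NULL; counts <- NULL
    for (s in seq_len(n_sub)) {
      ep <- epoch_recording(make_rec(s), events$target,
                            config$tau_min, config$tau_max)
      for (e in event_types()) {
        sel <- ep$info$event_type == e
        m <- apply(ep$data[sel, , , drop = FALSE], c(2, 3), sum)
        if (is.null(sums)) {
          sums <- stats::setNames(vector("list", 3), event_types())
          counts <- stats::setNames(numeric(3), event_types())
        }
        sums[[e]] <- if (is.null(sums[[e]])) m else sums[[e]] + m
        counts[[e]] <- counts[[e]] + sum(sel)
      }
    }
    lapply(stats::setNames(event_types(), event_types()), function(e) {
      g <- sums[[e]] / counts[[e]]
      rownames(g) <- topo_channels()
      g
    })
  }, verbose)

  weights <- .cached_stage(cache, "pca-weights", .hash_obj(list(key_ga)),
                           function() pca_weights(ga), verbose)
  utils::write.csv(as.data.frame(weights$w),
                   file.path(out_dir, "pca-weights.csv"))

  trial_info <- session_trial_info(session)

  # recordings are regenerated from their stage seeds one subject at a
  # time rather than held in memory together
  component <- config$component
  if (identical(component, "auto")) {
    scores <- 0
    for (s in seq_len(n_sub))
      scores <- scores + select_component(
        list(make_rec(s)), events$target, trial_info, weights,
        tau_min = config$tau_min, tau_max = config$tau_max)$scores
    component <- as.integer(which.max(scores))
    if (verbose) message("[component] auto-selected C", component)
  }

  key_esm <- .hash_obj(list(key_ga, component, config$tau_w, config$n_perm,
                            sseed(2)))
  esm <- .cached_stage(cache, "esm", key_esm, function()
    esm_analysis(make_rec, events$target, trial_info, weights, component,
                 tau_min = config$tau_min, tau_max = config$tau_max,
                 tau_w = config$tau_w, n_perm = config$n_perm,
                 seed = sseed(2), n_subjects = n_sub), verbose)

  lagmap <- NULL
  if (!is.null(config$lags)) {
    key_lag <- .hash_obj(list(key_esm, config$lags))
    lagmap <- .cached_stage(cache, "lagmap", key_lag, function()
      lag_esm_map(make_rec, events$target, trial_info, weights, component,
                  lags = config$lags, tau_w = config$tau_w,
                  n_perm = config$n_perm, seed = sseed(3),
                  n_subjects = n_sub), verbose)
  }

  key_stats <- .hash_obj(list(key_esm, config$stats_alpha,
                              config$stats_n_perm, sseed(4)))
  stats_out <- .cached_stage(cache, "stats", key_stats, function() {
    types <- event_types()
    set.seed(sseed(4))
    cluster <- list()
    for (ei in 1:3) for (fi in 1:3) {
      cr <- cluster_permutation_t(esm$corrected_subject[, ei, fi, ],
                                  alpha = config$stats_alpha,
                                  n_perm = config$stats_n_perm)
      sig <- cr$clusters[cr$clusters$p <= config$stats_alpha, , drop = FALSE]
      if (nrow(sig)) {
        sig$train <- types[ei]; sig$test <- types[fi]
        cluster[[length(cluster) + 1L]] <- sig
      }
    }
    tanova <- lapply(stats::setNames(1:3, types), function(fi)
      pointwise_repeated_F(esm$corrected_subject[, , fi, ]))
    hcorr <- list()
    for (fi in 1:3) for (ei in setdiff(1:3, fi)) {
      h <- event_histogram(events$target, types[fi], types[ei],
                           tau_w = config$tau_w)
      hc <- esm_histogram_correlation(esm$corrected[ei, fi, ], esm$tau, h)
      hcorr[[paste(types[fi], types[ei], sep = ".")]] <- hc
    }
    list(clusters = if (length(cluster)) do.call(rbind, cluster) else NULL,
         tanova = tanova, histogram_correlations = hcorr)
  }, verbose)

  manifest <- list(
    package_version = as.character(utils::packageVersion("topotrack")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = list(session = sseed(1), esm = sseed(2), lagmap = sseed(3),
                       stats = sseed(4),
                       recordings = vapply(seq_len(n_sub),
                                           function(s) sseed(100L + s), 0)),
    stage_keys = list(session = key_sess, events = key_ev,
                      grand_average = key_ga, esm = key_esm,
                      stats = key_stats),
    component = component,
    config_hash = .hash_obj(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_report(file.path(out_dir, "report.txt"), events, weights, component,
                esm, stats_out)
  invisible(list(events = events, weights = weights, component = component,
                 esm = esm, lagmap = lagmap, stats = stats_out,
                 manifest = manifest))
}

.write_report <- function(path, events, weights, component, esm, stats_out) {
  types <- event_types()
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("topotrack pipeline report")
  w("=========================")
  w("")
  tab <- table(events$target$event_type)
  w("target-set events:    flip %d, concave %d, convex %d",
    tab[["flip"]], tab[["concave"]], tab[["convex"]])
  tab <- table(events$distractor$event_type)
  w("distractor-set events: flip %d, concave %d, convex %d",
    tab[["flip"]], tab[["concave"]], tab[["convex"]])
  pv <- 100 * weights$explained_variance / sum(weights$explained_variance)
  w("")
  w("PCA variance explained (C1..C6): %s",
    paste(sprintf("%.1f%%", pv[seq_len(min(6, length(pv)))]), collapse = " "))
  w("decoding component: C%d", component)
  w("")
  mid <- which.min(abs(esm$tau))
  for (ei in 1:3) {
    vals <- vapply(1:3, function(fi) esm$corrected[ei, fi, mid], 0)
    w("corrected ESM at event time (train %s): %s", types[ei],
      paste(sprintf("%s %.4f", types, vals), collapse = ", "))
  }
  w("")
  if (!is.null(stats_out$clusters)) {
    w("significant clusters (corrected p <= alpha):")
    for (i in seq_len(nrow(stats_out$clusters))) {
      cl <- stats_out$clusters[i, ]
      w("  train %s / test %s: mass %.2f, p = %.4f",
        cl$train, cl$test, cl$mass, cl$p)
    }
  } else {
    w("no significant clusters")
  }
}

# ---- event table and recording IO -----------------------------------

#' Write / read transition event tables
#'
#' Event tables round-trip losslessly through CSV or JSON (chosen by
#' the file extension). Times are stored in seconds.
#'
#' @param events a `topo_events` data frame.
#' @param path output path ending in `.csv` or `.json`.
#' @return `write_event_table` returns `path` invisibly;
#'   `read_event_table` returns a `topo_events` data frame.
#' @export
write_event_table <- function(events, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(events)
  df$event_type <- as.character(df$event_type)
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "columns", digits = NA)
  } else stop("unsupported extension: ", ext)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else stop("unsupported extension: ", ext)
  need <- c("trial_id", "set_label", "event_type", "time", "frame")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$event_type), event_types())
  if (length(bad))
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  df <- df[, need]
  df$trial_id <- as.integer(df$trial_id)
  df$frame <- as.integer(df$frame)
  df$event_type <- factor(df$event_type, levels = event_types())
  class(df) <- c("topo_events", "data.frame")
  df
}

#' Write / read continuous recordings
#'
#' Recordings are serialized as RDS (R's native binary format); the
#' object round-trips exactly.
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @return `write_recording` returns `path` invisibly;
#'   `read_recording` returns the `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "eeg_recording"))
    stop("file does not contain an eeg_recording")
  rec
}
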