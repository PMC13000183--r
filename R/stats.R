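# connected components of a logical mask; 1-D runs or 4-connected 2-D
.label_clusters <- function(mask) {
  if (is.null(dim(mask)) || length(dim(mask)) == 1L) {
    lab <- integer(length(mask))
    r <- rle(as.logical(mask))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    k <- 0L
    for (i in seq_along(r$values)) {
      if (r$values[i]) {
        k <- k + 1L
        lab[starts[i]:ends[i]] <- k
      }
    }
    return(lab)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- matrix(c(i, j), 1)
      while (nrow(queue)) {
        cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        ci <- cur[1]; cj <- cur[2]
        if (ci < 1 || ci > nr || cj < 1 || cj > nc) next
        if (!mask[ci, cj] || lab[ci, cj] != 0L) next
        lab[ci, cj] <- k
        queue <- rbind(queue, c(ci - 1L, cj), c(ci + 1L, cj),
                       c(ci, cj - 1L), c(ci, cj + 1L))
      }
    }
  }
  lab
}

# one-sample t statistics per column; zero-variance points give t = 0
.col_t <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- (colSums(x * x) - n * m * m) / (n - 1)
  v <- pmax(v, 0)
  t <- ifelse(v <= 1e-300, 0, m / sqrt(v / n))
  t
}

# max positive supra-threshold cluster mass of a t vector/matrix
.max_mass <- function(tv, thr, dims) {
  if (!is.null(dims)) dim(tv) <- dims
  mask <- tv > thr
  if (!any(mask)) return(0)
  lab <- .label_clusters(mask)
  max(vapply(seq_len(max(lab)), function(k) sum(tv[lab == k]), 0))
}

#' Cluster-based permutation test of one-sample curves or maps
#'
#' Pointwise one-sample t-tests against zero; contiguous
#' supra-threshold points (runs for curves, 4-connected components for
#' 2-D maps) form clusters whose mass is the sum of their t values.
#' The null distribution of the maximum cluster mass is obtained by
#' randomly sign-flipping whole subjects (exhaustively over all `2^n`
#' flips when `exact = TRUE`, by Monte Carlo otherwise); the corrected
#' p of a cluster is the fraction of flips whose maximum mass is at
#' least the observed mass. One-sided by design; `alternative =
#' "less"` negates the data first.
#'
#' @param x numeric matrix `subjects x points`, or 3-D array
#'   `subjects x rows x cols` for 2-D maps.
#' @param alpha primary threshold level for the pointwise t (default
#'   0.05, one-sided, `n - 1` df).
#' @param n_perm number of random sign-flips (default 1000; a warning
#'   is issued below 100).
#' @param alternative `"greater"` (default) or `"less"`.
#' @param exact enumerate all `2^n` sign patterns (requires `n <= 20`).
#' @param seed optional seed for the Monte Carlo flips.
#' @return An object of class `cluster_result`: list with `clusters`
#'   (data frame: id, size, mass, p), `label` (cluster labels over the
#'   grid), `t` (pointwise statistics), `threshold`, `alpha`,
#'   `n_perm`, `exact`.
#' @export
cluster_permutation_t <- function(x, alpha = 0.05, n_perm = 1000,
                                  alternative = c("greater", "less"),
                                  exact = FALSE, seed = NULL) {
  alternative <- match.arg(alternative)
  dims <- NULL
  if (length(dim(x)) == 3L) {
    dims <- dim(x)[2:3]
    x <- matrix(x, nrow = dim(x)[1])
  }
  x <- as.matrix(x)
  if (alternative == "less") x <- -x
  n <- nrow(x)
  if (n < 2) stop("need at least 2 subjects")
  if (!exact && n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  if (!is.null(seed)) set.seed(seed)

  tv <- .col_t(x)
  thr <- stats::qt(1 - alpha, df = n - 1)
  tgrid <- tv
  if (!is.null(dims)) dim(tgrid) <- dims
  mask <- tgrid > thr
  lab <- .label_clusters(mask)
  nclus <- max(lab)
  masses <- if (nclus > 0)
    vapply(seq_len(nclus), function(k) sum(tgrid[lab == k]), 0) else numeric(0)

  # null: sign flips; only the column means change under a flip, the
  # column sums of squares are invariant
  ss <- colSums(x * x)
  if (exact) {
    if (n > 20) stop("exact enumeration limited to n <= 20 subjects")
    E <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    E <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
  }
  M <- (E %*% x) / n
  null_max <- numeric(nrow(E))
  for (b in seq_len(nrow(E))) {
    v <- pmax((ss - n * M[b, ]^2) / (n - 1), 0)
    tb <- ifelse(v <= 1e-300, 0, M[b, ] / sqrt(v / n))
    null_max[b] <- .max_mass(tb, thr, dims)
  }
  p <- if (exact) {
    vapply(masses, function(ms) mean(null_max >= ms - 1e-12), 0)
  } else {
    vapply(masses, function(ms) (1 + sum(null_max >= ms - 1e-12)) /
             (nrow(E) + 1), 0)
  }
  clusters <- data.frame(id = seq_len(nclus),
                         size = if (nclus > 0)
                           vapply(seq_len(nclus), function(k) sum(lab == k), 0L)
                         else integer(0),
                         mass = masses, p = p)
  out <- list(clusters = clusters, label = lab, t = tgrid, threshold = thr,
              alpha = alpha, n_perm = nrow(E), exact = exact,
              null_max = null_max)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), threshold t > %.3f (%s)\n",
              nrow(x$clusters), x$threshold,
              if (x$exact) "exact" else paste0(x$n_perm, " flips")))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Pointwise one-factor repeated-measures F
#'
#' Standard one-factor (within-subject) repeated-measures F statistic
#' at every grid point, computed from sums of squares; no sphericity
#' correction is applied and the p-values are reported as uncorrected.
#'
#' @param y numeric array `subjects x conditions x points`.
#' @return list with `F`, `p` (vectors over points), `df1`, `df2`.
#' @export
pointwise_repeated_F <- function(y) {
  stopifnot(length(dim(y)) == 3L)
  if (anyNA(y)) stop("missing cells are not supported")
  n_s <- dim(y)[1]; n_c <- dim(y)[2]; n_p <- dim(y)[3]
  stopifnot(n_s >= 2, n_c >= 2)
  ms <- apply(y, c(1, 3), mean)          # subject means  [s x p]
  mc <- apply(y, c(2, 3), mean)          # condition means [c x p]
  gm <- colMeans(ms)                     # grand mean      [p]
  ss_cond <- n_s * colSums((mc - rep(gm, each = n_c))^2)
  resid <- y -
    aperm(array(ms, c(n_s, n_p, n_c)), c(1, 3, 2)) -
    aperm(array(mc, c(n_c, n_p, n_s)), c(3, 1, 2)) +
    aperm(array(gm, c(n_p, n_s, n_c)), c(2, 3, 1))
  ss_err <- apply(resid^2, 3, sum)
  df1 <- n_c - 1L
  df2 <- (n_c - 1L) * (n_s - 1L)
  Fv <- (ss_cond / df1) / pmax(ss_err / df2, .Machine$double.xmin)
  Fv[ss_cond <= 1e-300 & ss_err <= 1e-300] <- 0
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Histogram of event co-occurrences
#'
#' Counts events of one type in a window around every event of a
#' reference type (within the same trial and item set), binned over
#' `[-tau_w, tau_w]`.
#'
#' @param events a `topo_events` data frame.
#' @param ref_type reference (locking) event type.
#' @param rel_type counted event type.
#' @param tau_w half-width in seconds (default 0.5).
#' @param bin bin width in seconds (default 0.02).
#' @return An object of class `event_histogram`: list with `counts`,
#'   `mids`, `breaks`, `n_ref`.
#' @export
event_histogram <- function(events, ref_type, rel_type, tau_w = 0.5,
                            bin = 0.02) {
  breaks <- seq(-tau_w, tau_w, by = bin)
  dts <- numeric(0)
  refs <- events[events$event_type == ref_type, , drop = FALSE]
  rels <- events[events$event_type == rel_type, , drop = FALSE]
  for (i in seq_len(nrow(refs))) {
    same <- rels$trial_id == refs$trial_id[i]
    if (ref_type == rel_type)
      same <- same & abs(rels$time - refs$time[i]) > 1e-12
    dt <- rels$time[same] - refs$time[i]
    dts <- c(dts, dt[dt >= -tau_w & dt <= tau_w])
  }
  h <- graphics::hist(dts, breaks = breaks, plot = FALSE)
  out <- list(counts = h$counts, mids = h$mids, breaks = breaks,
              n_ref = nrow(refs))
  class(out) <- "event_histogram"
  out
}

#' Correlation between an ESM time course and an event histogram
#'
#' Linearly interpolates the histogram counts onto the ESM tau grid
#' and computes the Pearson correlation between the two curves.
#'
#' @param values ESM values over tau.
#' @param tau tau grid in seconds.
#' @param hist an [event_histogram()].
#' @return list with `r`, `p` (two-sided), `n`. Constant inputs give a
#'   missing `r` with a message.
#' @export
esm_histogram_correlation <- function(values, tau, hist) {
  hv <- stats::approx(hist$mids, hist$counts, xout = tau, rule = 2)$y
  ok <- !is.na(values) & !is.na(hv)
  if (stats::sd(values[ok]) == 0 || stats::sd(hv) == 0) {
    message("constant input: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- stats::cor.test(values[ok], hv[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Median split into performance groups
#'
#' Splits subjects into high- and low-performance groups by the
#' median of their error rates; subjects exactly at the median are
#' assigned by the parity of their subject id (even ids go to the
#' high-performance group), which makes the split deterministic even
#' under ties.
#'
#' @param error_rates numeric vector of per-subject overall error
#'   rates.
#' @param subject_ids integer ids (default `seq_along(error_rates)`).
#' @return factor with levels `high`/`low`, named by subject id.
#' @export
performance_split <- function(error_rates, subject_ids = seq_along(error_rates)) {
  med <- stats::median(error_rates)
  grp <- ifelse(error_rates < med, "high",
                ifelse(error_rates > med, "low",
                       ifelse(subject_ids %% 2 == 0, "high", "low")))
  factor(stats::setNames(grp, subject_ids), levels = c("high", "low"))
}
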