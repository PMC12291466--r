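#' Sample distance correlation
#'
#' Distance correlation between two equal-length samples, computed from
#' first principles: pairwise Euclidean distance matrices, double
#' centering, \eqn{dCov^2 = \mathrm{mean}(A \circ B)} and
#' \eqn{dCorr = dCov / \sqrt[4]{dVar_x\, dVar_y}}. Unlike Pearson
#' correlation, the population distance correlation is zero if and only if
#' the variables are independent, which is what makes it usable as a proxy
#' for how far a droplet population is from the size-independent
#' composition expected at equilibrium. When either marginal is constant
#' the statistic is defined as 0.
#'
#' @param x,y numeric vectors of equal length \code{n >= 2}.
#' @return distance correlation in \[0, 1\].
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  a <- as.matrix(stats::dist(x))
  b <- as.matrix(stats::dist(y))
  A <- a - rowMeans(a) - rep(colMeans(a), each = n) + mean(a)
  B <- b - rowMeans(b) - rep(colMeans(b), each = n) + mean(b)
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  denom <- sqrt(dvarx * dvary)
  if (denom <= 0) return(0)
  v <- dcov2 / denom
  if (v <= 0) 0 else min(1, sqrt(v))
}

#' Bootstrap distance correlation of a droplet population
#'
#' Distance correlation between refractive index and diameter,
#' dCorr(n_p, d_p), with uncertainty from resampling droplets with
#' replacement. Large values indicate size-dependent composition, the
#' signature of a population far from equilibrium.
#'
#' @param snapshot a \code{population_snapshot} with at least 10 records.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed for reproducibility.
#' @return object of class \code{"dcorr_result"}: \code{estimate},
#'   \code{bootstrap_se}, \code{bootstrap_interval} (percentile 2.5-97.5),
#'   \code{n_boot}, \code{seed}, \code{n}, \code{degenerate}.
#' @export
bootstrap_dcorr <- function(snapshot, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(snapshot, "population_snapshot"))
  d <- snapshot$records$diameter_um
  np <- snapshot$records$refractive_index
  n <- length(d)
  if (n < 10L) {
    stop("need at least 10 droplets for a bootstrap estimate", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  est <- distance_correlation(np, d)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    distance_correlation(np[idx], d[idx])
  }, numeric(1))
  degenerate <- n_boot < 2L
  structure(list(estimate = est,
                 bootstrap_se = if (degenerate) 0 else stats::sd(boot),
                 bootstrap_interval = if (degenerate) c(est, est) else
                   unname(stats::quantile(boot, c(0.025, 0.975))),
                 n_boot = n_boot, seed = seed, n = n,
                 degenerate = degenerate),
            class = "dcorr_result")
}

#' @export
print.dcorr_result <- function(x, ...) {
  cat(sprintf(
    "dCorr(n_p, d_p) = %.3f +/- %.3f (bootstrap, B = %d, n = %d)\n",
    x$estimate, x$bootstrap_se, x$n_boot, x$n))
  if (x$degenerate) cat("  [degenerate: too few resamples for an SE]\n")
  invisible(x)
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' \eqn{JSD = \frac12 KL(P\|M) + \frac12 KL(Q\|M)} with
#' \eqn{M = (P+Q)/2}, logarithms base 2 so the divergence lies in
#' \[0, 1\] with 1 attained on disjoint supports. Inputs are smoothed
#' additively and renormalized.
#'
#' @param p,q non-negative vectors of equal length (normalized internally).
#' @param eps additive smoothing constant.
#' @return divergence in bits, in \[0, 1\].
#' @export
jsd_discrete <- function(p, q, eps = 1e-12) {
  if (length(p) != length(q)) stop("p and q must align", call. = FALSE)
  p <- p + eps; q <- q + eps
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) sum(a * (log2(a) - log2(b)))
  v <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  min(1, max(0, v))
}

#' Jensen-Shannon divergence between two measured samples
#'
#' Histograms both samples on shared bin edges spanning their pooled range
#' and returns the divergence of the two normalized histograms. Used to
#' score run-to-run reproducibility of size measurements: identical runs
#' give 0, completely non-overlapping runs give 1.
#'
#' @param samples_a,samples_b numeric samples, non-empty.
#' @param bins number of bins, or \code{"fd"} (default) for the
#'   Freedman-Diaconis rule on the pooled sample.
#' @param eps additive smoothing for empty bins.
#' @return object of class \code{"jsd_result"}: \code{value},
#'   \code{bin_edges}, \code{counts_a}, \code{counts_b}.
#' @export
jensen_shannon <- function(samples_a, samples_b, bins = "fd", eps = 1e-12) {
  if (length(samples_a) < 1L || length(samples_b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pooled <- c(samples_a, samples_b)
  if (identical(bins, "fd")) {
    iqr <- stats::IQR(pooled)
    if (iqr > 0) {
      h <- 2 * iqr / length(pooled)^(1 / 3)
      bins <- max(1L, ceiling(diff(range(pooled)) / h))
    } else bins <- 10L
  }
  rng <- range(pooled)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  ca <- graphics::hist(samples_a, breaks = edges, plot = FALSE)$counts
  cb <- graphics::hist(samples_b, breaks = edges, plot = FALSE)$counts
  structure(list(value = jsd_discrete(ca, cb, eps = eps),
                 bin_edges = edges, counts_a = ca, counts_b = cb),
            class = "jsd_result")
}

#' @export
print.jsd_result <- function(x, ...) {
  cat(sprintf("Jensen-Shannon divergence = %.4f bits (%d bins)\n",
              x$value, length(x$counts_a)))
  invisible(x)
}

#' Distance-correlation time course
#'
#' Applies [bootstrap_dcorr()] to each snapshot of an ordered dataset,
#' producing the recovery/perturbation curves used to follow a population
#' as it relaxes toward (or is driven away from) equilibrium. Snapshots
#' that fail the preconditions contribute an error entry rather than
#' aborting the sweep.
#'
#' @param dataset a \code{condensate_timeseries} (or list of snapshots).
#' @param n_boot bootstrap resamples per snapshot.
#' @param seed integer seed; each snapshot gets a derived sub-seed.
#' @return object of class \code{"dcorr_timecourse"}: data.frame
#'   \code{series} (time, estimate, se, lo, hi) plus the per-snapshot
#'   results and any errors.
#' @export
dcorr_timecourse <- function(dataset, n_boot = 1000, seed = NULL) {
  snaps <- if (inherits(dataset, "condensate_timeseries")) {
    dataset$snapshots
  } else dataset
  results <- vector("list", length(snaps))
  errors <- vector("list", length(snaps))
  for (i in seq_along(snaps)) {
    sub_seed <- if (is.null(seed)) NULL else seed + i
    results[[i]] <- tryCatch(
      bootstrap_dcorr(snaps[[i]], n_boot = n_boot, seed = sub_seed),
      error = function(e) {
        errors[[i]] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(results, is.null, logical(1))
  series <- data.frame(
    time_s = vapply(snaps[ok], snapshot_time, numeric(1)),
    estimate = vapply(results[ok], `[[`, numeric(1), "estimate"),
    se = vapply(results[ok], `[[`, numeric(1), "bootstrap_se"),
    lo = vapply(results[ok], function(r) r$bootstrap_interval[1], numeric(1)),
    hi = vapply(results[ok], function(r) r$bootstrap_interval[2], numeric(1)))
  structure(list(series = series, results = results, errors = errors,
                 n_boot = n_boot, seed = seed),
            class = "dcorr_timecourse")
}

#' @export
print.dcorr_timecourse <- function(x, ...) {
  cat(sprintf("dCorr(n_p, d_p) time course over %d snapshots\n",
              nrow(x$series)))
  print(x$series, row.names = FALSE)
  invisible(x)
}

#' @export
plot.dcorr_timecourse <- function(x, ...) {
  s <- x$series
  graphics::plot(s$time_s, s$estimate, type = "b", pch = 19,
                 ylim = c(0, 1), xlab = "time (s)",
                 ylab = "dCorr(n_p, d_p)", ...)
  graphics::arrows(s$time_s, s$lo, s$time_s, s$hi,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
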