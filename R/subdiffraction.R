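#' Density-based clustering of localizations (DBSCAN)
#'
#' First-principles implementation of the original density-reachability
#' algorithm with Euclidean distances: points with at least
#' \code{min_pts} neighbors within \code{eps_nm} (counting themselves)
#' are core points; clusters are the connected components of the
#' core-point graph plus any border points within \code{eps_nm} of a
#' core; everything else is noise. Labeling is deterministic up to
#' cluster-id permutation (ids are assigned in order of the first core
#' point encountered).
#'
#' @param points a \code{localization_set}, or a data.frame/matrix with
#'   x/y coordinates in its first two columns.
#' @param eps_nm neighborhood radius (same units as the coordinates).
#' @param min_pts minimum neighborhood size for a core point (>= 1),
#'   counting the point itself.
#' @return object of class \code{"cluster_labeling"}: integer
#'   \code{label} per point (0 = noise), logical \code{core},
#'   \code{n_clusters}, \code{eps_nm}, \code{min_pts}.
#' @export
dbscan_cluster <- function(points, eps_nm, min_pts) {
  if (inherits(points, "localization_set")) points <- points$points
  xy <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(xy) <- "double"
  if (eps_nm <= 0) stop("eps must be positive", call. = FALSE)
  if (min_pts < 1) stop("min_pts must be at least 1", call. = FALSE)
  n <- nrow(xy)
  if (n == 0L) {
    return(structure(list(label = integer(0), core = logical(0),
                          n_clusters = 0L, eps_nm = eps_nm,
                          min_pts = min_pts),
                     class = "cluster_labeling"))
  }
  if (!all(is.finite(xy))) stop("coordinates must be finite", call. = FALSE)
  dm <- as.matrix(stats::dist(xy))
  nb <- dm <= eps_nm            # includes self on the diagonal
  core <- rowSums(nb) >= min_pts
  label <- integer(n)           # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || label[i] != 0L) next
    cl <- cl + 1L
    # expand the cluster from this seed core point (BFS over cores)
    frontier <- i
    label[i] <- cl
    while (length(frontier) > 0L) {
      reach <- which(colSums(nb[frontier, , drop = FALSE]) > 0L)
      new <- reach[label[reach] == 0L]
      label[new] <- cl
      frontier <- new[core[new]]
    }
  }
  structure(list(label = label, core = core,
                 n_clusters = cl, eps_nm = eps_nm, min_pts = min_pts),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("DBSCAN labeling: %d clusters, %d noise points of %d total\n",
              x$n_clusters, sum(x$label == 0L), length(x$label)))
  invisible(x)
}

#' Per-cluster localization counts
#'
#' Counts localizations in each cluster and the number of outliers
#' (noise). Totals conserve the point count.
#'
#' @param labeling a [dbscan_cluster()] result.
#' @return list with \code{counts} (named by cluster id),
#'   \code{n_outliers}, \code{n_total}.
#' @export
cluster_summary <- function(labeling) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  lab <- labeling$label
  cl <- lab[lab != 0L]
  counts <- if (length(cl) > 0L) {
    tab <- table(cl)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  list(counts = counts,
       n_outliers = sum(lab == 0L),
       n_total = length(lab))
}

#' Temporal image correlation (TICS) map
#'
#' Per-pixel Pearson correlation between the intensity time series
#' \eqn{I(t)} and its lagged copy \eqn{I(t+\tau)} over all valid frame
#' pairs. High correlation marks static regions; values near zero mark
#' pixels dominated by fast intensity fluctuations (mobile molecules).
#' Pixels with zero temporal variance are static by definition and are
#' assigned correlation 1, flagged in the \code{constant} map. Sweep
#' \code{lag_frames} to probe the persistence of the dynamics.
#'
#' @param stack an \code{image_stack} (or a height x width x frames array).
#' @param lag_frames lag \eqn{\tau} in frames (default 1).
#' @return object of class \code{"tics_map"}: \code{values} (matrix in
#'   \[-1, 1\]), \code{constant} (logical matrix), \code{lag_frames},
#'   \code{frame_interval_ms}.
#' @export
tics_map <- function(stack, lag_frames = 1) {
  interval <- 20
  if (inherits(stack, "image_stack")) {
    interval <- stack$frame_interval_ms
    stack <- stack$data
  }
  stopifnot(length(dim(stack)) == 3L)
  nf <- dim(stack)[3]
  if (lag_frames < 1 || lag_frames + 1 >= nf) {
    stop("need frame count > lag_frames + 1", call. = FALSE)
  }
  h <- dim(stack)[1]; w <- dim(stack)[2]
  m <- matrix(aperm(stack, c(3, 1, 2)), nrow = nf)  # frames x pixels
  a <- m[1:(nf - lag_frames), , drop = FALSE]
  b <- m[(1 + lag_frames):nf, , drop = FALSE]
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  num <- colSums(ca * cb)
  den <- sqrt(colSums(ca^2) * colSums(cb^2))
  vals <- ifelse(den > 0, num / den, 1)
  vals <- pmin(1, pmax(-1, vals))
  structure(list(values = matrix(vals, h, w),
                 constant = matrix(den <= 0, h, w),
                 lag_frames = lag_frames,
                 frame_interval_ms = interval),
            class = "tics_map")
}

#' @export
print.tics_map <- function(x, ...) {
  cat(sprintf(
    "TICS map %dx%d, lag %d frame(s) (%g ms): correlation %.3f to %.3f\n",
    nrow(x$values), ncol(x$values), x$lag_frames,
    x$lag_frames * x$frame_interval_ms,
    min(x$values), max(x$values)))
  invisible(x)
}

#' Histogram of TICS correlation values
#'
#' Normalized frequency distribution of per-pixel correlation values over
#' \[-1, 1\], optionally restricted to a mask (for example, the pixels
#' inside one condensate). Normalized to unit area so distributions from
#' different conditions are directly comparable.
#'
#' @param map a [tics_map()] result.
#' @param mask logical matrix selecting pixels; default all.
#' @param bins number of bins over \[-1, 1\] (default 50).
#' @return object of class \code{"tics_histogram"}: \code{breaks},
#'   \code{density} (unit area), \code{counts}, \code{n_pixels}.
#' @export
tics_histogram <- function(map, mask = NULL, bins = 50) {
  stopifnot(inherits(map, "tics_map"))
  v <- map$values
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(v)))
    v <- v[mask]
  }
  v <- as.numeric(v)
  if (length(v) < 1L) {
    stop("mask selects no pixels", call. = FALSE)
  }
  breaks <- seq(-1, 1, length.out = bins + 1L)
  hh <- graphics::hist(v, breaks = breaks, plot = FALSE)
  width <- diff(breaks)[1]
  structure(list(breaks = breaks,
                 density = hh$counts / (sum(hh$counts) * width),
                 counts = hh$counts,
                 n_pixels = length(v)),
            class = "tics_histogram")
}

#' @export
print.tics_histogram <- function(x, ...) {
  cat(sprintf("TICS correlation histogram: %d pixels in %d bins\n",
              x$n_pixels, length(x$counts)))
  invisible(x)
}

#' @export
plot.tics_histogram <- function(x, ...) {
  mid <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::plot(mid, x$density, type = "h",
                 xlab = "temporal correlation", ylab = "density", ...)
  invisible(x)
}

#' Read / write localization tables
#'
#' Plain CSV with columns \code{x_nm,y_nm,frame}.
#' @param path file path.
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_nm", "y_nm", "frame")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(points = df[, need], true_label = NULL,
                 centers = NULL, field_nm = NA_real_),
            class = "localization_set")
}

#' @rdname read_localizations
#' @param locs a \code{localization_set}.
#' @export
write_localizations <- function(locs, path) {
  if (inherits(locs, "localization_set")) locs <- locs$points
  utils::write.csv(locs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write image stacks as multi-page TIFF
#'
#' Thin wrappers over the \pkg{tiff} package (in Suggests); stacks are
#' stored height x width x frames.
#' @param path file path.
#' @param frame_interval_ms acquisition interval to attach on read.
#' @export
read_image_stack <- function(path, frame_interval_ms = 20) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to read TIFF stacks", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  data <- array(unlist(pages),
                dim = c(dim(pages[[1]])[1:2], length(pages)))
  structure(list(data = data, frame_interval_ms = frame_interval_ms,
                 static_map = NULL, mobile_mask = NULL),
            class = "image_stack")
}

#' @rdname read_image_stack
#' @param stack an \code{image_stack}.
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to write TIFF stacks", call. = FALSE)
  }
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  rng <- range(data)
  scaled <- if (diff(rng) > 0) (data - rng[1]) / diff(rng) else data * 0
  pages <- lapply(seq_len(dim(data)[3]), function(f) scaled[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
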