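# shared fixture builders and independent oracles

make_snapshot <- function(diameters, indexes = NULL, times = 0,
                          volume_mL = 1e-4) {
  n <- length(diameters)
  if (is.null(indexes)) indexes <- rep(1.36, n)
  rec <- data.frame(replicate_id = rep("r1", n),
                    time_s = rep_len(times, max(n, 0)),
                    droplet_id = seq_len(n),
                    diameter_um = diameters,
                    refractive_index = indexes,
                    z_um = rep(NA_real_, n))
  population_snapshot(droplet_records(rec), sampled_volume_mL = volume_mL)
}

# dataset whose snapshot at time t holds `n_per` diameters drawn from the
# scaled Smoluchowski distribution with the given per-time mean
make_scaling_dataset <- function(times, means, alpha, n_per = 400,
                                 seed = 1, volume_mL = 1e-4) {
  set.seed(seed)
  snaps <- lapply(seq_along(times), function(i) {
    d <- sample_smoluchowski(n_per, means[i], alpha)
    n <- length(d)
    rec <- data.frame(replicate_id = "sim", time_s = times[i],
                      droplet_id = seq_len(n), diameter_um = d,
                      refractive_index = 1.36, z_um = NA_real_)
    population_snapshot(droplet_records(rec), sampled_volume_mL = volume_mL,
                        time_bin = c(times[i], times[i]))
  })
  condensate_timeseries(snaps, label = "scaling fixture")
}

write_droplet_fixture_file <- function(path,
                                       time_s = c(10, 20, 30),
                                       diameter = c(1, 2, 3),
                                       index = c(1.36, 1.36, 1.36),
                                       volume = 3e-5, bin_width = 60) {
  lines <- c(sprintf("# sampled_volume_mL=%g", volume),
             "# medium_index=1.340",
             "# wavelength_nm=450",
             sprintf("# bin_width_s=%g", bin_width),
             "replicate_id,time_s,droplet_id,diameter_um,refractive_index,z_um",
             sprintf("r1,%g,%d,%g,%g,", time_s, seq_along(time_s),
                     diameter, index))
  writeLines(lines, path)
  path
}

# from-definition distance correlation: explicit double loops, no matrix
# shortcuts, independent of the package implementation
dcorr_bruteforce <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j])
    b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  if (dvx * dvy <= 0) return(0)
  v <- dcov2 / sqrt(dvx * dvy)
  if (v <= 0) 0 else sqrt(v)
}

# reachability-closure DBSCAN oracle: cores from neighbourhood counts,
# clusters as connected components of the core graph (igraph), borders
# attached to any adjacent core's component
dbscan_oracle <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  if (n == 0L) return(list(label = integer(0), core = logical(0)))
  dm <- as.matrix(stats::dist(xy))
  nb <- dm <= eps
  core <- rowSums(nb) >= min_pts
  label <- integer(n)
  if (any(core)) {
    ci <- which(core)
    g <- igraph::graph_from_adjacency_matrix(
      nb[ci, ci, drop = FALSE], mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    label[ci] <- comp
    for (i in which(!core)) {
      adj <- ci[nb[i, ci]]
      if (length(adj) > 0L) label[i] <- label[adj[1]]
    }
  }
  list(label = label, core = core)
}

# set partition induced by a labeling, ignoring label ids (noise = 0 kept
# as its own identified set)
partition_sets <- function(label) {
  cl <- sort(unique(label[label != 0L]))
  sets <- lapply(cl, function(k) sort(which(label == k)))
  sets[order(vapply(sets, `[`, integer(1), 1))]
}
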