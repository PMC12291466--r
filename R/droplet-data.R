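#' Per-droplet record table
#'
#' Validates and normalizes a table of per-droplet holographic
#' characterization records. Each row is one droplet measured at one time:
#' its diameter \eqn{d_p} (micrometers) and refractive index \eqn{n_p}
#' (dimensionless), with optional axial position \code{z_um} in the
#' microfluidic channel.
#'
#' @param df data.frame with columns \code{replicate_id}, \code{time_s},
#'   \code{droplet_id}, \code{diameter_um}, \code{refractive_index} and
#'   optionally \code{z_um}.
#' @return the validated data.frame (with \code{z_um} added as \code{NA} if
#'   absent), classed \code{"droplet_records"}.
#' @export
droplet_records <- function(df) {
  required <- c("replicate_id", "time_s", "droplet_id",
                "diameter_um", "refractive_index")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"z_um" %in% names(df)) df$z_um <- NA_real_
  df <- df[, c(required, "z_um")]
  for (col in c("time_s", "diameter_um", "refractive_index", "z_um")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(!is.finite(df$diameter_um) | df$diameter_um <= 0)
  if (length(bad) > 0L) {
    stop("non-positive or non-finite diameter_um at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  # NA marks composition not yet assigned (ground-truth simulator output)
  ri <- df$refractive_index
  bad <- which(!is.na(ri) & (!is.finite(ri) | ri <= 1))
  if (length(bad) > 0L) {
    stop("refractive_index must exceed 1.0; bad row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$time_s) | df$time_s < 0)
  if (length(bad) > 0L) {
    stop("negative or non-finite time_s at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("droplet_records", "data.frame")
  df
}

#' Population snapshot
#'
#' A collection of droplet records sharing one nominal time bin, together
#' with the sampling metadata needed for number-density estimates: the
#' interrogated fluid volume, the medium refractive index \eqn{n_m} and the
#' illumination vacuum wavelength.
#'
#' @param records a \code{droplet_records} table (or plain data.frame).
#' @param sampled_volume_mL interrogated fluid volume, milliliters (> 0).
#' @param medium_index refractive index of the aqueous medium; default 1.340
#'   (aqueous buffer at 450 nm).
#' @param wavelength_nm illumination vacuum wavelength, nanometers.
#' @param time_bin numeric length-2 \code{c(start, end)} in seconds; by
#'   default the range of the record times.
#' @return object of class \code{"population_snapshot"}.
#' @export
population_snapshot <- function(records, sampled_volume_mL,
                                medium_index = 1.340,
                                wavelength_nm = 450,
                                time_bin = NULL) {
  if (!inherits(records, "droplet_records")) {
    records <- droplet_records(as.data.frame(records))
  }
  if (!is.numeric(sampled_volume_mL) || length(sampled_volume_mL) != 1L ||
      !is.finite(sampled_volume_mL) || sampled_volume_mL <= 0) {
    stop("sampled_volume_mL must be a single positive number", call. = FALSE)
  }
  if (is.null(time_bin)) {
    time_bin <- if (nrow(records) > 0L) range(records$time_s) else c(0, 0)
  }
  stopifnot(length(time_bin) == 2L, time_bin[1] <= time_bin[2])
  if (nrow(records) > 0L &&
      (any(records$time_s < time_bin[1]) || any(records$time_s > time_bin[2]))) {
    stop("record times fall outside the declared time bin", call. = FALSE)
  }
  structure(list(records = records,
                 sampled_volume_mL = sampled_volume_mL,
                 medium_index = medium_index,
                 wavelength_nm = wavelength_nm,
                 time_bin = as.numeric(time_bin)),
            class = "population_snapshot")
}

#' @export
print.population_snapshot <- function(x, ...) {
  cat(sprintf(
    "Population snapshot: %d droplets, t in [%g, %g] s, volume %g mL\n",
    nrow(x$records), x$time_bin[1], x$time_bin[2], x$sampled_volume_mL))
  invisible(x)
}

#' Nominal time of a snapshot (seconds)
#'
#' Mean acquisition time of the records, falling back to the bin midpoint
#' for an empty snapshot.
#' @param snapshot a \code{population_snapshot}.
#' @export
snapshot_time <- function(snapshot) {
  if (nrow(snapshot$records) > 0L) mean(snapshot$records$time_s)
  else mean(snapshot$time_bin)
}

#' Time-resolved droplet dataset
#'
#' An ordered collection of population snapshots with strictly increasing
#' nominal times.
#'
#' @param snapshots list of \code{population_snapshot} objects.
#' @param label free-text label.
#' @return object of class \code{"condensate_timeseries"}.
#' @export
condensate_timeseries <- function(snapshots, label = "") {
  stopifnot(is.list(snapshots))
  ok <- vapply(snapshots, inherits, logical(1), "population_snapshot")
  if (!all(ok)) stop("all elements must be population_snapshot objects",
                     call. = FALSE)
  if (length(snapshots) > 1L) {
    tt <- vapply(snapshots, snapshot_time, numeric(1))
    if (any(diff(tt) <= 0)) {
      stop("snapshot times must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(snapshots = snapshots, label = as.character(label)),
            class = "condensate_timeseries")
}

#' @export
print.condensate_timeseries <- function(x, ...) {
  n <- vapply(x$snapshots, function(s) nrow(s$records), integer(1))
  cat(sprintf("Condensate time series '%s': %d snapshots, %d droplets total\n",
              x$label, length(x$snapshots), sum(n)))
  invisible(x)
}

#' Read a droplet record table
#'
#' Reads the package's droplet-record CSV dialect: '#'-prefixed
#' \code{key=value} header lines carrying the sampling metadata
#' (\code{sampled_volume_mL}, \code{medium_index}, \code{wavelength_nm},
#' \code{bin_width_s}), then a column-name row and the data rows with
#' columns \code{replicate_id,time_s,droplet_id,diameter_um,
#' refractive_index,z_um}. Records are grouped into snapshots by time bin.
#'
#' @param path file path.
#' @param bin_width_s time-bin width in seconds; overrides the header value.
#'   Default (from the header, else 60 s) reflects snapshots accumulated
#'   over short acquisition windows.
#' @return a \code{condensate_timeseries}.
#' @seealso [write_droplet_table()] for the lossless companion writer.
#' @export
read_droplet_table <- function(path, bin_width_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    if (!grepl("=", kv, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    meta[[key]] <- val
  }
  for (key in c("sampled_volume_mL", "medium_index", "wavelength_nm")) {
    if (is.null(meta[[key]])) {
      stop("header lacks mandatory key '", key, "'", call. = FALSE)
    }
  }
  if (is.null(bin_width_s)) {
    bin_width_s <- if (!is.null(meta$bin_width_s)) {
      as.numeric(meta$bin_width_s)
    } else 60
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 1L) stop("no column row found in ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  required <- c("replicate_id", "time_s", "droplet_id",
                "diameter_um", "refractive_index")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- droplet_records(df)
  bins <- floor(records$time_s / bin_width_s)
  snaps <- lapply(sort(unique(bins)), function(b) {
    population_snapshot(
      records[bins == b, , drop = FALSE],
      sampled_volume_mL = as.numeric(meta$sampled_volume_mL),
      medium_index = as.numeric(meta$medium_index),
      wavelength_nm = as.numeric(meta$wavelength_nm),
      time_bin = c(b, b + 1) * bin_width_s)
  })
  ds <- condensate_timeseries(snaps, label = basename(path))
  attr(ds, "bin_width_s") <- bin_width_s
  ds
}

#' Write a droplet record table
#'
#' Companion writer for [read_droplet_table()]; the pair round-trips valid
#' datasets losslessly to the declared precision (6 decimal places, chosen
#' because the instrument resolves the refractive index to about 1e-5).
#'
#' @param dataset a \code{condensate_timeseries}.
#' @param path output file path.
#' @export
write_droplet_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "condensate_timeseries"))
  s1 <- dataset$snapshots[[1]]
  bw <- attr(dataset, "bin_width_s")
  if (is.null(bw)) bw <- diff(s1$time_bin)
  hdr <- c(sprintf("# sampled_volume_mL=%.10g", s1$sampled_volume_mL),
           sprintf("# medium_index=%.6f", s1$medium_index),
           sprintf("# wavelength_nm=%.10g", s1$wavelength_nm),
           sprintf("# bin_width_s=%.10g", bw))
  rec <- do.call(rbind, lapply(dataset$snapshots,
                               function(s) as.data.frame(s$records)))
  rec$time_s <- sprintf("%.6f", rec$time_s)
  rec$diameter_um <- sprintf("%.6f", rec$diameter_um)
  rec$refractive_index <- sprintf("%.6f", rec$refractive_index)
  rec$z_um <- ifelse(is.na(rec$z_um), "", sprintf("%.6f", rec$z_um))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rec, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a snapshot to the instrument's detection band
#'
#' Holographic characterization has detection efficiency close to unity for
#' droplet diameters between about 0.5 and 10 micrometers; droplets outside
#' that band are unreliable and are dropped before population statistics
#' are computed. Both bounds are inclusive. The input is not modified and
#' sampling metadata is carried through.
#'
#' @param snapshot a \code{population_snapshot}.
#' @param d_min,d_max detection band in micrometers, \code{0 < d_min < d_max}.
#' @return a filtered \code{population_snapshot}.
#' @export
filter_detection_band <- function(snapshot, d_min = 0.5, d_max = 10) {
  stopifnot(inherits(snapshot, "population_snapshot"))
  if (!(is.finite(d_min) && is.finite(d_max) && d_min > 0 && d_min < d_max)) {
    stop("require 0 < d_min < d_max", call. = FALSE)
  }
  keep <- snapshot$records$diameter_um >= d_min &
    snapshot$records$diameter_um <= d_max
  out <- snapshot
  out$records <- snapshot$records[keep, , drop = FALSE]
  out
}

#' Population summary statistics
#'
#' Mean, standard deviation and standard error of the mean for both
#' measurement channels (diameter and refractive index), plus the droplet
#' count. With a single record the SE is reported as 0 and flagged
#' degenerate.
#'
#' @param snapshot a non-empty \code{population_snapshot}.
#' @return list with \code{n}, \code{mean_d}, \code{sd_d}, \code{se_d},
#'   \code{mean_n}, \code{se_n}, \code{degenerate}.
#' @export
population_stats <- function(snapshot) {
  stopifnot(inherits(snapshot, "population_snapshot"))
  d <- snapshot$records$diameter_um
  np <- snapshot$records$refractive_index
  n <- length(d)
  if (n == 0L) stop("empty snapshot: no droplets to summarize", call. = FALSE)
  degenerate <- n == 1L
  sd_d <- if (degenerate) 0 else stats::sd(d)
  sd_n <- if (degenerate) 0 else stats::sd(np)
  list(n = n,
       mean_d = mean(d), sd_d = sd_d, se_d = sd_d / sqrt(n),
       mean_n = mean(np), sd_n = sd_n, se_n = sd_n / sqrt(n),
       degenerate = degenerate)
}

#' Condensate number density
#'
#' Count per interrogated volume, with a Poisson-counting interval
#' \eqn{(N \pm \sqrt N)/V}. Zero counts are allowed: the density is 0 and
#' only the upper bound is informative.
#'
#' @param snapshot a \code{population_snapshot}.
#' @return list with \code{density_per_mL}, \code{lower}, \code{upper},
#'   \code{count}, \code{sampled_volume_mL}.
#' @export
number_density <- function(snapshot) {
  stopifnot(inherits(snapshot, "population_snapshot"))
  n <- nrow(snapshot$records)
  v <- snapshot$sampled_volume_mL
  list(density_per_mL = n / v,
       lower = max(0, (n - sqrt(n)) / v),
       upper = (n + max(1, sqrt(n))) / v,
       count = n,
       sampled_volume_mL = v)
}

#' Concatenate snapshots sharing metadata
#'
#' Pools the records of several snapshots taken under the same sampling
#' metadata into one snapshot whose volume is the sum of the parts.
#' @param ... \code{population_snapshot} objects.
#' @export
concat_snapshots <- function(...) {
  snaps <- list(...)
  if (length(snaps) == 1L && is.list(snaps[[1]]) &&
      !inherits(snaps[[1]], "population_snapshot")) {
    snaps <- snaps[[1]]
  }
  stopifnot(length(snaps) >= 1L)
  rec <- do.call(rbind, lapply(snaps, function(s) as.data.frame(s$records)))
  population_snapshot(
    droplet_records(rec),
    sampled_volume_mL = sum(vapply(snaps, function(s) s$sampled_volume_mL,
                                   numeric(1))),
    medium_index = snaps[[1]]$medium_index,
    wavelength_nm = snaps[[1]]$wavelength_nm,
    time_bin = range(vapply(snaps, function(s) s$time_bin, numeric(2))))
}
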