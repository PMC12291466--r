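#' Run manifest for reproducible analyses
#'
#' Records everything needed to regenerate an analysis output: the
#' command name, the full configuration, the RNG seed, input/output
#' paths, the package version and a timestamp. Re-running a stochastic
#' stage with the seed from its manifest reproduces the output
#' bit-for-bit.
#'
#' @param command character name of the analysis stage.
#' @param config list of configuration values (must be JSON-serializable).
#' @param seed integer RNG seed (or NULL for deterministic stages).
#' @param inputs,outputs character vectors of paths.
#' @return object of class \code{"run_manifest"}.
#' @export
run_manifest <- function(command, config = list(), seed = NULL,
                         inputs = character(0), outputs = character(0)) {
  structure(list(command = command,
                 config = config,
                 seed = seed,
                 inputs = inputs,
                 outputs = outputs,
                 package_version =
                   as.character(utils::packageVersion("condkit")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a \code{run_manifest}.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Run manifest: %s (condkit %s, seed %s)\n",
              x$command, x$package_version,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Population characterization report
#'
#' End-to-end characterization of one or more droplet-record files (or
#' in-memory datasets): detection-band filtering, per-snapshot summary
#' statistics, number densities, and effective-medium conversion of the
#' mean refractive index to dense-phase volume fraction and mass
#' concentration. With two or more replicates the report also includes
#' the pairwise Jensen-Shannon divergence of their pooled size
#' distributions, the run-to-run reproducibility score.
#'
#' @param inputs character vector of droplet-table paths, or a list of
#'   \code{condensate_timeseries} objects.
#' @param band detection band \code{c(d_min, d_max)} um, or NULL.
#' @param mixing a [mixing_params()] object.
#' @param out_json optional path; when given, the report (plus manifest)
#'   is written there.
#' @return list of class \code{"characterize_report"}.
#' @export
run_characterize <- function(inputs, band = c(0.5, 10),
                             mixing = mixing_params(), out_json = NULL) {
  datasets <- load_inputs(inputs)
  if (length(datasets) == 0L) {
    stop("no input datasets supplied", call. = FALSE)
  }
  per_dataset <- lapply(datasets, function(ds) {
    snaps <- ds$snapshots
    if (!is.null(band)) {
      snaps <- lapply(snaps, filter_detection_band, band[1], band[2])
    }
    rows <- lapply(snaps, function(s) {
      if (nrow(s$records) == 0L) return(NULL)
      st <- population_stats(s)
      nd <- number_density(s)
      phi <- tryCatch(volume_fraction_from_index(st$mean_n, mixing),
                      error = function(e) NA_real_)
      data.frame(time_s = snapshot_time(s), n = st$n,
                 mean_d_um = st$mean_d, se_d_um = st$se_d,
                 mean_n_p = st$mean_n, se_n_p = st$se_n,
                 density_per_mL = nd$density_per_mL,
                 phi = phi,
                 conc_mg_per_mL = if (is.na(phi)) NA_real_ else
                   concentration_from_phi(phi, mixing))
    })
    list(label = ds$label, table = do.call(rbind, rows))
  })
  jsd_matrix <- NULL
  if (length(datasets) >= 2L) {
    pool <- lapply(datasets, function(ds) {
      unlist(lapply(ds$snapshots, function(s) s$records$diameter_um))
    })
    m <- length(pool)
    jsd_matrix <- matrix(0, m, m,
                         dimnames = list(names(datasets), names(datasets)))
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      jsd_matrix[i, j] <- jsd_matrix[j, i] <-
        jensen_shannon(pool[[i]], pool[[j]])$value
    }
  }
  report <- structure(list(datasets = per_dataset,
                           replicate_jsd = jsd_matrix,
                           band = band,
                           mixing = unclass(mixing)),
                      class = "characterize_report")
  if (!is.null(out_json)) {
    payload <- list(
      datasets = lapply(per_dataset, function(x) {
        list(label = x$label, table = x$table)
      }),
      replicate_jsd = jsd_matrix,
      band = band, mixing = unclass(mixing),
      manifest = unclass(run_manifest(
        "characterize",
        config = list(band = band, mixing = unclass(mixing)),
        inputs = if (is.character(inputs)) inputs else "in-memory",
        outputs = out_json)))
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE, dataframe = "columns")
  }
  report
}

#' @export
print.characterize_report <- function(x, ...) {
  for (d in x$datasets) {
    cat("Dataset:", d$label, "\n")
    print(d$table, row.names = FALSE, digits = 5)
  }
  if (!is.null(x$replicate_jsd) && nrow(x$replicate_jsd) == 2L) {
    cat(sprintf("Replicate size-distribution JSD = %.4f bits\n",
                x$replicate_jsd[1, 2]))
  }
  invisible(x)
}

#' Growth-mechanism study report
#'
#' The full growth pipeline on a time-resolved dataset: detection-band
#' filtering, per-snapshot statistics, power-law fit, dynamic-scaling
#' collapse test, self-regulated fit, mass-fractal fit on the
#' decreasing-density regime, and model ranking. With fewer than 4
#' usable snapshots the report degrades gracefully to
#' characterization-only with a warning.
#'
#' @param input a droplet-table path or a \code{condensate_timeseries}.
#' @param band detection band, um.
#' @param df fractal dimension fixed in the self-regulated fit.
#' @param out_json optional JSON report path.
#' @return list of class \code{"growth_report"}.
#' @export
run_growth_study <- function(input, band = c(0.5, 10), df = 2,
                             out_json = NULL) {
  ds <- load_inputs(list(input))[[1]]
  characterization <- run_characterize(list(ds), band = band)
  tab <- characterization$datasets[[1]]$table
  comparison <- NULL
  mass_fractal <- NULL
  if (is.null(tab) || nrow(tab) < 4L) {
    warning("fewer than 4 usable snapshots: reporting characterization only")
  } else {
    comparison <- compare_growth_models(ds, band = band, df = df)
    # mass-fractal fit over the regime where density decreases
    dens <- tab$density_per_mL
    peak <- which.max(dens)
    if (nrow(tab) - peak + 1L >= 3L) {
      mass_fractal <- tryCatch(
        fit_mass_fractal(dens[peak:nrow(tab)],
                         tab$mean_d_um[peak:nrow(tab)]),
        error = function(e) NULL)
    }
  }
  report <- structure(list(characterization = characterization,
                           comparison = comparison,
                           mass_fractal = mass_fractal),
                      class = "growth_report")
  if (!is.null(out_json)) {
    payload <- list(
      table = tab,
      ranking = if (!is.null(comparison)) comparison$ranking else NULL,
      aicc = if (!is.null(comparison)) as.list(comparison$aicc) else NULL,
      beta = if (!is.null(comparison$power_law))
        comparison$power_law$beta else NULL,
      beta_se = if (!is.null(comparison$power_law))
        comparison$power_law$beta_se else NULL,
      z_beta_vs_lsw = if (!is.null(comparison))
        comparison$z_beta_vs_lsw else NULL,
      self_regulated = if (!is.null(comparison$self_regulated))
        as.list(coef(comparison$self_regulated)) else NULL,
      max_collapse_jsd = if (!is.null(comparison$collapse))
        comparison$collapse$max_jsd else NULL,
      mass_fractal_df = if (!is.null(mass_fractal))
        mass_fractal$df else NULL,
      manifest = unclass(run_manifest(
        "growth-study", config = list(band = band, df = df),
        inputs = if (is.character(input)) input else "in-memory",
        outputs = out_json)))
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE, dataframe = "columns")
  }
  report
}

#' @export
print.growth_report <- function(x, ...) {
  print(x$characterization)
  if (!is.null(x$comparison)) print(x$comparison)
  if (!is.null(x$mass_fractal)) print(x$mass_fractal)
  invisible(x)
}

# accept paths or in-memory datasets, uniformly
load_inputs <- function(inputs) {
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (inherits(inputs, "condensate_timeseries")) inputs <- list(inputs)
  out <- lapply(inputs, function(x) {
    if (inherits(x, "condensate_timeseries")) x
    else if (is.character(x)) read_droplet_table(x)
    else stop("inputs must be file paths or condensate_timeseries objects",
              call. = FALSE)
  })
  names(out) <- vapply(out, function(d) d$label, character(1))
  out
}
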