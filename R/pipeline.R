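# Orchestration: one configuration drives simulate -> extract -> filter ->
# epoch -> average -> cluster test (per lock) -> RT model, with a serializable
# result bundle and figure output.

#' Pipeline run configuration
#'
#' @param generator a [generator_config()] (simulate mode).
#' @param exclusion an [exclusion_config()].
#' @param locks subset of `c("TL1", "TL2", "TL3")` to analyze.
#' @param permutation a [permutation_spec()]; its `alpha_final` defaults to
#'   `.05 / length(locks)` (Bonferroni across the lockings) unless given.
#' @param normalization Delta normalization for the frames path.
#' @param delta_source `"kinematics"` (rendering-free observation path, fast;
#'   the default for simulation studies) or `"frames"` (render pixel stacks
#'   and extract the Delta trace from them).
#' @param min_trials,clip_range analysis-window policy, see
#'   [build_analysis_matrix()]. `clip_range` may be a single `c(lo, hi)` or a
#'   named list per lock.
#' @param seed master seed; deterministically spawns the generator seed and
#'   per-lock permutation seeds (recorded in the bundle provenance).
#' @return list of class `artidelta_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       exclusion = exclusion_config(),
                       locks = c("TL1", "TL2", "TL3"),
                       permutation = NULL,
                       normalization = "per_pixel_rms",
                       delta_source = c("kinematics", "frames"),
                       min_trials = 1L,
                       clip_range = NULL,
                       seed = 1L) {
  locks <- match.arg(locks, LOCKS, several.ok = TRUE)
  if (length(locks) == 0L) stop("locks must be nonempty")
  delta_source <- match.arg(delta_source)
  if (is.null(permutation))
    permutation <- permutation_spec(alpha_final = 0.05 / length(locks))
  structure(list(generator = generator, exclusion = exclusion, locks = locks,
                 permutation = permutation, normalization = normalization,
                 delta_source = delta_source, min_trials = as.integer(min_trials),
                 clip_range = clip_range, seed = as.integer(seed)),
            class = "artidelta_run_config")
}

# Master seed -> per-stage seeds, all < 2^31.
spawn_seeds <- function(seed, locks) {
  base <- (as.integer(seed) %% 1000000L) * 1000L
  list(generator = base + 1L,
       permutation = stats::setNames(base + 100L + seq_along(locks), locks))
}

#' Run the full analysis pipeline
#'
#' In simulate mode: generates the dataset, derives per-trial Delta traces
#' (from rendered frames or directly from the latent kinematics), applies the
#' sequential trial exclusions, and for each configured time-locking epochs,
#' averages per participant and condition, and runs the cluster-based
#' permutation test; finally fits the RT mixed model on the kept trials.
#' Deterministic under the master seed.
#'
#' @param config an [run_config()].
#' @param out_dir optional directory; when given the bundle is written there
#'   (events CSV, exclusion report JSON, per-lock grand-average CSVs and
#'   cluster JSONs, RT JSON, provenance JSON, and one figure per lock).
#' @return list of class `artidelta_bundle`: `events`, `kept`,
#'   `exclusion_report`, per-lock `locks[[lock]]` (with `grand_average`,
#'   `cluster`, `matrix`), `rt_summary`, `rt_model`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "artidelta_run_config"))
  seeds <- spawn_seeds(config$seed, config$locks)
  gen <- config$generator
  gen$seed <- seeds$generator

  want_frames <- config$delta_source == "frames"
  ds <- generate_dataset(gen, output = c("events", if (want_frames) "frames" else "kinematics"))
  traces <- if (want_frames) {
    lapply(ds$stacks, function(st) extract_delta_trace(st, config$normalization))
  } else {
    lapply(ds$kinematics, delta_from_kinematics)
  }
  if (want_frames) {
    keys <- names(traces)
    traces <- lapply(seq_along(traces), function(i) {
      key <- keys[i]
      ev <- ds$events[sprintf("P%d_I%d_%s", ds$events$participant_id,
                              ds$events$item_id, ds$events$condition) == key, , drop = FALSE]
      align_to_events(traces[[i]], ev)
    })
    names(traces) <- keys
  }

  flt <- filter_trials(ds$events, config$exclusion)

  lock_results <- list()
  for (lock in config$locks) {
    averages <- average_dataset(traces, flt$kept, lock)
    clip <- config$clip_range
    if (is.list(clip) && !is.null(names(clip))) clip <- clip[[lock]]
    mats <- build_analysis_matrix(averages, min_trials = config$min_trials,
                                  clip_range = clip)
    spec <- config$permutation
    spec$seed <- seeds$permutation[[lock]]
    res <- cluster_test(mats$early_planning, mats$late_planning, mats$times, spec)
    ga <- data.frame(time_s = mats$times,
                     early_planning = colMeans(mats$early_planning),
                     late_planning = colMeans(mats$late_planning))
    lock_results[[lock]] <- list(grand_average = ga, cluster = res, matrix = mats)
  }

  bundle <- structure(list(
    events = ds$events,
    kept = flt$kept,
    exclusion_report = flt$report,
    locks = lock_results,
    rt_summary = summarize_rt(flt$kept),
    rt_model = fit_rt_model(flt$kept),
    provenance = list(master_seed = config$seed,
                      generator_seed = seeds$generator,
                      permutation_seeds = as.list(seeds$permutation),
                      n_permutations = config$permutation$n_permutations,
                      alpha_cluster = config$permutation$alpha_cluster,
                      alpha_final = config$permutation$alpha_final,
                      delta_source = config$delta_source,
                      package_version = as.character(utils::packageVersion("artidelta")))
  ), class = "artidelta_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

cluster_result_json <- function(res) {
  cl <- res$clusters
  list(clusters = lapply(seq_len(nrow(cl)), function(i) list(
    start_s = cl$start_time[i], end_s = cl$end_time[i],
    sign = if (cl$sign[i] > 0) "+" else "-",
    mass = cl$mass[i], p = cl$p_value[i],
    significant = cl$significant[i])),
    n_permutations = length(res$null),
    mode = res$spec$mode,
    seed = res$spec$seed,
    alpha_cluster = res$spec$alpha_cluster,
    alpha_final = res$spec$alpha_final,
    null_max_mass_quantiles = as.list(stats::quantile(res$null, c(.5, .95, .99))))
}

#' Write a result bundle to disk
#'
#' @param bundle an `artidelta_bundle`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_events(bundle$events, file.path(out_dir, "events.csv"))
  jsonlite::write_json(bundle$exclusion_report,
                       file.path(out_dir, "exclusion_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (lock in names(bundle$locks)) {
    lr <- bundle$locks[[lock]]
    utils::write.csv(lr$grand_average,
                     file.path(out_dir, paste0("grand_average_", lock, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(cluster_result_json(lr$cluster),
                         file.path(out_dir, paste0("clusters_", lock, ".json")),
                         auto_unbox = TRUE, digits = NA)
    plot_traces(bundle, lock, file.path(out_dir, paste0("traces_", lock, ".png")))
  }
  rt <- bundle$rt_model
  jsonlite::write_json(list(summary = bundle$rt_summary, model = unclass(rt)),
                       file.path(out_dir, "rt_model.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Plot grand-average condition traces with significant clusters shaded
#'
#' Time is displayed in milliseconds relative to the lock point; significant
#' cluster extents are shaded.
#'
#' @param bundle an `artidelta_bundle` containing the lock.
#' @param lock which time-locking to plot.
#' @param file output PNG (or SVG, by extension) path; `NULL` plots to the
#'   active device.
#' @return `file`, invisibly.
#' @export
plot_traces <- function(bundle, lock, file = NULL) {
  if (is.null(bundle$locks[[lock]]))
    stop("bundle does not contain lock ", lock)
  lr <- bundle$locks[[lock]]
  ga <- lr$grand_average
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 4.5)
    else grDevices::png(file, width = 900, height = 560)
    on.exit(grDevices::dev.off())
  }
  tms <- ga$time_s * 1000
  ylim <- range(ga$early_planning, ga$late_planning)
  graphics::plot(tms, ga$early_planning, type = "n", ylim = ylim,
                 xlab = paste0("time relative to ", lock, " (ms)"),
                 ylab = "frame-to-frame change (a.u.)",
                 main = paste("Tongue-movement trace,", lock))
  cl <- lr$cluster$clusters
  sig <- cl[cl$significant, , drop = FALSE]
  if (nrow(sig) > 0L) {
    for (i in seq_len(nrow(sig)))
      graphics::rect(sig$start_time[i] * 1000, ylim[1L],
                     sig$end_time[i] * 1000, ylim[2L],
                     col = grDevices::adjustcolor("grey", 0.5), border = NA)
  }
  graphics::lines(tms, ga$early_planning, col = "red", lwd = 2)
  graphics::lines(tms, ga$late_planning, col = "black", lwd = 2, lty = 2)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topleft", c("early planning", "late planning"),
                   col = c("red", "black"), lty = c(1, 2), lwd = 2, bty = "n")
  invisible(file)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `generator`, `exclusion`, `permutation` override the
#' corresponding constructor defaults field by field (nested lists merge
#' shallowly per argument); `locks`, `normalization`, `delta_source`,
#' `min_trials`, `clip_range` and `seed` map directly to [run_config()].
#'
#' @param path YAML file.
#' @return an `artidelta_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  merge_args <- function(fn, overrides) {
    if (is.null(overrides)) return(fn())
    defaults <- formals(fn)
    args <- list()
    for (nm in names(overrides)) {
      if (!nm %in% names(defaults)) stop("unknown config field: ", nm)
      dflt <- eval(defaults[[nm]])
      args[[nm]] <- if (is.list(dflt) && is.list(overrides[[nm]]))
        utils::modifyList(dflt, overrides[[nm]]) else overrides[[nm]]
    }
    do.call(fn, args)
  }
  run_config(
    generator = merge_args(generator_config, y$generator),
    exclusion = merge_args(exclusion_config, y$exclusion),
    locks = y$locks %||% c("TL1", "TL2", "TL3"),
    permutation = if (is.null(y$permutation)) NULL else
      merge_args(permutation_spec, y$permutation),
    normalization = y$normalization %||% "per_pixel_rms",
    delta_source = y$delta_source %||% "kinematics",
    min_trials = y$min_trials %||% 1L,
    clip_range = y$clip_range,
    seed = y$seed %||% 1L
  )
}
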