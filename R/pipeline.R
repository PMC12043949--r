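# Reproducible simulate-and-analyze runs driven by a config list or YAML
# file, with provenance (resolved config, seed, package version) written
# next to the outputs.

pipeline_stage_kinds <- c("relaxation", "frap", "tracks", "stack", "lamin")

#' Run a configured simulate-and-analyze pipeline
#'
#' Executes the requested stages in order, writing data, fit results and a
#' recovery report per stage, plus a resolved-config JSON with provenance
#' (config MD5, seed, package version). Reruns with the same config and
#' seed reproduce all numeric outputs exactly. A failing stage aborts the
#' run with the stage named and leaves a `<stage>.partial` marker.
#'
#' @param config A named list, or the path to a YAML file, with keys
#'   `seed` (integer), `outdir` (directory, created if needed) and
#'   `stages` (named list; each entry has `what`, one of `"relaxation"`,
#'   `"frap"`, `"tracks"`, `"stack"`, `"lamin"`, and an optional `params`
#'   list passed to the matching generator). Unknown keys are rejected
#'   before any computation.
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_schema("config must be a list or a YAML file path")
  allowed <- c("seed", "outdir", "stages")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) stop_schema(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  if (is.null(config$seed) || is.null(config$outdir) || is.null(config$stages)) {
    stop_schema("config needs keys: seed, outdir, stages")
  }
  for (nm in names(config$stages)) {
    st <- config$stages[[nm]]
    if (is.null(st$what) || !st$what %in% pipeline_stage_kinds) {
      stop_schema(sprintf("stage '%s': 'what' must be one of %s", nm,
                          paste(pipeline_stage_kinds, collapse = ", ")))
    }
    bad <- setdiff(names(st), c("what", "params"))
    if (length(bad)) stop_schema(sprintf("stage '%s': unknown key(s) %s", nm,
                                         paste(bad, collapse = ", ")))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  results <- list()
  for (nm in names(config$stages)) {
    st <- config$stages[[nm]]
    partial <- file.path(outdir, paste0(nm, ".partial"))
    file.create(partial)
    res <- tryCatch(
      run_stage(st$what, st$params, seed = seed, outdir = outdir, name = nm),
      error = function(e) {
        nm_stop(sprintf("stage '%s' (%s) failed: %s", nm, st$what,
                        conditionMessage(e)), "pipeline_stage_error")
      })
    unlink(partial)
    results[[nm]] <- res
  }

  cfg_path <- file.path(outdir, "config.resolved.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  prov <- list(config_md5 = unname(tools::md5sum(cfg_path)), seed = seed,
               package = "nucleomech",
               version = as.character(utils::packageVersion("nucleomech")))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

# Simulate one input with its ground truth, run the matching analysis, and
# write data + results + a recovery report for the stage.
run_stage <- function(what, params, seed, outdir, name) {
  params <- c(params, list(seed = seed))
  out_json <- function(x, suffix) {
    jsonlite::write_json(x, file.path(outdir, paste0(name, "_", suffix, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (what == "relaxation") {
    sim <- do.call(gen_relaxation, params)
    utils::write.csv(data.frame(time_s = sim$curve$time, stress_kpa = sim$curve$stress),
                     file.path(outdir, paste0(name, "_data.csv")), row.names = FALSE)
    fit <- fit_relaxation(sim$curve)
    out_json(unclass(fit), "fit")
    out_json(sim$truth$params, "truth")
    return(list(fit = fit, truth = sim$truth))
  }
  if (what == "frap") {
    sim <- do.call(gen_frap_trace, params)
    tr <- sim$trace
    df <- rbind(
      data.frame(time_s = -rev(seq_along(tr$prescan_intensity)) * tr$protocol$prescan_interval,
                 intensity = tr$prescan_intensity, phase = "prescan"),
      data.frame(time_s = tr$time, intensity = tr$intensity, phase = "post"))
    utils::write.csv(df, file.path(outdir, paste0(name, "_data.csv")), row.names = FALSE)
    fit <- fit_recovery(normalize_trace(tr))
    out_json(unclass(fit), "fit")
    out_json(sim$truth$params, "truth")
    return(list(fit = fit, truth = sim$truth))
  }
  if (what == "tracks") {
    sim <- do.call(gen_tracks, params)
    write_tracks_csv(sim$tracks, file.path(outdir, paste0(name, "_data.csv")))
    fits <- lapply(sim$tracks, function(tr) fit_powerlaw(time_avg_msd(tr)))
    summ <- ensemble_summary(fits)
    utils::write.csv(summ, file.path(outdir, paste0(name, "_summary.csv")), row.names = FALSE)
    out_json(sim$truth$params, "truth")
    report <- list(alpha_truth = sim$truth$params$alpha,
                   alpha_median = summ$alpha_median,
                   D_truth = sim$truth$params$D, D_median = summ$D_median,
                   n_accepted = summ$n_accepted, n_rejected = summ$n_rejected)
    out_json(report, "recovery")
    return(list(summary = summ, truth = sim$truth))
  }
  if (what == "stack") {
    sim <- do.call(gen_nucleus_stack, params)
    write_stack(sim$stack, file.path(outdir, paste0(name, "_data.tif")),
                scale = max(sim$stack$data) * 1.001)
    mask <- segment_stack(sim$stack)
    res <- compaction_index(sim$stack, mask)
    out_json(c(unclass(res), list(volume_truth = sim$truth$params$volume_um3)), "result")
    return(list(result = res, truth = sim$truth))
  }
  if (what == "lamin") {
    sim <- do.call(gen_lamin_image, params)
    write_stack(sim$image, file.path(outdir, paste0(name, "_data.tif")),
                scale = max(sim$image) * 1.001)
    res <- wrinkling_index(sim$image)
    out_json(c(unclass(res), list(fold_amplitude_truth = sim$truth$params$fold_amplitude)),
             "result")
    return(list(result = res, truth = sim$truth))
  }
  stop_schema(paste("unsupported stage kind:", what))
}
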