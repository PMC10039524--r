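#' Pipeline configuration
#'
#' One configuration object drives the whole analysis: simulation,
#' preprocessing, wave detection, complexity, and (optionally) the
#' adversarial model.  Every stochastic stage receives a seed derived
#' deterministically from the global seed and the stage name
#' ([derive_seed()]), so a re-run with the same configuration reproduces
#' identical outputs.  Configurations serialise to JSON
#' ([write_pipeline_config()]).
#'
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @param simulate a [dataset_spec()], plus layout dimensions via
#'   `layout_rows`, `layout_cols`, `pitch_um` entries in `...`.
#' @param layout_rows,layout_cols,pitch_um electrode grid of the simulated
#'   recording.
#' @param band delta band edges in Hz for filtering.
#' @param artifact_uv artifact threshold in uV.
#' @param thresholds a [wave_thresholds()] list.
#' @param pr_mode eigenspectrum mode for complexity results.
#' @param gan `NULL` to skip the adversarial stage, or a [gan_config()].
#' @param gan_iterations training iterations for the pipeline run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("spiralmea_run_"),
                            simulate = dataset_spec(),
                            layout_rows = 32L, layout_cols = 32L,
                            pitch_um = 42,
                            band = c(1, 4), artifact_uv = 200,
                            thresholds = wave_thresholds(),
                            pr_mode = "spatial-svd-pooled",
                            gan = NULL, gan_iterations = 200L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  obj$simulate <- unclass(obj$simulate)
  obj$gan <- if (!is.null(obj$gan)) unclass(obj$gan)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj[["simulate"]] <- do.call(dataset_spec, obj[["simulate"]])
  obj[["thresholds"]] <- do.call(wave_thresholds, obj[["thresholds"]])
  ## note [[ ]]: `$gan` would partially match `gan_iterations` when the
  ## adversarial stage is disabled
  if (!is.null(obj[["gan"]]) && length(obj[["gan"]]))
    obj[["gan"]] <- do.call(gan_config, obj[["gan"]])
  else obj["gan"] <- list(NULL)
  do.call(pipeline_config, obj)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess (delta filter, artifact removal) ->
#' detect -> complexity -> (optional) adversarial training and sampling,
#' writing every stage output under `config$out_dir` and returning a run
#' manifest with per-file checksums.  Re-running with an identical
#' configuration reproduces identical checksums for all deterministic
#' stages.
#'
#' @param config a [pipeline_config()].
#' @return A `run_manifest`: list with `config`, `outputs` (files and md5
#'   checksums), per-stage summaries, and timestamps.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lay <- electrode_layout(config$layout_rows, config$layout_cols,
                          config$pitch_um)

  ## simulate
  ds <- generate_dataset(config$simulate, seed = derive_seed(config$seed,
                                                             "simulate"),
                         layout = lay)
  rec_dir <- file.path(config$out_dir, "recording")
  write_recording(ds$recording, rec_dir)
  write_event_table(ds$ground_truth,
                    file.path(config$out_dir, "ground_truth.csv"))
  write_event_table(ds$ground_truth,
                    file.path(config$out_dir, "ground_truth.json"))

  ## preprocess: zero-phase delta filter, then artifact removal
  filt <- bandpass_delta(ds$recording, config$band[1], config$band[2])
  clean <- remove_artifacts(filt, config$artifact_uv)

  ## detect
  det <- detect_waves(clean, frame_interval = 1 / clean$sampling_rate,
                      thresholds = config$thresholds)
  waves_csv <- file.path(config$out_dir, "waves.csv")
  write_event_table(det$table, waves_csv)

  ## complexity per detected event
  comp <- lapply(seq_along(det$events), function(i) {
    ev <- det$events[[i]]
    idx <- round(ev$window[1] * clean$sampling_rate) + 1
    idx <- idx:min(round(ev$window[2] * clean$sampling_rate),
                   ncol(clean$voltage))
    stack <- snapshot_stack(array(clean$voltage[, idx],
                                  c(lay$n_rows, lay$n_cols, length(idx))),
                            frame_interval = 1 / clean$sampling_rate)
    k6 <- if (n_frames(stack) >= 6) select_evenly_spaced(stack, 6) else stack
    pr <- participation_ratio(eigenspectrum(k6, config$pr_mode))
    data.frame(event_id = i, kind = ev$kind, pr = pr$pr,
               pr_per_sqrt_n = pr$pr_per_sqrt_n,
               pr_per_sqrt_k = pr$pr_per_sqrt_k, mode = config$pr_mode)
  })
  comp <- if (length(comp)) do.call(rbind, comp)
  else data.frame(event_id = integer(), kind = character(), pr = numeric(),
                  pr_per_sqrt_n = numeric(), pr_per_sqrt_k = numeric(),
                  mode = character())
  pr_csv <- file.path(config$out_dir, "complexity.csv")
  write_event_table(comp, pr_csv)

  ## optional adversarial stage
  gan_files <- character()
  if (!is.null(config$gan)) {
    spiral_idx <- which(vapply(det$events, function(e) e$kind == "spiral",
                               logical(1)))
    if (length(spiral_idx) >= 2) {
      stacks <- lapply(spiral_idx, function(i) {
        ev <- det$events[[i]]
        idx <- round(ev$window[1] * clean$sampling_rate) + 1
        idx <- idx:min(round(ev$window[2] * clean$sampling_rate),
                       ncol(clean$voltage))
        snapshot_stack(array(clean$voltage[, idx],
                             c(lay$n_rows, lay$n_cols, length(idx))),
                       frame_interval = 1 / clean$sampling_rate)
      })
      ts <- build_training_set(stacks, k = config$gan$n_planes)
      model <- gan_init(config$gan)
      tr <- gan_train(model, ts, iterations = config$gan_iterations)
      ckpt <- file.path(config$out_dir, "gan_model.json")
      save_gan(tr$model, ckpt)
      hist_csv <- file.path(config$out_dir, "gan_scores.csv")
      write_event_table(tr$history, hist_csv)
      gan_files <- c(ckpt, hist_csv)
    }
  }

  files <- c(file.path(rec_dir, "voltage.csv"),
             file.path(rec_dir, "meta.json"),
             file.path(config$out_dir, "ground_truth.csv"),
             waves_csv, pr_csv, gan_files)
  manifest <- list(
    config = config,
    outputs = data.frame(file = files,
                         md5 = vapply(files, function(f)
                           as.character(tools::md5sum(f)), character(1))),
    detection = list(n_events = length(det$events),
                     rate_per_min = det$rate_per_min,
                     duration_mean_s = det$duration_mean_s,
                     duration_sd_s = det$duration_sd_s),
    started = t0, finished = Sys.time())
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n  events:", x$detection$n_events,
      " spiral rate/min:", signif(x$detection$rate_per_min, 3), "\n")
  cat("  outputs:\n")
  for (i in seq_len(nrow(x$outputs)))
    cat("   ", x$outputs$file[i], x$outputs$md5[i], "\n")
  invisible(x)
}
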