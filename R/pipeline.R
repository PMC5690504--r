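# Umbrella pipeline: simulate -> score/select -> train -> evaluate, driven
# by one configuration object and one master seed.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations. A single master seed
#' deterministically derives every stage seed (see [derive_seed()]), so the
#' whole run is reproducible from this object alone.
#'
#' @param cycles List of [breathing_cycle()]s, one session per cycle.
#' @param markers,reference,duration,dt,waveform_exponent Simulator
#'   settings, see [simulation_config()].
#' @param criteria A [selection_criteria()].
#' @param train A [train_config()] (its `seed` is overridden by a derived
#'   stage seed).
#' @param output_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param log_level `"info"` (one message per stage) or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cycles = standard_cycles(),
                            markers = default_markers(),
                            reference = reference_preset(),
                            duration = 60, dt = 0.025, waveform_exponent = 2,
                            criteria = selection_criteria(),
                            train = train_config(),
                            output_dir = tempfile("respmark_run_"),
                            seed = 1, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (length(cycles) == 0) {
    stop_respmark("pipeline requires at least one session cycle",
                  "invalid_config")
  }
  stopifnot(inherits(criteria, "selection_criteria"),
            inherits(train, "train_config"),
            is.numeric(seed), length(seed) == 1L)
  structure(list(cycles = cycles, markers = markers, reference = reference,
                 duration = duration, dt = dt,
                 waveform_exponent = waveform_exponent,
                 criteria = criteria, train = train,
                 output_dir = output_dir, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

pipeline_log <- function(pc, stage, seed) {
  if (pc$log_level != "quiet") {
    message(sprintf("[respmark] stage %-10s seed %d", stage, seed))
  }
}

#' Run the full marker-placement pipeline
#'
#' Stages, in order: 1) simulate one session per configured cycle and write
#' them as CSV; 2) score all markers with CCA and PCA on the training
#' sessions, select subsets, write `scores.csv`; 3) train the correlation
#' model on the CCA-selected subset, write `model.json`; 4) run the
#' six-mode comparison, write `report.csv`. A manifest (JSON) recording the
#' configuration, derived stage seeds and output files is written last.
#' Identical configurations produce identical outputs.
#'
#' @param pc A [pipeline_config()].
#' @return The run manifest (list), invisibly; its `files` entry lists all
#'   written artifacts.
#' @export
run_pipeline <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  if (length(pc$cycles) < 2) {
    stop_respmark("pipeline evaluation needs at least two sessions",
                  "invalid_config")
  }
  dir.create(pc$output_dir, showWarnings = FALSE, recursive = TRUE)
  sess_dir <- file.path(pc$output_dir, "sessions")
  dir.create(sess_dir, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- character(0)
  stage_seeds <- list()

  run_stage <- function(stage, body) {
    seed <- derive_seed(pc$seed, stage)
    stage_seeds[[stage]] <<- seed
    pipeline_log(pc, stage, seed)
    tryCatch(body(seed), error = function(e) {
      stop_respmark(sprintf("pipeline stage '%s' failed: %s", stage,
                            conditionMessage(e)), "pipeline_stage_error")
    })
  }

  sessions <- run_stage("simulate", function(seed) {
    ss <- simulate_sessions(cycles = pc$cycles, markers = pc$markers,
                            reference = pc$reference, duration = pc$duration,
                            dt = pc$dt, seed = seed,
                            waveform_exponent = pc$waveform_exponent)
    for (s in ss) {
      f <- file.path(sess_dir, paste0(s$config$session_id, ".csv"))
      write_session_csv(s, f)
      files <<- c(files, f, default_config_path(f))
    }
    ss
  })

  selections <- run_stage("select", function(seed) {
    sp <- split_sessions(sessions)
    sel <- lapply(c(cca = "cca", pca = "pca"), function(method) {
      select_markers(aggregate_scores(score_all(sp$train, method)),
                     pc$criteria)
    })
    f <- file.path(pc$output_dir, "scores.csv")
    write_scores_csv(sel, f)
    files <<- c(files, f)
    sel
  })

  model <- run_stage("train", function(seed) {
    tc <- pc$train
    tc$seed <- seed
    sp <- split_sessions(sessions)
    m <- fit_setup_model(sp$train, selections$cca$selected, tc)
    f <- file.path(pc$output_dir, "model.json")
    write_setup_model(m, f)
    files <<- c(files, f)
    m
  })

  report <- run_stage("evaluate", function(seed) {
    tc <- pc$train
    tc$seed <- seed
    rep <- compare_modes(sessions, pc$criteria, tc)
    f <- file.path(pc$output_dir, "report.csv")
    write_report(rep, f)
    files <<- c(files, f)
    rep
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("respmark")),
    master_seed = pc$seed,
    stage_seeds = stage_seeds,
    n_sessions = length(sessions),
    selected_cca = selections$cca$selected,
    selected_pca = selections$pca$selected,
    files = files,
    started = format(t0, "%Y-%m-%dT%H:%M:%OS3"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
  )
  jsonlite::write_json(manifest, file.path(pc$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
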