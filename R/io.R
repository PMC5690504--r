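# Shared I/O: session CSV schema, configuration and model serialization.
# All files are plain text (CSV / JSON) with locale-independent '.' decimal
# formatting.

SESSION_COLUMNS <- c("time_s",
                     as.vector(t(outer(MARKER_LABELS, c("_ap", "_si"),
                                       paste0))),
                     "ref_ap", "ref_si")

#' Write a session to CSV (with a JSON config sidecar)
#'
#' Schema: `time_s, M1_ap, M1_si, ..., M9_ap, M9_si, ref_ap, ref_si`,
#' header row mandatory, UTF-8, '.' decimal. The generating configuration
#' is serialized alongside as a JSON key-value file so a session
#' round-trips completely.
#'
#' @param session A `synthetic_session`.
#' @param path Output CSV path.
#' @param config_path Sidecar JSON path; default replaces the `.csv`
#'   extension with `_config.json`. `NULL` skips the sidecar.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path,
                              config_path = default_config_path(path)) {
  stopifnot(inherits(session, "synthetic_session"))
  cols <- list(time_s = session$reference$time)
  for (lab in MARKER_LABELS) {
    tr <- session$markers[[lab]]
    cols[[paste0(lab, "_ap")]] <- tr$ap
    cols[[paste0(lab, "_si")]] <- tr$si
  }
  cols$ref_ap <- session$reference$ap
  cols$ref_si <- session$reference$si
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(config_path) && !is.null(session$config)) {
    write_config_json(session$config, config_path)
  }
  invisible(path)
}

default_config_path <- function(path) {
  sub("\\.csv$", "_config.json", path)
}

#' Serialize / restore a simulation configuration as JSON
#'
#' @param config A [simulation_config()].
#' @param path JSON file path.
#' @return `write_config_json` returns `path` invisibly;
#'   `read_config_json` returns the restored [simulation_config()].
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  payload <- list(
    format_version = 1L,
    cycle = unclass(config$cycle),
    markers = lapply(config$markers, unclass),
    reference = unclass(config$reference),
    duration = config$duration, dt = config$dt, seed = config$seed,
    waveform_exponent = config$waveform_exponent,
    session_id = config$session_id
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_spec <- function(s) do.call(marker_spec, s)
  simulation_config(
    cycle = do.call(breathing_cycle, p$cycle),
    markers = lapply(p$markers, as_spec),
    reference = as_spec(p$reference),
    duration = p$duration, dt = p$dt, seed = p$seed,
    waveform_exponent = p$waveform_exponent, session_id = p$session_id
  )
}

#' Read a session from CSV
#'
#' Validates the schema (all 21 columns present, uniform strictly
#' increasing timestamps, no missing values) and reports offending columns
#' or rows. If the JSON config sidecar exists it is restored; otherwise the
#' session carries a minimal placeholder config.
#'
#' @param path Session CSV path.
#' @param config_path Sidecar JSON path (default: derived from `path`);
#'   ignored if the file does not exist.
#' @return A `synthetic_session`.
#' @export
read_session_csv <- function(path, config_path = default_config_path(path)) {
  if (!file.exists(path)) {
    stop_respmark(paste("no such session file:", path), "format_error")
  }
  if (file.size(path) == 0) {
    stop_respmark(paste("empty session file:", path), "format_error")
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop_respmark(paste("malformed session CSV:", conditionMessage(e)),
                    "format_error")
    }
  )
  missing <- setdiff(SESSION_COLUMNS, names(df))
  if (length(missing)) {
    stop_respmark(paste("session CSV missing column(s):",
                        paste(missing, collapse = ", ")), "schema_error")
  }
  if (nrow(df) < 2) {
    stop_respmark("session CSV must contain at least two samples",
                  "format_error")
  }
  bad <- which(!stats::complete.cases(df[SESSION_COLUMNS]))
  if (length(bad)) {
    stop_respmark(paste("malformed/missing values at data row(s):",
                        paste(utils::head(bad, 5), collapse = ", ")),
                  "format_error")
  }
  dts <- diff(df$time_s)
  if (any(dts <= 0) || diff(range(dts)) > 1e-6 * max(dts)) {
    stop_respmark("non-uniform or non-increasing timestamps", "format_error")
  }
  config <- if (!is.null(config_path) && file.exists(config_path)) {
    read_config_json(config_path)
  } else {
    NULL
  }
  markers <- lapply(MARKER_LABELS, function(lab) {
    motion_trace(df$time_s, df[[paste0(lab, "_ap")]],
                 df[[paste0(lab, "_si")]])
  })
  names(markers) <- MARKER_LABELS
  session <- list(markers = markers,
                  reference = motion_trace(df$time_s, df$ref_ap, df$ref_si),
                  config = config)
  if (is.null(config)) {
    session$config <- list(session_id =
                             sub("\\.csv$", "", basename(path)))
  }
  structure(session, class = "synthetic_session")
}

#' Serialize / restore a trained correlation model
#'
#' Flat JSON with a format version, the Gaussian premise parameters, the
#' linear consequents and the training configuration.
#'
#' @param model A `setup_model` (see [fit_setup_model()]).
#' @param path JSON file path.
#' @return `write_setup_model` returns `path` invisibly;
#'   `read_setup_model` returns the restored `setup_model`.
#' @export
write_setup_model <- function(model, path) {
  stopifnot(inherits(model, "setup_model"))
  ser_axis <- function(m) {
    list(centers = m$centers, sigmas = m$sigmas, coef = m$coef,
         input_labels = m$input_labels, output_axis = m$output_axis,
         training_history = m$training_history)
  }
  payload <- list(format_version = 1L, markers = model$markers,
                  config = unclass(model$config),
                  ap = ser_axis(model$ap), si = ser_axis(model$si))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_setup_model
#' @export
read_setup_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_axis <- function(a) {
    m <- new_anfis_model(as.matrix(a$centers), as.matrix(a$sigmas),
                         as.matrix(a$coef), input_labels = a$input_labels,
                         output_axis = a$output_axis)
    m$training_history <- a$training_history
    m
  }
  structure(list(ap = de_axis(p$ap), si = de_axis(p$si),
                 markers = p$markers,
                 config = do.call(train_config, p$config)),
            class = "setup_model")
}

#' Write aggregated selection scores to CSV
#'
#' Columns: `label, method, mean_score, sd_score, n_sessions, selected`
#' (0/1).
#'
#' @param results List of `selection_result`s (one per method).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    df <- r$scores
    df$selected <- as.integer(df$selected)
    df
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
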