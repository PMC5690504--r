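# Evaluation: RMSE of the predicted setup, marker-subset comparison modes,
# and the per-region "importance degree" ranking.

#' Root mean square error
#'
#' `sqrt(mean((actual - predicted)^2))` between benchmark positions `A_i`
#' and model predictions `P_i`.
#'
#' @param actual,predicted Equal-length numeric vectors (mm).
#' @return RMSE in mm, >= 0.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
rmse <- function(actual, predicted) {
  stopifnot(is.numeric(actual), is.numeric(predicted))
  if (length(actual) != length(predicted) || length(actual) < 1) {
    stop_respmark("`actual` and `predicted` must be equal-length, non-empty",
                  "invalid_parameter")
  }
  if (anyNA(actual) || anyNA(predicted)) {
    stop_respmark("missing values in RMSE input", "invalid_parameter")
  }
  rms(actual - predicted)
}

#' Fixed region subsets of the nine-site layout
#'
#' @return Named list: `upper` = M1-M3, `middle` = M4-M6, `lower` = M7-M9.
#' @export
region_subsets <- function() {
  list(upper = c("M1", "M2", "M3"),
       middle = c("M4", "M5", "M6"),
       lower = c("M7", "M8", "M9"))
}

# Pooled per-axis RMSE of a fitted setup model over a list of sessions,
# plus the combined value (root of the mean of the two axis MSEs).
evaluate_setup <- function(model, sessions) {
  err_ap <- c(); err_si <- c()
  for (s in sessions) {
    pred <- predict_setup(model, s)
    err_ap <- c(err_ap, pred$ap - s$reference$ap)
    err_si <- c(err_si, pred$si - s$reference$si)
  }
  c(ap = rms(err_ap), si = rms(err_si),
    combined = sqrt(mean(c(mean(err_ap^2), mean(err_si^2)))))
}

# Deterministic session split: the last ~30% of sessions (at least one) are
# held out for testing.
split_sessions <- function(sessions, test_fraction = 0.3) {
  n <- length(sessions)
  if (n < 2) {
    stop_respmark("at least two sessions required for train/test separation",
                  "invalid_parameter")
  }
  n_test <- max(1L, min(n - 1L, ceiling(n * test_fraction)))
  list(train = sessions[seq_len(n - n_test)],
       test = sessions[seq.int(n - n_test + 1L, n)])
}

#' Importance degree of marker subsets
#'
#' Trains one correlation model per subset on the training sessions,
#' evaluates its RMSE on held-out sessions, and ranks subsets in ascending
#' RMSE order: rank 1 (lowest prediction error) marks the most important
#' placement region. Ties are broken by subset name.
#'
#' @param sessions List of at least two `synthetic_session`s; the last ~30%
#'   are held out as the test set.
#' @param subsets Named list of marker-label vectors, default
#'   [region_subsets()].
#' @param config A [train_config()].
#' @return data.frame ordered by rank: `subset`, `n_markers`, `rmse_mm`
#'   (combined-axis test RMSE), `rank`.
#' @export
importance_degree <- function(sessions, subsets = region_subsets(),
                              config = train_config()) {
  stopifnot(is.list(subsets), length(subsets) >= 1,
            !is.null(names(subsets)))
  if (any(vapply(subsets, length, integer(1)) == 0L)) {
    stop_respmark("empty marker subset", "schema_error")
  }
  sp <- split_sessions(sessions)
  res <- vapply(subsets, function(markers) {
    model <- fit_setup_model(sp$train, markers, config)
    evaluate_setup(model, sp$test)[["combined"]]
  }, numeric(1))
  ord <- order(res, names(subsets))
  out <- data.frame(subset = names(subsets)[ord],
                    n_markers = vapply(subsets[ord], length, integer(1)),
                    rmse_mm = unname(res[ord]),
                    rank = seq_along(res))
  rownames(out) <- NULL
  out
}

eval_mode_subsets <- function(sel_cca, sel_pca) {
  regions <- region_subsets()
  list(selected_cca = sel_cca, selected_pca = sel_pca,
       all_markers = MARKER_LABELS,
       upper = regions$upper, middle = regions$middle, lower = regions$lower)
}

#' Compare marker-subset modes end to end
#'
#' Runs the full pipeline on a set of sessions: scores all markers with CCA
#' and PCA on the training sessions, selects marker subsets with the given
#' criteria, trains one correlation model per evaluation mode
#' (`selected_cca`, `selected_pca`, `all_markers`, `upper`, `middle`,
#' `lower`), and reports held-out-session RMSE per mode and axis. Identical
#' subsets are fitted once, so two modes that select the same markers get
#' identical RMSEs.
#'
#' @param sessions List of at least two `synthetic_session`s.
#' @param criteria A [selection_criteria()].
#' @param config A [train_config()].
#' @return An `evaluation_report`: data.frame with columns `mode`, `axis`,
#'   `rmse_mm`, `n_markers`, `rank` (6 modes x 2 axes rows; rank over modes
#'   by combined-axis RMSE, ties broken by mode name). Selection results
#'   and configs are attached as attributes `selection` and `meta`.
#' @export
compare_modes <- function(sessions, criteria = selection_criteria(),
                          config = train_config()) {
  sp <- split_sessions(sessions)
  selections <- lapply(c(cca = "cca", pca = "pca"), function(method) {
    select_markers(aggregate_scores(score_all(sp$train, method)), criteria)
  })
  modes <- eval_mode_subsets(selections$cca$selected, selections$pca$selected)
  keys <- vapply(modes, function(m) paste(sort(m), collapse = "+"),
                 character(1))
  fits <- new.env(parent = emptyenv())
  mode_rmse <- lapply(names(modes), function(mode) {
    key <- keys[[mode]]
    if (is.null(fits[[key]])) {
      model <- fit_setup_model(sp$train, modes[[mode]], config)
      fits[[key]] <- evaluate_setup(model, sp$test)
    }
    fits[[key]]
  })
  names(mode_rmse) <- names(modes)
  combined <- vapply(mode_rmse, `[[`, numeric(1), "combined")
  ord <- order(combined, names(modes))
  ranks <- integer(length(modes))
  ranks[ord] <- seq_along(ord)
  out <- do.call(rbind, lapply(names(modes), function(mode) {
    data.frame(mode = mode, axis = c("ap", "si"),
               rmse_mm = unname(mode_rmse[[mode]][c("ap", "si")]),
               n_markers = length(modes[[mode]]),
               rank = ranks[match(mode, names(modes))])
  }))
  rownames(out) <- NULL
  attr(out, "selection") <- selections
  attr(out, "meta") <- list(criteria = criteria, train = config,
                            n_train = length(sp$train),
                            n_test = length(sp$test))
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Write / read an evaluation report
#'
#' CSV serialization (`mode, axis, rmse_mm, n_markers, rank`) with
#' locale-independent formatting; round-trips losslessly to within 1e-9.
#'
#' @param report An `evaluation_report` (any data.frame with the report
#'   columns is accepted).
#' @param path Output CSV path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the report data.frame.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
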