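# Marker scoring and selection: CCA and PCA scores of each external marker
# against the internal reference, aggregation across sessions, and the
# high-correlation / low-variability selection rule.

#' First canonical correlation between two channel sets
#'
#' Canonical correlation analysis finds linear combinations of the columns
#' of `x` and of `y` with maximal mutual correlation; the first canonical
#' correlation is that maximum. Computed by whitening both covariance blocks
#' (symmetric inverse square root) and taking the largest singular value of
#' the whitened cross-covariance. Invariant under invertible affine
#' transformations of either channel set.
#'
#' @param x,y Numeric matrices (or vectors) with one column per channel and
#'   equal row counts.
#' @param ridge Non-negative ridge added to the diagonal of each
#'   within-set covariance block. Rank-deficient blocks are automatically
#'   regularized with a small documented ridge (`1e-8 x mean diagonal`) and
#'   a warning.
#' @return The first canonical correlation, in `[0, 1]`.
#' @export
#' @examples
#' x <- matrix(rnorm(100), 50)
#' cca_first_correlation(x, x)  # 1
cca_first_correlation <- function(x, y, ridge = 0) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  n <- nrow(x)
  if (nrow(y) != n) {
    stop_respmark("`x` and `y` must have the same number of rows",
                  "alignment_error")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_respmark("missing values in input series", "invalid_trace")
  }
  sds <- c(apply(x, 2, stats::sd), apply(y, 2, stats::sd))
  if (any(sds == 0)) {
    stop_respmark("constant channel: canonical correlation undefined",
                  "degenerate_input")
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sxx <- crossprod(xc) / (n - 1)
  syy <- crossprod(yc) / (n - 1)
  sxy <- crossprod(xc, yc) / (n - 1)

  inv_sqrt <- function(s, ridge) {
    e <- eigen(s, symmetric = TRUE)
    if (min(e$values) < 1e-10 * max(e$values) && ridge == 0) {
      ridge <- 1e-8 * mean(diag(s))
      warning("rank-deficient covariance block; applying ridge ",
              format(ridge), call. = FALSE)
    }
    if (ridge > 0) {
      e <- eigen(s + diag(ridge, ncol(s)), symmetric = TRUE)
    }
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  k <- inv_sqrt(sxx, ridge) %*% sxy %*% inv_sqrt(syy, ridge)
  rho <- svd(k, nu = 0, nv = 0)$d[1]
  min(max(rho, 0), 1)
}

#' Reduce a multichannel trace to its first principal component
#'
#' Channels are mean-centred (not rescaled: all axes share units of mm) and
#' projected on the leading eigenvector of the covariance matrix. The PC1
#' sign is fixed by requiring positive correlation with the channel of
#' largest variance.
#'
#' @param x Numeric matrix, one column per channel (>= 2 channels, >= 3
#'   rows).
#' @return List with `pc1_signal` (numeric vector) and `pc1_var_fraction`
#'   (leading eigenvalue over the eigenvalue sum).
#' @export
#' @examples
#' pca_reduce(cbind(1:3, 1:3))$pc1_var_fraction  # collinear: 1
pca_reduce <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) < 2) {
    stop_respmark("at least two channels required", "degenerate_input")
  }
  if (nrow(x) < 3) {
    stop_respmark("at least three samples required", "degenerate_input")
  }
  vars <- apply(x, 2, stats::var)
  if (all(vars == 0)) {
    stop_respmark("constant input: PCA undefined", "degenerate_input")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  pc1 <- pr$x[, 1]
  lead <- which.max(vars)
  if (stats::var(x[, lead]) > 0) {
    r <- suppressWarnings(stats::cor(pc1, x[, lead]))
    if (!is.na(r) && r < 0) pc1 <- -pc1
  }
  list(pc1_signal = pc1, pc1_var_fraction = ev[1] / sum(ev))
}

trace_matrix <- function(trace) {
  cbind(ap = trace$ap, si = trace$si)
}

check_shared_grid <- function(marker, reference) {
  if (length(marker$time) != length(reference$time) ||
      max(abs(marker$time - reference$time)) > 1e-9) {
    stop_respmark("marker and reference traces must share timestamps",
                  "alignment_error")
  }
}

#' PCA score of a marker against the reference
#'
#' Both the marker's and the reference's (AP, SI) traces are collapsed to
#' their first principal component; the score is the absolute Pearson
#' correlation between the two mono-dimensional signals. The marker's PC1
#' explained-variance fraction is carried along as a data-quality figure.
#'
#' @param marker,reference [motion_trace()]s sharing one time grid.
#' @return One-row data.frame: `label` (NA here; filled by [score_all()]),
#'   `method`, `score`, `pc1_var_fraction`.
#' @export
pca_score <- function(marker, reference) {
  check_shared_grid(marker, reference)
  pm <- pca_reduce(trace_matrix(marker))
  pr <- pca_reduce(trace_matrix(reference))
  data.frame(method = "pca",
             score = abs(stats::cor(pm$pc1_signal, pr$pc1_signal)),
             pc1_var_fraction = pm$pc1_var_fraction)
}

#' CCA score of a marker against the reference
#'
#' First canonical correlation between the marker's (AP, SI) channels and
#' the reference's (AP, SI) channels.
#'
#' @inheritParams pca_score
#' @return One-row data.frame: `method`, `score`, `pc1_var_fraction` (NA).
#' @export
cca_score <- function(marker, reference) {
  check_shared_grid(marker, reference)
  data.frame(method = "cca",
             score = cca_first_correlation(trace_matrix(marker),
                                           trace_matrix(reference)),
             pc1_var_fraction = NA_real_)
}

#' Score every marker of every session against the reference
#'
#' @param sessions List of `synthetic_session` objects (simulated or loaded
#'   from CSV); all sessions must carry the same marker label set.
#' @param method `"cca"` or `"pca"`.
#' @return data.frame with one row per (session, marker), ordered by
#'   session then label: `session_id`, `label`, `method`, `score`,
#'   `pc1_var_fraction`.
#' @export
score_all <- function(sessions, method = c("cca", "pca")) {
  method <- match.arg(method)
  stopifnot(length(sessions) >= 1)
  label_sets <- lapply(sessions, function(s) sort(names(s$markers)))
  if (!all(vapply(label_sets, identical, logical(1), label_sets[[1]]))) {
    stop_respmark("inconsistent marker sets across sessions", "schema_error")
  }
  scorer <- if (method == "cca") cca_score else pca_score
  rows <- lapply(sessions, function(s) {
    labels <- sort(names(s$markers))
    per <- lapply(labels, function(lab) {
      row <- scorer(s$markers[[lab]], s$reference)
      cbind(session_id = s$config$session_id, label = lab, row)
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-session marker scores
#'
#' Mean and population standard deviation of the score per (label, method),
#' with the number of contributing sessions.
#'
#' @param scores data.frame as returned by [score_all()].
#' @return data.frame: `label`, `method`, `mean_score`, `sd_score`,
#'   `n_sessions`, ordered by method then label.
#' @export
aggregate_scores <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1)
  key <- interaction(scores$label, scores$method, drop = TRUE)
  parts <- split(scores, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(label = p$label[1], method = p$method[1],
               mean_score = mean(p$score), sd_score = pop_sd(p$score),
               n_sessions = nrow(p))
  }))
  out <- out[order(out$method, out$label), ]
  rownames(out) <- NULL
  out
}

#' Selection criteria
#'
#' The selection rule admits a marker when its cross-session mean score is
#' at least `tau_corr` and its score SD is at most `tau_sd` (high
#' correlation with minimum variability). `coverage_threshold` is the
#' strict lower bound used by the [coverage_check()] data-quality gate.
#'
#' @param tau_corr Mean-score threshold, default 0.95.
#' @param tau_sd Score-SD ceiling, default 0.25.
#' @param coverage_threshold Coverage bound, default 0.90.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(tau_corr = 0.95, tau_sd = 0.25,
                               coverage_threshold = 0.90) {
  vals <- c(tau_corr, tau_sd, coverage_threshold)
  stopifnot(is.numeric(vals), all(vals > 0), all(vals <= 1))
  structure(list(tau_corr = tau_corr, tau_sd = tau_sd,
                 coverage_threshold = coverage_threshold),
            class = "selection_criteria")
}

#' Select markers by the high-correlation / low-variability rule
#'
#' A marker is selected iff `mean_score >= tau_corr` and
#' `sd_score <= tau_sd` (both thresholds inclusive). An empty selection is
#' allowed but raises a warning.
#'
#' @param agg Aggregated scores ([aggregate_scores()]) for one method,
#'   covering all nine markers.
#' @param criteria A [selection_criteria()].
#' @return An object of class `selection_result`: list with `method`,
#'   `selected` (character vector of labels), `scores` (the aggregated
#'   table, plus a logical `selected` column), `criteria`.
#' @export
#' @examples
#' agg <- data.frame(label = paste0("M", 1:9), method = "cca",
#'                   mean_score = c(.98, .67, .97, .97, .67, .96, .98, .67, .97),
#'                   sd_score   = c(.18, .23, .20, .32, .21, .30, .21, .21, .19),
#'                   n_sessions = 4)
#' select_markers(agg)$selected  # M1 M3 M7 M9
select_markers <- function(agg, criteria = selection_criteria()) {
  stopifnot(is.data.frame(agg), inherits(criteria, "selection_criteria"))
  if (length(unique(agg$method)) != 1L) {
    stop_respmark("aggregated scores mix methods; select per method",
                  "mixed_method_error")
  }
  if (!setequal(agg$label, MARKER_LABELS)) {
    stop_respmark("aggregated scores must cover exactly M1..M9",
                  "schema_error")
  }
  agg <- agg[order(agg$label), ]
  keep <- agg$mean_score >= criteria$tau_corr & agg$sd_score <= criteria$tau_sd
  agg$selected <- keep
  selected <- agg$label[keep]
  if (length(selected) == 0L) {
    warning("no marker satisfies the selection criteria", call. = FALSE)
  }
  structure(list(method = agg$method[1], selected = selected,
                 scores = agg, criteria = criteria),
            class = "selection_result")
}

#' Coverage gate
#'
#' Data-quality check applied before selection: a marker passes when its
#' coverage value (PC1 explained-variance fraction for PCA, first canonical
#' correlation for CCA) strictly exceeds the threshold, i.e. "more than
#' 90%" coverage by default. Failures are reported, not fatal.
#'
#' @param values Numeric vector in `[0, 1]`.
#' @param threshold Strict lower bound, default 0.90.
#' @return Logical vector, `TRUE` where `values > threshold`.
#' @export
coverage_check <- function(values, threshold = 0.90) {
  stopifnot(is.numeric(values), all(values >= 0), all(values <= 1),
            is.numeric(threshold), length(threshold) == 1L)
  values > threshold
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result [%s]: %s>\n", x$method,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "none selected"))
  print(x$scores, row.names = FALSE)
  invisible(x)
}
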