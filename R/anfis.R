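# Adaptive neuro-fuzzy inference system (first-order Sugeno), written from
# scratch: Gaussian premise membership functions seeded by fuzzy c-means,
# product t-norm firing strengths, weighted-average defuzzification, and
# hybrid training (exact least squares for the linear consequents, gradient
# descent for the premise parameters).

#' Training configuration for the neuro-fuzzy correlation model
#'
#' @param n_rules Number of Sugeno rules = FCM cluster count, default 3.
#' @param fcm_fuzzifier FCM fuzzifier `m`, default 2.
#' @param fcm_tol FCM convergence tolerance, default 1e-5.
#' @param fcm_max_iter FCM iteration cap, default 200.
#' @param epochs Hybrid-training epochs, default 50.
#' @param premise_learning_rate Gradient step size for premise centers and
#'   widths, default 0.01 (halved automatically on divergence).
#' @param train_fraction Fraction of samples in the training block of a
#'   contiguous train/test split, default 0.7.
#' @param seed Integer seed (FCM initialization).
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_rules = 3, fcm_fuzzifier = 2.0, fcm_tol = 1e-5,
                         fcm_max_iter = 200, epochs = 50,
                         premise_learning_rate = 0.01, train_fraction = 0.7,
                         seed = 1) {
  stopifnot(n_rules >= 1, fcm_fuzzifier > 1, fcm_tol > 0, fcm_max_iter >= 1,
            epochs >= 1, premise_learning_rate >= 0,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_rules = as.integer(n_rules),
                 fcm_fuzzifier = fcm_fuzzifier, fcm_tol = fcm_tol,
                 fcm_max_iter = as.integer(fcm_max_iter),
                 epochs = as.integer(epochs),
                 premise_learning_rate = premise_learning_rate,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "train_config")
}

new_anfis_model <- function(centers, sigmas, coef, input_labels = NULL,
                            output_axis = NA_character_) {
  structure(
    list(centers = centers, sigmas = sigmas, coef = coef,
         input_dim = ncol(centers), n_rules = nrow(centers),
         input_labels = input_labels, output_axis = output_axis,
         training_history = NULL),
    class = "anfis_model"
  )
}

#' Initialize a Sugeno model from a fuzzy c-means fit
#'
#' Rule `j`'s Gaussian premise in input dimension `k` is centred on the FCM
#' cluster center, with width equal to the membership-weighted standard
#' deviation of that dimension around the center (floored at 1e-6 with a
#' warning for zero-spread dimensions). All consequents start from one
#' global least-squares linear fit of the targets on the inputs.
#'
#' @param fcm An [fcm_cluster()] result fitted on the input columns.
#' @param x Training inputs, `n x d`.
#' @param y Training targets, length `n`.
#' @return An `anfis_model` with one rule per FCM cluster.
#' @export
init_from_fcm <- function(fcm, x, y) {
  stopifnot(inherits(fcm, "fcm_result"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(length(y) == n, nrow(fcm$memberships) == n,
            ncol(fcm$centers) == ncol(x))
  c <- nrow(fcm$centers)
  d <- ncol(x)
  u <- fcm$memberships
  sigmas <- matrix(0, c, d)
  for (j in seq_len(c)) {
    w <- u[, j] / sum(u[, j])
    dev2 <- sweep(x, 2, fcm$centers[j, ])^2
    sigmas[j, ] <- sqrt(colSums(dev2 * w))
  }
  if (any(sigmas < 1e-6)) {
    warning("zero-spread premise dimension; sigma floored at 1e-6",
            call. = FALSE)
    sigmas <- pmax(sigmas, 1e-6)
  }
  beta <- stats::lm.fit(cbind(x, 1), y)$coefficients
  beta[is.na(beta)] <- 0
  coef <- matrix(beta, d + 1, c)
  new_anfis_model(fcm$centers, sigmas, coef, input_labels = colnames(x))
}

# Log firing strengths (n x c) under the product t-norm of Gaussian MFs.
anfis_log_firing <- function(model, x) {
  n <- nrow(x)
  lw <- matrix(0, n, model$n_rules)
  for (j in seq_len(model$n_rules)) {
    z <- sweep(x, 2, model$centers[j, ], "-")
    z <- sweep(z, 2, model$sigmas[j, ], "/")
    lw[, j] <- -0.5 * rowSums(z^2)
  }
  lw
}

# Vectorized forward pass; returns list(pred, w, sw, rule_out, fallback).
anfis_eval <- function(model, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != model$input_dim) {
    stop_respmark("input dimension does not match the model", "schema_error")
  }
  lw <- anfis_log_firing(model, x)
  w <- exp(lw)
  sw <- rowSums(w)
  rule_out <- cbind(x, 1) %*% model$coef        # n x c
  fallback <- sw < 1e-300
  pred <- numeric(nrow(x))
  ok <- !fallback
  if (any(ok)) {
    pred[ok] <- rowSums(w[ok, , drop = FALSE] *
                          rule_out[ok, , drop = FALSE]) / sw[ok]
  }
  if (any(fallback)) {
    nearest <- max.col(lw[fallback, , drop = FALSE], ties.method = "first")
    pred[fallback] <- rule_out[cbind(which(fallback), nearest)]
  }
  list(pred = pred, w = w, sw = sw, rule_out = rule_out, fallback = fallback)
}

#' Evaluate a Sugeno model
#'
#' Firing strength of rule `j` is the product over input dimensions of
#' Gaussian memberships `exp(-(x_k - c_jk)^2 / (2 sigma_jk^2))`; the output
#' is the firing-strength-weighted average of the linear rule consequents.
#' If every rule's firing strength underflows (below 1e-300), the nearest
#' rule's consequent is used and the affected samples are flagged in the
#' `"fallback"` attribute.
#'
#' @param model An `anfis_model`.
#' @param x A single input vector of length `input_dim`.
#' @return Predicted output (scalar, mm).
#' @export
anfis_forward <- function(model, x) {
  stopifnot(inherits(model, "anfis_model"), is.numeric(x))
  if (length(x) != model$input_dim) {
    stop_respmark("input length does not match the model", "schema_error")
  }
  ev <- anfis_eval(model, matrix(x, 1))
  out <- ev$pred
  if (any(ev$fallback)) attr(out, "fallback") <- TRUE
  out
}

#' Predict for a matrix of inputs
#'
#' Vectorized version of [anfis_forward()].
#'
#' @param model An `anfis_model`.
#' @param x Input matrix, `n x input_dim`. If both carry column labels they
#'   must match the labels the model was trained on.
#' @return Numeric vector of predictions, with a `"fallback"` attribute
#'   (row indices) when underflow fallback occurred.
#' @export
anfis_predict <- function(model, x) {
  stopifnot(inherits(model, "anfis_model"))
  x <- as.matrix(x)
  if (!is.null(model$input_labels) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$input_labels)) {
    stop_respmark("input columns do not match the model's training layout",
                  "schema_error")
  }
  ev <- anfis_eval(model, x)
  out <- ev$pred
  if (any(ev$fallback)) attr(out, "fallback") <- which(ev$fallback)
  out
}

# One exact least-squares solve of all rule consequents given fixed premises.
anfis_lse_step <- function(model, x, y) {
  ev <- anfis_eval(model, x)
  wbar <- ev$w / pmax(ev$sw, 1e-300)
  if (any(ev$fallback)) {
    # degenerate rows: attribute them fully to the nearest rule
    lw <- anfis_log_firing(model, x)
    nearest <- max.col(lw[ev$fallback, , drop = FALSE], ties.method = "first")
    wbar[ev$fallback, ] <- 0
    wbar[cbind(which(ev$fallback), nearest)] <- 1
  }
  c <- model$n_rules
  d <- model$input_dim
  design <- do.call(cbind, lapply(seq_len(c), function(j) {
    cbind(x * wbar[, j], wbar[, j])
  }))
  fit <- stats::lm.fit(design, y)
  theta <- fit$coefficients
  if (anyNA(theta)) {
    warning("singular consequent system; applying ridge regularization",
            call. = FALSE)
    lambda <- 1e-8 * mean(diag(crossprod(design)))
    theta <- solve(crossprod(design) + diag(lambda, ncol(design)),
                   crossprod(design, y))
  }
  model$coef <- matrix(theta, d + 1, c)
  model
}

# Gradient of the mean-squared error w.r.t. premise centers and sigmas.
anfis_premise_grad <- function(model, x, y) {
  ev <- anfis_eval(model, x)
  n <- nrow(x)
  resid <- ev$pred - y
  g <- (2 * resid / n) * (ev$rule_out - ev$pred) * ev$w / pmax(ev$sw, 1e-300)
  g[ev$fallback, ] <- 0
  gs <- colSums(g)
  gx <- crossprod(g, x)                      # c x d
  gx2 <- crossprod(g, x^2)
  grad_c <- (gx - gs * model$centers) / model$sigmas^2
  grad_s <- (gx2 - 2 * model$centers * gx + gs * model$centers^2) /
    model$sigmas^3
  list(centers = grad_c, sigmas = grad_s)
}

#' Hybrid training of a Sugeno neuro-fuzzy model
#'
#' Each epoch first solves the linear rule consequents exactly by least
#' squares on firing-strength-weighted regressors (so the training RMSE
#' never increases at this step), then takes one gradient-descent step on
#' the premise centers and widths. A premise step that raises the RMSE by
#' more than 10% is rejected and retried with a halved learning rate.
#'
#' @param model An `anfis_model` (see [init_from_fcm()]).
#' @param x Training inputs, `n x d` with `n >= 10 x n_rules`.
#' @param y Training targets, length `n`.
#' @param config A [train_config()].
#' @return The trained model; `training_history` holds one row per epoch
#'   with the RMSE before the consequent solve, after it, and at epoch end.
#' @export
train_hybrid <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(model, "anfis_model"), inherits(config, "train_config"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (n < 10 * model$n_rules) {
    stop_respmark("need at least 10 samples per rule for training",
                  "invalid_parameter")
  }
  lr <- config$premise_learning_rate
  hist <- data.frame(epoch = integer(0), rmse_pre = numeric(0),
                     rmse_lse = numeric(0), rmse_post = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    rmse_pre <- rms(anfis_eval(model, x)$pred - y)
    model <- anfis_lse_step(model, x, y)
    rmse_lse <- rms(anfis_eval(model, x)$pred - y)
    rmse_post <- rmse_lse
    if (lr > 0) {
      grad <- anfis_premise_grad(model, x, y)
      for (attempt in 1:8) {
        cand <- model
        cand$centers <- model$centers - lr * grad$centers
        cand$sigmas <- pmax(model$sigmas - lr * grad$sigmas, 1e-6)
        rmse_cand <- rms(anfis_eval(cand, x)$pred - y)
        if (rmse_cand <= rmse_lse * 1.10) {
          model <- cand
          rmse_post <- rmse_cand
          break
        }
        lr <- lr / 2
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch, rmse_pre = rmse_pre,
                                   rmse_lse = rmse_lse,
                                   rmse_post = rmse_post))
    if (rmse_post < 1e-12) break
  }
  model$training_history <- hist
  model
}

#' Contiguous train/test split
#'
#' The first `floor(train_fraction x n)` samples form the training block and
#' the remainder the test block. Block-wise rather than random, so serial
#' correlation in the motion traces cannot leak between splits; the split is
#' a deterministic function of `n` and the fraction.
#'
#' @param n Number of samples.
#' @param train_fraction Fraction in `(0, 1)`, default 0.7.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering `1:n`).
#' @export
split_blocks <- function(n, train_fraction = 0.7) {
  stopifnot(n >= 2, train_fraction > 0, train_fraction < 1)
  k <- max(1L, min(n - 1L, floor(n * train_fraction)))
  list(train = seq_len(k), test = seq.int(k + 1L, n))
}

#' Design matrix of selected-marker signals
#'
#' Concatenates the AP and SI channels of the given markers at each time
#' sample into the input layout used by the correlation model (columns
#' `M1_ap`, `M1_si`, ... in label order).
#'
#' @param session A `synthetic_session`.
#' @param markers Character vector of marker labels (non-empty).
#' @return Numeric matrix `n x (2 x length(markers))`.
#' @export
marker_design <- function(session, markers) {
  if (length(markers) == 0L) {
    stop_respmark("empty marker subset", "schema_error")
  }
  missing <- setdiff(markers, names(session$markers))
  if (length(missing)) {
    stop_respmark(paste("markers absent from session:",
                        paste(missing, collapse = ", ")), "schema_error")
  }
  markers <- sort(markers)
  cols <- lapply(markers, function(lab) {
    tr <- session$markers[[lab]]
    m <- cbind(tr$ap, tr$si)
    colnames(m) <- paste0(lab, c("_ap", "_si"))
    m
  })
  do.call(cbind, cols)
}

#' Fit the external/internal correlation model for a marker subset
#'
#' Pools the selected markers' signals across the training sessions and
#' trains one Sugeno neuro-fuzzy model per output axis (AP and SI of the
#' internal reference point). The FCM premise clustering is shared between
#' the two axis models since both see the same inputs.
#'
#' @param sessions List of `synthetic_session`s (training data).
#' @param markers Character vector of marker labels to use as inputs.
#' @param config A [train_config()].
#' @return An object of class `setup_model`: list with `ap` and `si`
#'   (`anfis_model`s), `markers`, `config`.
#' @export
fit_setup_model <- function(sessions, markers, config = train_config()) {
  stopifnot(length(sessions) >= 1)
  x <- do.call(rbind, lapply(sessions, marker_design, markers = markers))
  y_ap <- unlist(lapply(sessions, function(s) s$reference$ap), use.names = FALSE)
  y_si <- unlist(lapply(sessions, function(s) s$reference$si), use.names = FALSE)
  fcm <- fcm_cluster(x, c = config$n_rules, m = config$fcm_fuzzifier,
                     tol = config$fcm_tol, max_iter = config$fcm_max_iter,
                     seed = derive_seed(config$seed, "anfis-fcm"))
  fit_axis <- function(y, axis) {
    model <- init_from_fcm(fcm, x, y)
    model$output_axis <- axis
    train_hybrid(model, x, y, config)
  }
  structure(list(ap = fit_axis(y_ap, "AP"), si = fit_axis(y_si, "SI"),
                 markers = sort(markers), config = config),
            class = "setup_model")
}

#' Predict the internal reference trajectory from marker signals
#'
#' @param models A `setup_model` (or a list with `ap` and `si`
#'   `anfis_model`s and a `markers` field).
#' @param session A `synthetic_session` providing the marker signals.
#' @return A [motion_trace()] of predicted reference AP/SI displacement on
#'   the session's time grid.
#' @export
predict_setup <- function(models, session) {
  stopifnot(!is.null(models$ap), !is.null(models$si))
  x <- marker_design(session, models$markers)
  if (!identical(colnames(x), models$ap$input_labels)) {
    stop_respmark("marker subset does not match the trained model",
                  "schema_error")
  }
  motion_trace(session$reference$time,
               ap = as.numeric(anfis_predict(models$ap, x)),
               si = as.numeric(anfis_predict(models$si, x)))
}

#' @export
print.anfis_model <- function(x, ...) {
  cat(sprintf("<anfis_model [%s]: %d rules, %d inputs%s>\n",
              x$output_axis, x$n_rules, x$input_dim,
              if (!is.null(x$training_history))
                sprintf(", final RMSE %.4g",
                        utils::tail(x$training_history$rmse_post, 1))
              else ", untrained"))
  invisible(x)
}

#' @export
print.setup_model <- function(x, ...) {
  cat(sprintf("<setup_model: markers %s, %d rules/axis>\n",
              paste(x$markers, collapse = ","), x$config$n_rules))
  invisible(x)
}
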