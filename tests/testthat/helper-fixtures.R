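# Shared fixtures and independent oracles, built in code at test time.

# A short default-preset session (fast; ~800 samples).
quick_session <- function(seed = 1, duration = 20, markers = default_markers(),
                          cycle = breathing_cycle(1.2, 2, 5), ...) {
  simulate_session(simulation_config(cycle, markers = markers,
                                     duration = duration, seed = seed, ...))
}

# Grid-search oracle for the first canonical correlation of 2x2-channel
# data: maximize |cor| over unit-norm combination directions on a 1-degree
# grid. Independent of the eigen/SVD solver.
cca_grid_oracle <- function(x, y, step = pi / 180) {
  th <- seq(0, pi, by = step)
  dirs <- cbind(cos(th), sin(th))
  xs <- x %*% t(dirs)
  ys <- y %*% t(dirs)
  max(abs(stats::cor(xs, ys)))
}

# Direction-grid oracle for the PC1 explained-variance fraction in 2-D:
# max over unit directions of projected variance over total variance.
pca_grid_oracle <- function(x, step = pi / 360) {
  th <- seq(0, pi, by = step)
  dirs <- cbind(cos(th), sin(th))
  v <- apply(x %*% t(dirs), 2, stats::var)
  max(v) / sum(diag(stats::cov(x)))
}

# Literal term-by-term Sugeno evaluation: product of scalar Gaussian
# memberships, weighted average of linear consequents. Loops on purpose.
anfis_naive_oracle <- function(model, x) {
  c <- model$n_rules
  w <- numeric(c)
  f <- numeric(c)
  for (j in seq_len(c)) {
    wj <- 1
    for (k in seq_len(model$input_dim)) {
      wj <- wj * exp(-(x[k] - model$centers[j, k])^2 /
                       (2 * model$sigmas[j, k]^2))
    }
    w[j] <- wj
    f[j] <- sum(model$coef[seq_len(model$input_dim), j] * x) +
      model$coef[model$input_dim + 1, j]
  }
  sum(w * f) / sum(w)
}

# Random 2-rule Sugeno data generator with known noise level.
two_rule_data <- function(seed, n = 400, noise = 0.1) {
  set.seed(seed)
  x <- matrix(stats::runif(n, -4, 4), ncol = 1)
  w1 <- exp(-(x[, 1] + 2)^2 / (2 * 1.5^2))
  w2 <- exp(-(x[, 1] - 2)^2 / (2 * 1.5^2))
  y <- (w1 * (2 * x[, 1] + 1) + w2 * (-x[, 1] + 3)) / (w1 + w2) +
    stats::rnorm(n, 0, noise)
  list(x = x, y = y)
}

expect_motion_trace <- function(tr) {
  expect_s3_class(tr, "motion_trace")
  expect_length(tr$ap, length(tr$time))
  expect_length(tr$si, length(tr$time))
}
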