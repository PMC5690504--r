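# CCA / PCA scoring, aggregation, and the selection rule.

test_that("first canonical correlation: identity, univariate and oracle cases", {
  set.seed(1)
  x <- matrix(rnorm(100), 50)
  expect_equal(cca_first_correlation(x, x), 1, tolerance = 1e-9)

  a <- rnorm(60)
  b <- 0.4 * a + rnorm(60)
  expect_equal(cca_first_correlation(a, b), abs(cor(a, b)),
               tolerance = 1e-10)

  for (i in 1:10) {
    x <- matrix(rnorm(100), 50)
    y <- matrix(rnorm(100), 50) + 0.5 * x
    expect_equal(cca_first_correlation(x, y), cca_grid_oracle(x, y),
                 tolerance = 1e-3)
  }
})

test_that("CCA agrees with the base-R reference implementation", {
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(rnorm(150), 50)
    y <- matrix(rnorm(100), 50) + 0.3 * x[, 1:2]
    expect_equal(cca_first_correlation(x, y), stats::cancor(x, y)$cor[1],
                 tolerance = 1e-8)
  }
})

test_that("CCA is affine-invariant and dominates single-channel correlations", {
  set.seed(3)
  for (i in 1:10) {
    x <- matrix(rnorm(120), 60)
    y <- matrix(rnorm(120), 60) + 0.4 * x
    rho <- cca_first_correlation(x, y)
    # invariance under invertible affine maps of either set
    ax <- matrix(c(2, 0.5, -1, 3), 2)
    by <- matrix(c(1, -0.7, 0.2, 0.9), 2)
    expect_equal(cca_first_correlation(x %*% ax, sweep(y %*% by, 2, c(5, -2))),
                 rho, tolerance = 1e-8)
    # first canonical correlation bounds every channel-pair correlation
    expect_gte(rho + 1e-10, max(abs(cor(x, y))))
  }
})

test_that("CCA error contract: constants, misalignment, rank deficiency", {
  x <- matrix(rnorm(60), 30)
  expect_error(cca_first_correlation(cbind(x[, 1], 1), x),
               class = "degenerate_input")
  expect_error(cca_first_correlation(x, x[1:10, ]), class = "alignment_error")
  xdef <- cbind(x[, 1], x[, 1] * 2)  # rank-1 block
  expect_warning(r <- cca_first_correlation(xdef, x), "ridge")
  expect_true(r >= 0 && r <= 1)
})

test_that("pca_reduce matches eigendecomposition and handles named cases", {
  expect_equal(pca_reduce(cbind(1:3, 1:3))$pc1_var_fraction, 1.0)
  sym <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(pca_reduce(sym)$pc1_var_fraction, 0.5)

  set.seed(5)
  for (i in 1:5) {
    x <- cbind(rnorm(100, sd = 2), rnorm(100))
    ev <- eigen(cov(x), symmetric = TRUE)$values
    red <- pca_reduce(x)
    expect_equal(red$pc1_var_fraction, ev[1] / sum(ev), tolerance = 1e-10)
    # 2-D direction-grid oracle: PC1 variance fraction is the max over
    # unit directions of the projected-variance fraction
    expect_equal(red$pc1_var_fraction, pca_grid_oracle(x), tolerance = 1e-4)
    # sign convention: positive correlation with largest-variance channel
    expect_gt(cor(red$pc1_signal, x[, 1]), 0)
  }
  expect_error(pca_reduce(matrix(1, 5, 2)), class = "degenerate_input")
  expect_error(pca_reduce(matrix(rnorm(5), 5, 1)),
               class = "degenerate_input")
})

test_that("pca_score is 1 for self and reflection-invariant", {
  s <- quick_session(seed = 2)
  m <- s$markers$M1
  expect_equal(pca_score(m, m)$score, 1, tolerance = 1e-12)
  flipped <- motion_trace(m$time, m$ap, -m$si)
  expect_equal(pca_score(flipped, m)$score, 1, tolerance = 1e-9)
})

test_that("a high-gain zero-noise marker scores >= 0.99 against the reference", {
  mk <- default_markers()
  mk$M1 <- marker_spec("M1", "upper", 0.95, 0.5, noise_sd = 0,
                       gain_jitter_sd = 0)
  s <- quick_session(seed = 4, duration = 60, markers = mk)
  expect_gte(pca_score(s$markers$M1, s$reference)$score, 0.99)
  # noiseless AP/SI channels are collinear: the documented ridge path engages
  expect_warning(r <- cca_score(s$markers$M1, s$reference)$score, "ridge")
  expect_gte(r, 0.99)
})

test_that("score_all produces one stable-ordered row per marker and session", {
  sessions <- simulate_sessions(cycles = standard_cycles()[1:2],
                                duration = 20, seed = 8)
  sc <- score_all(sessions, "cca")
  expect_equal(nrow(sc), 18)
  expect_equal(sc$label, rep(paste0("M", 1:9), 2))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # pca carries the variance fraction, cca does not
  sp <- score_all(sessions, "pca")
  expect_true(all(is.finite(sp$pc1_var_fraction)))
  expect_true(all(is.na(sc$pc1_var_fraction)))
})

test_that("aggregation uses population SD and is order-invariant", {
  sc <- data.frame(session_id = c("a", "b"), label = "M1", method = "cca",
                   score = c(0.9, 1.0), pc1_var_fraction = NA)
  agg <- aggregate_scores(sc)
  expect_equal(agg$mean_score, 0.95)
  expect_equal(agg$sd_score, 0.05)
  expect_equal(agg$n_sessions, 2)

  sessions <- simulate_sessions(cycles = standard_cycles()[1:3],
                                duration = 20, seed = 9)
  sc <- score_all(sessions, "pca")
  agg1 <- aggregate_scores(sc)
  agg2 <- aggregate_scores(sc[sample(nrow(sc)), ])
  expect_equal(agg1, agg2)
  expect_equal(nrow(agg1), 9)
  # single session: SD identically zero
  agg_one <- aggregate_scores(score_all(sessions[1], "pca"))
  expect_true(all(agg_one$sd_score == 0))
})

test_that("selection rule reproduces the reported four-patient outcome", {
  agg <- data.frame(
    label = paste0("M", 1:9), method = "cca",
    mean_score = c(0.98, 0.67, 0.97, 0.97, 0.67, 0.96, 0.98, 0.67, 0.97),
    sd_score = c(0.18, 0.23, 0.20, 0.32, 0.21, 0.30, 0.21, 0.21, 0.19),
    n_sessions = 4
  )
  sel <- select_markers(agg)
  expect_identical(sel$selected, c("M1", "M3", "M7", "M9"))
  # M4 passes the mean threshold but is excluded by the SD ceiling
  m4 <- sel$scores[sel$scores$label == "M4", ]
  expect_gte(m4$mean_score, 0.95)
  expect_false(m4$selected)
})

test_that("selection is monotone in the mean and total under perfect scores", {
  agg <- data.frame(label = paste0("M", 1:9), method = "pca",
                    mean_score = 1, sd_score = 0, n_sessions = 3)
  expect_identical(select_markers(agg)$selected, paste0("M", 1:9))

  # raising any marker's mean (SD fixed) never removes it
  base <- data.frame(
    label = paste0("M", 1:9), method = "cca",
    mean_score = seq(0.5, 0.995, length.out = 9),
    sd_score = rep(c(0.1, 0.3, 0.2), 3), n_sessions = 5
  )
  sel0 <- select_markers(base)$selected
  for (i in 1:9) {
    up <- base
    up$mean_score[i] <- min(1, up$mean_score[i] + 0.3)
    expect_true(all(setdiff(sel0, up$label[i]) %in%
                      select_markers(up)$selected))
  }
})

test_that("selection edge cases: empty result warns, mixed methods error", {
  agg <- data.frame(label = paste0("M", 1:9), method = "cca",
                    mean_score = 0.5, sd_score = 0.4, n_sessions = 2)
  expect_warning(sel <- select_markers(agg), "no marker")
  expect_length(sel$selected, 0)
  agg$method <- rep(c("cca", "pca", "cca"), 3)
  expect_error(select_markers(agg), class = "mixed_method_error")
})

test_that("coverage gate uses a strict inequality", {
  expect_true(coverage_check(0.95, 0.90))
  expect_false(coverage_check(0.90, 0.90))
  expect_false(coverage_check(0.0, 0.90))
  expect_equal(coverage_check(c(0.91, 0.89, 0.9), 0.9),
               c(TRUE, FALSE, FALSE))
})
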