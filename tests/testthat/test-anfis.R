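# Sugeno neuro-fuzzy model: initialization, forward pass, hybrid training.

test_that("FCM-seeded premises recover the sample moments", {
  set.seed(1)
  x <- matrix(rnorm(1000), ncol = 1)
  y <- x[, 1] + rnorm(1000, 0, 0.1)
  fit <- fcm_cluster(x, 1, seed = 1)
  model <- init_from_fcm(fit, x, y)
  expect_equal(model$n_rules, 1)
  expect_equal(model$centers[1, 1], mean(x), tolerance = 0.1)
  expect_equal(model$sigmas[1, 1], 1, tolerance = 0.1)
})

test_that("requested rule count is honoured and constant columns floored", {
  set.seed(2)
  x <- cbind(rnorm(50), 1)  # second dimension has zero spread
  y <- rnorm(50)
  fit <- fcm_cluster(x, 3, seed = 2)
  expect_warning(model <- init_from_fcm(fit, x, y), "floored")
  expect_equal(model$n_rules, 3)
  expect_true(all(model$sigmas[, 2] == 1e-6))
})

test_that("forward pass matches a literal term-by-term Sugeno evaluation", {
  set.seed(3)
  model <- respmark:::new_anfis_model(
    centers = matrix(rnorm(6), 3), sigmas = matrix(runif(6, 0.5, 2), 3),
    coef = matrix(rnorm(9), 3)
  )
  for (i in 1:20) {
    x <- rnorm(2)
    expect_equal(anfis_forward(model, x), anfis_naive_oracle(model, x),
                 tolerance = 1e-12)
  }
})

test_that("single-rule and identical-consequent models reduce to linear output", {
  one <- respmark:::new_anfis_model(
    centers = matrix(c(0, 0), 1), sigmas = matrix(c(1, 2), 1),
    coef = matrix(c(2, -1, 0.5), 3, 1)
  )
  for (i in 1:5) {
    x <- rnorm(2)
    expect_equal(anfis_forward(one, x), sum(c(2, -1) * x) + 0.5,
                 tolerance = 1e-12)
  }
  same <- respmark:::new_anfis_model(
    centers = matrix(rnorm(4), 2), sigmas = matrix(runif(4, 0.5, 1), 2),
    coef = matrix(rep(c(1, -2, 3), 2), 3, 2)
  )
  x <- rnorm(2)
  expect_equal(anfis_forward(same, x), sum(c(1, -2) * x) + 3,
               tolerance = 1e-12)
})

test_that("output is a convex combination of rule consequents", {
  set.seed(8)
  model <- respmark:::new_anfis_model(
    centers = matrix(rnorm(8), 4), sigmas = matrix(runif(8, 0.3, 2), 4),
    coef = matrix(rnorm(12), 3)
  )
  for (i in 1:25) {
    x <- rnorm(2, sd = 2)
    f <- as.numeric(cbind(rbind(x), 1) %*% model$coef)
    out <- anfis_forward(model, x)
    expect_gte(out + 1e-10, min(f))
    expect_lte(out - 1e-10, max(f))
  }
})

test_that("underflowing firing strengths fall back to the nearest rule", {
  model <- respmark:::new_anfis_model(
    centers = matrix(c(0, 1e4), 2), sigmas = matrix(c(0.1, 0.1), 2),
    coef = matrix(c(0, 5, 0, -7), 2)  # constants 5 and -7
  )
  out <- anfis_forward(model, 5000 + 200)  # nearer the second rule
  expect_equal(as.numeric(out), -7)
  expect_true(isTRUE(attr(out, "fallback")))
})

test_that("a noiseless linear target is solved exactly by one LSE step", {
  x <- matrix(seq(-1, 1, length.out = 200), ncol = 1)
  y <- 2 * x[, 1] + 1
  fit <- fcm_cluster(x, 1, seed = 1)
  model <- train_hybrid(init_from_fcm(fit, x, y), x, y,
                        train_config(n_rules = 1, epochs = 1))
  expect_lt(tail(model$training_history$rmse_post, 1), 1e-6)
})

test_that("a constant target is fit exactly", {
  set.seed(4)
  x <- matrix(rnorm(100), ncol = 2)
  y <- rep(3.25, 50)
  fit <- fcm_cluster(x, 2, seed = 4)
  model <- train_hybrid(init_from_fcm(fit, x, y), x, y,
                        train_config(n_rules = 2, epochs = 2))
  expect_lt(tail(model$training_history$rmse_post, 1), 1e-10)
  expect_equal(as.numeric(anfis_predict(model, x)), y, tolerance = 1e-8)
})

test_that("the LSE step never raises the training RMSE", {
  set.seed(6)
  x <- matrix(runif(300, -3, 3), ncol = 1)
  y <- sin(x[, 1]) + rnorm(300, 0, 0.05)
  fit <- fcm_cluster(x, 3, seed = 6)
  model <- train_hybrid(init_from_fcm(fit, x, y), x, y,
                        train_config(n_rules = 3, epochs = 20))
  h <- model$training_history
  expect_true(all(h$rmse_lse <= h$rmse_pre + 1e-9))
})

test_that("five rules approximate sin(x) to RMSE < 0.05", {
  x <- matrix(seq(0, 2 * pi, length.out = 500), ncol = 1)
  y <- sin(x[, 1])
  fit <- fcm_cluster(x, 5, seed = 1)
  model <- train_hybrid(init_from_fcm(fit, x, y), x, y,
                        train_config(n_rules = 5, epochs = 50))
  expect_lt(tail(model$training_history$rmse_post, 1), 0.05)
})

test_that("a known two-rule Sugeno system is recovered from noisy data", {
  ok <- vapply(1:10, function(seed) {
    d <- two_rule_data(seed, n = 400, noise = 0.1)
    sp <- split_blocks(nrow(d$x), 0.7)
    xtr <- d$x[sp$train, , drop = FALSE]
    fit <- fcm_cluster(xtr, 2, seed = seed)
    model <- train_hybrid(init_from_fcm(fit, xtr, d$y[sp$train]),
                          xtr, d$y[sp$train],
                          train_config(n_rules = 2, epochs = 30, seed = seed))
    rmse(d$y[sp$test],
         anfis_predict(model, d$x[sp$test, , drop = FALSE])) <= 0.2
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the block split is deterministic, disjoint and covering", {
  sp <- split_blocks(100, 0.7)
  expect_identical(sp, split_blocks(100, 0.7))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_equal(length(sp$train), 70)
})

test_that("setup model round-trips through prediction consistently", {
  sessions <- simulate_sessions(cycles = standard_cycles()[1:2],
                                duration = 20, seed = 12)
  cfg <- train_config(epochs = 5, seed = 12)
  model <- fit_setup_model(sessions, c("M1", "M7"), cfg)
  pred <- predict_setup(model, sessions[[1]])
  expect_motion_trace(pred)
  expect_identical(pred$time, sessions[[1]]$reference$time)
  # training-set prediction error is close to the recorded training RMSE
  final <- tail(model$ap$training_history$rmse_post, 1)
  err <- rmse(pred$ap, sessions[[1]]$reference$ap)
  expect_lt(err, 3 * final + 0.5)
  # schema violations
  expect_error(marker_design(sessions[[1]], character(0)),
               class = "schema_error")
  expect_error(predict_setup(list(ap = model$ap, si = model$si,
                                  markers = c("M1", "M2")), sessions[[1]]),
               class = "schema_error")
})

test_that("prediction error on held-out data stays below twice the noise floor", {
  mk <- default_markers()
  # moderate fixed noise, no session jitter: known noise structure
  for (lab in names(mk)) mk[[lab]]$gain_jitter_sd <- 0
  sessions <- simulate_sessions(markers = mk, duration = 30, seed = 21)
  sp <- list(train = sessions[1:4], test = sessions[5])
  model <- fit_setup_model(sp$train, c("M1", "M3", "M7", "M9"),
                           train_config(epochs = 10, seed = 21))
  pred <- predict_setup(model, sp$test[[1]])
  ref <- sp$test[[1]]$reference
  noise_floor <- reference_preset()$noise_sd
  expect_lt(rmse(pred$ap, ref$ap), 2 * noise_floor + 2 * 0.6)
  expect_lt(rmse(pred$si, ref$si), 2 * noise_floor + 2 * 0.6)
})
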