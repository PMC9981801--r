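test_that("a symmetric separable pair puts the boundary at zero", {
  m <- train_classifier(matrix(c(-1, 1), ncol = 1), c(-1, 1), C = 100)
  expect_equal(sign(decision_value(m, -1)), -1)
  expect_equal(sign(decision_value(m, 1)), 1)
  expect_lt(abs(m$bias), 1e-6)
  expect_true(all(m$slacks >= 0))
})

test_that("training matches a generic QP oracle on random 20-point cohorts", {
  skip_if_not_installed("kernlab")
  for (s in 1:3) {
    set.seed(s)
    X <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
    y <- rep(c(-1, 1), each = 10)
    m <- train_classifier(X, y, C = 100)
    oracle <- qp_primal_oracle(X, y, 100)
    expect_lt(abs(m$objective - oracle$objective) /
                max(oracle$objective, 1e-12), 1e-4)
    # soft constraint satisfaction: y (r.x + g) >= 1 - zeta - tol
    margins <- y * decision_value(m, X)
    expect_true(all(margins >= 1 - m$slacks - 1e-6))
    expect_true(all(m$slacks >= 0))
  }
})

test_that("training matches the QP oracle on an overlapping cohort", {
  skip_if_not_installed("kernlab")
  set.seed(11)
  X <- rbind(matrix(rnorm(40, -0.5), 20, 2), matrix(rnorm(40, 0.5), 20, 2))
  y <- rep(c(-1, 1), each = 20)
  m <- train_classifier(X, y, C = 1)
  oracle <- qp_primal_oracle(X, y, 1)
  expect_lt(abs(m$objective - oracle$objective) / oracle$objective, 1e-4)
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(train_classifier(X, rep(1, 5), C = 1), "both classes")
  expect_error(train_classifier(X, c(1, 1, 1, 1, 0), C = 1), "-1/\\+1")
  expect_error(train_classifier(X, c(1, 1, 1, -1, -1), C = 0), "C")
  X[1, 1] <- NA
  expect_error(train_classifier(X, c(1, 1, 1, -1, -1), C = 1), "non-finite")
})

test_that("decision values equal an element-wise loop oracle", {
  set.seed(3)
  m <- structure(list(weights = rnorm(4), bias = rnorm(1), dim = 4L),
                 class = "margin_classifier")
  expect_equal(decision_value(m, c(2, 5, 0, 0)),
               sum(m$weights * c(2, 5, 0, 0)) + m$bias)
  X <- matrix(rnorm(40), 10, 4)
  loop <- vapply(seq_len(10), function(i) {
    acc <- m$bias
    for (j in 1:4) acc <- acc + m$weights[j] * X[i, j]
    acc
  }, numeric(1))
  expect_equal(decision_value(m, X), loop, tolerance = 1e-12)
  expect_error(decision_value(m, c(1, 2)), "columns")
})

test_that("calibration maximizes the smoothed Bernoulli likelihood", {
  set.seed(2)
  d <- c(rnorm(150, 2), rnorm(150, -2))
  y <- rep(c(1, -1), each = 150)
  cal <- fit_calibration(d, y)
  expect_lt(cal$S, 0)  # larger d => positive class
  # IRLS oracle on the same smoothed targets
  t <- ifelse(y > 0, (150 + 1) / (150 + 2), 1 / (150 + 2))
  gm <- stats::glm(t ~ d, family = stats::quasibinomial())
  expect_equal(unname(stats::coef(gm)), c(-cal$F, -cal$S), tolerance = 1e-6)
  # extremes saturate near the smoothed plateau
  p <- calibrated_probability(cal, d)
  expect_true(all(p[d > 3] >= 0.99))
  expect_true(all(p[d < -3] <= 0.01))
})

test_that("calibration respects symmetry and rejects degenerate input", {
  d <- c(-3, -2, -1, 1, 2, 3)
  y <- c(-1, -1, -1, 1, 1, 1)
  cal <- fit_calibration(d, y)
  expect_lt(abs(cal$F), 1e-3)  # dataset symmetric under (d, y) -> (-d, -y)
  mirrored <- fit_calibration(-d, -y)
  expect_equal(mirrored$S, cal$S, tolerance = 1e-6)
  expect_error(fit_calibration(d, rep(1, 6)), "both labels")
})

test_that("the Diabetes Index stays in [0,1] and is monotone in d", {
  m <- structure(list(weights = c(1, -2), bias = 0.3, dim = 2L),
                 class = "margin_classifier")
  flat <- structure(list(S = 0, F = 0), class = "calibration")
  set.seed(8)
  X <- matrix(rnorm(2e4, sd = 10), ncol = 2)
  expect_true(all(diabetes_index(m, flat, X) == 0.5))

  cal <- structure(list(S = -1.7, F = 0.2), class = "calibration")
  di <- diabetes_index(m, cal, X)
  expect_true(all(di >= 0 & di <= 1))
  d <- decision_value(m, X)
  expect_true(all(diff(di[order(d)]) >= 0))      # monotone non-decreasing
  # strictly monotone wherever the sigmoid is not saturated
  grid <- seq(-10, 10, length.out = 500)
  expect_true(all(diff(calibrated_probability(cal, grid)) > 0))

  # sigmoid limits
  expect_equal(calibrated_probability(cal, 1e6), 1)
  expect_equal(calibrated_probability(cal, -1e6), 0)
})

test_that("end-to-end: positives score higher and held-out accuracy >= 0.9", {
  accs <- numeric(5)
  for (s in 1:5) {
    co <- generate_cohort(cohort_spec(500, effect_size = 3, seed = s))
    ri <- cohort_risk_inputs(co, 0.5)
    idx <- seq_len(500) %% 2L == 1L
    fit <- fit_risk_model(ri$inputs[idx, ], ri$labels[idx], C = 1)
    di <- diabetes_index(fit$model, fit$calibration, ri$inputs)
    expect_gt(mean(di[ri$labels > 0]), mean(di[ri$labels < 0]))
    pred <- ifelse(di >= 0.5, 1L, -1L)
    accs[s] <- mean(pred[!idx] == ri$labels[!idx])
  }
  expect_gte(mean(accs), 0.9)
})

test_that("risk models round-trip through their text serialization", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(c(-1, 1), 15)
  fit <- fit_risk_model(X, y, C = 2)
  path <- tempfile(fileext = ".txt")
  write_risk_model(fit$model, fit$calibration, 0.5, path)
  back <- read_risk_model(path)
  expect_equal(back$model$weights, fit$model$weights)
  expect_equal(back$model$bias, fit$model$bias)
  expect_equal(back$calibration$S, fit$calibration$S)
  expect_equal(back$decay_rate, 0.5)
  expect_equal(diabetes_index(back$model, back$calibration, X),
               diabetes_index(fit$model, fit$calibration, X))
})
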