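test_that("energy matches hand values and a triple-loop oracle", {
  zero <- rbm_params(c(0, 0), c(0, 0, 0), matrix(0, 2, 3))
  for (z1 in 0:1) for (x1 in 0:1) {
    expect_equal(energy(zero, c(z1, 1), c(x1, 0, 1)), 0)
  }
  expect_equal(energy(rbm_params(1, 2, matrix(3)), 1, 1), -6)

  set.seed(9)
  p <- rbm_params(rnorm(4), rnorm(3), matrix(rnorm(12), 4, 3))
  z <- c(1, 0, 1, 1)
  x <- c(0, 1, 1)
  loop <- 0
  for (i in 1:4) loop <- loop - p$b[i] * z[i]
  for (j in 1:3) loop <- loop - p$c[j] * x[j]
  for (i in 1:4) for (j in 1:3) loop <- loop - z[i] * p$W[i, j] * x[j]
  expect_equal(energy(p, z, x), loop, tolerance = 1e-12)
  expect_error(energy(p, c(1, 0), x), "length")
})

test_that("the partition function counts states and normalizes the joint", {
  zero21 <- rbm_params(c(0, 0), 0, matrix(0, 2, 1))
  expect_equal(partition_function(zero21), 8)  # 2^3 states at exp(0)

  for (s in 1:5) {
    set.seed(s)
    p <- rbm_params(rnorm(3), rnorm(2), matrix(rnorm(6), 3, 2))
    joint <- enum_rbm_joint(p)
    expect_equal(partition_function(p), joint$B, tolerance = 1e-12)
    expect_lt(abs(sum(joint$unnorm / joint$B) - 1), 1e-12)
  }
  big <- rbm_params(numeric(15), numeric(15), matrix(0, 15, 15))
  expect_error(partition_function(big), "enumeration")
})

test_that("activation conditionals match enumeration on random small machines", {
  expect_equal(hidden_activation(rbm_params(0, c(0, 0), matrix(0, 1, 2)), 1),
               c(0.5, 0.5))
  expect_equal(visible_activation(rbm_params(c(0, 0), 0, matrix(0, 2, 1)), 1),
               c(0.5, 0.5))
  sat <- rbm_params(0, 50, matrix(0, 1, 1))
  expect_gt(hidden_activation(sat, 0)[1], 1 - 1e-10)
  neg <- rbm_params(-50, 0, matrix(0, 1, 1))
  expect_lt(visible_activation(neg, 0)[1], 1e-10)

  for (s in 1:8) {
    set.seed(100 + s)
    m <- sample(2:6, 1)
    nh <- sample(2:5, 1)
    p <- rbm_params(rnorm(m), rnorm(nh), matrix(rnorm(m * nh, sd = 1.2),
                                                m, nh))
    joint <- enum_rbm_joint(p)
    z <- sample(0:1, m, replace = TRUE)
    x <- sample(0:1, nh, replace = TRUE)
    expect_equal(hidden_activation(p, z), enum_hidden_conditional(joint, z),
                 tolerance = 1e-10)
    expect_equal(visible_activation(p, x),
                 enum_visible_conditional(joint, x), tolerance = 1e-10)
  }
})

test_that("contrastive divergence is seeded, inert at zero rate, and improves fit", {
  set.seed(20)
  data <- matrix(as.numeric(runif(50 * 6) < 0.4), 50, 6)

  frozen <- train_cd(data, 3, epochs = 5, learning_rate = 0, seed = 2)
  init <- local({  # re-derive the seeded initialization directly
    set.seed(2L)
    matrix(rnorm(6 * 3, sd = 0.01), 6, 3)
  })
  expect_equal(frozen$W, init)
  expect_equal(frozen$b, numeric(6))
  expect_equal(frozen$c, numeric(3))

  a <- train_cd(data, 3, epochs = 10, learning_rate = 0.1, seed = 5)
  b <- train_cd(data, 3, epochs = 10, learning_rate = 0.1, seed = 5)
  expect_identical(a, b)
  c3 <- train_cd(data, 3, epochs = 10, learning_rate = 0.1, seed = 6)
  expect_false(identical(a$W, c3$W))

  trained <- train_cd(data, 3, epochs = 80, learning_rate = 0.1, seed = 3)
  expect_lte(reconstruction_error(trained, data),
             reconstruction_error(frozen, data))
  expect_error(train_cd(data[0, ], 3), "windows")
})

test_that("CD training does not decrease exact log-likelihood on planted data", {
  # plant an 6+4-unit machine, sample from it by Gibbs, retrain from scratch
  set.seed(7)
  planted <- rbm_params(rnorm(6, sd = 0.5), rnorm(4, sd = 0.5),
                        matrix(rnorm(24, sd = 1.5), 6, 4))
  v <- matrix(as.numeric(runif(200 * 6) < 0.5), 200, 6)
  for (it in 1:200) {
    ph <- sigmoidm(sweep(v %*% planted$W, 2, planted$c, `+`))
    h <- (matrix(runif(200 * 4), 200, 4) < ph) * 1
    pv <- sigmoidm(sweep(h %*% t(planted$W), 2, planted$b, `+`))
    v <- (matrix(runif(200 * 6), 200, 6) < pv) * 1
  }
  p0 <- train_cd(v, 4, epochs = 1, learning_rate = 0, seed = 11)
  pt <- train_cd(v, 4, epochs = 200, learning_rate = 0.1, seed = 11)
  expect_gte(rbm_log_likelihood(pt, v), rbm_log_likelihood(p0, v))
})

test_that("rmse matches definition and a loop oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(3, 1), 2)
  set.seed(12)
  p <- rnorm(100)
  a <- rnorm(100)
  acc <- 0
  for (i in 1:100) acc <- acc + (p[i] - a[i])^2
  expect_equal(rmse(p, a), sqrt(acc / 100), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "equal")
  expect_error(rmse(numeric(0), numeric(0)), "non-zero")
})

test_that("window encoding is invertible and windows align with the series", {
  tr <- generate_trace(trace_spec(length = 60, seed = 3))
  enc <- window_encoding(tr, lag = 4)
  v <- tr$values
  expect_equal(decode_values(enc, encode_values(enc, v)), v,
               tolerance = 1e-9)
  win <- make_windows(enc, tr)
  expect_equal(dim(win), c(56, 5))
  expect_equal(win[1, ], encode_values(enc, v[1:5]))
  expect_equal(win[56, ], encode_values(enc, v[56:60]))
  # constant series: padded range keeps max > min
  cenc <- window_encoding(rep(6, 10), lag = 2)
  expect_gt(cenc$max, cenc$min)
  expect_equal(decode_values(cenc, encode_values(cenc, 6)), 6)
})
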