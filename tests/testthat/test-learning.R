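test_that("ridge_fit recovers the identity-design solution and shrinks", {
  Y <- matrix(c(1, 2, 3), 3)
  expect_equal(ridge_fit(diag(3), Y, lambda = 0), t(Y))

  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  Ym <- matrix(rnorm(40), 20, 2)
  norms <- vapply(c(0.1, 1, 5, 20), function(l) {
    sum(ridge_fit(X, Ym, l)^2)
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("ridge_fit matches an independent normal-equations solve", {
  fx <- make_fixture("ridge_small", seed = 9)
  X <- fx$payload$X
  Y <- fx$payload$Y
  l <- fx$payload$lambda
  # oracle: augmented least squares [X; lambda I] \ [Y; 0] via QR
  Xa <- rbind(X, l * diag(ncol(X)))
  Ya <- rbind(Y, matrix(0, ncol(X), ncol(Y)))
  W_or <- t(qr.solve(Xa, Ya))
  expect_equal(ridge_fit(X, Y, l), W_or, tolerance = 1e-8)
})

test_that("ridge training error is non-increasing as lambda decreases", {
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5)
  Y <- matrix(rnorm(40), 40, 1)
  errs <- vapply(c(10, 3, 1, 0.3, 0.1), function(l) {
    W <- ridge_fit(X, Y, l)
    sum((X %*% t(W) - Y)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("singular ridge system at lambda = 0 gives a named error", {
  X <- matrix(1, 4, 3)   # rank 1
  Y <- matrix(1, 4, 1)
  expect_error(ridge_fit(X, Y, 0), "lambda")
})

test_that("BPDC update matches the hand-evaluated scalar case", {
  cfg <- bpdc_config(eta = 1, beta = 1, dt = 0.5)
  dW <- bpdc_update(z_t = 1, x_t = 0, e_t = 1, e_t1 = 0.2, cfg)
  expect_equal(as.numeric(dW), 0.3)
  # zero error and zero state both give a zero update
  expect_equal(as.numeric(bpdc_update(1, 0, 0, 0, cfg)), 0)
  expect_equal(as.numeric(bpdc_update(0, 0, 1, 0.2, cfg)), 0)
})

test_that("kwta keeps the k largest entries, ties to the lowest index", {
  expect_equal(kwta(c(3, 1, 2), 1), c(3, 0, 0))
  expect_equal(kwta(c(2, 2, 1), 1), c(2, 0, 0))
  v <- c(0.5, -1, 2, 0.5)
  expect_equal(kwta(v, 4), v)
  expect_equal(kwta(v, 2), c(0.5, 0, 2, 0))
  expect_error(kwta(v, 0))
  expect_error(kwta(v, 5))
})

test_that("Oja/kWTA update has the documented zeros and fixed point", {
  cfg <- oja_config(eta_sx = 0.1, k_striatum = 1, k_cortex = 1,
                    noise_sigma = 0)
  W <- matrix(0.3, 3, 4)
  expect_equal(oja_kwta_update(W, rep(0, 3), runif(4), cfg, noise = FALSE),
               matrix(0, 3, 4))
  # algebraic fixed point: W = s c^T / s^2 on the winning entries, rest 0
  s <- c(0.8, 0, 0)
  cc <- c(0, 1, 0, 0)
  Wfp <- matrix(0, 3, 4)
  Wfp[1, 2] <- cc[2] / s[1]
  expect_equal(oja_kwta_update(Wfp, s, cc, cfg, noise = FALSE),
               matrix(0, 3, 4), tolerance = 1e-12)
  # single-winner hand case from W = 0
  dW <- oja_kwta_update(matrix(0, 3, 4), s, cc, cfg, noise = FALSE)
  expect_equal(dW[1, 2], 0.1 * 0.8)
  expect_equal(sum(dW != 0), 1L)
})

test_that("Oja weights stay bounded over 1e4 iterations", {
  set.seed(11)
  cfg <- oja_config(eta_sx = 0.01, k_striatum = 1, k_cortex = 5,
                    noise_sigma = 0)
  W <- matrix(0, 2, 10)
  for (i in 1:10000) {
    s <- c(abs(rnorm(1, 0.8, 0.05)), 0)
    cc <- abs(rnorm(10, 0.5, 0.1))
    W <- W + oja_kwta_update(W, s, cc, cfg, noise = FALSE)
    if (i %% 1000 == 0) expect_lt(sqrt(sum(W[1, ]^2)), 10)
  }
  # classic Oja self-normalization: winning row norm is O(||c||/s)
  expect_lt(sqrt(sum(W[1, ]^2)), 5)
  expect_equal(W[2, ], rep(0, 10))
})

test_that("Oja noise is drawn from the seeded R stream", {
  cfg <- oja_config(noise_sigma = 0.1)
  W <- matrix(0, 2, 3)
  set.seed(7)
  d1 <- oja_kwta_update(W, c(0.5, 0.4), c(1, 0, 0), cfg, noise = TRUE)
  set.seed(7)
  d2 <- oja_kwta_update(W, c(0.5, 0.4), c(1, 0, 0), cfg, noise = TRUE)
  expect_identical(d1, d2)
})
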