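test_that("reservoir construction is seed-deterministic and normalized", {
  r1 <- small_reservoir(seed = 5)
  r2 <- small_reservoir(seed = 5)
  expect_identical(r1$W_u, r2$W_u)
  expect_identical(r1$W_ux, r2$W_ux)
  r3 <- small_reservoir(seed = 6)
  expect_false(identical(r1$W_u, r3$W_u))

  sp <- r1$spec
  expect_equal(effective_radius(r1$W_u, sp$dt, sp$tau),
               sp$effective_spectral_radius, tolerance = 1e-6)
})

test_that("unit partition is disjoint, complete, and input rows are masked", {
  r <- small_reservoir(n_units = 90)
  p <- r$partition
  expect_length(intersect(p$loop, p$input), 0)
  expect_length(intersect(p$loop, p$free), 0)
  expect_length(intersect(p$input, p$free), 0)
  expect_setequal(c(p$loop, p$input, p$free), seq_len(90))
  expect_equal(length(unique(lengths(p$channels))), 1L)  # equal sub-populations
  outside <- setdiff(seq_len(90), p$input)
  expect_true(all(r$W_ux[outside, ] == 0))
})

test_that("echo-state property: activity fades to zero without input", {
  mod <- small_module(n_units = 100)
  Tn <- 1500
  x <- matrix(0.5 * (1 + sin(2 * pi * (1:Tn) / 1000)), 1)
  x[, 1001:Tn] <- 0
  out <- run_module(mod, x, matrix(0, 3, Tn), rep(0, Tn))
  # 500 ms = 50 tau after input offset
  expect_lt(max(abs(out$mod$ctx$z)), 1e-3)
})

test_that("cortical step is causal: identical inputs give identical states", {
  mod <- small_module(seed = 8)
  Tn <- 300
  set.seed(2)
  x1 <- matrix(runif(Tn), 1)
  x2 <- x1
  x2[, 201:Tn] <- x2[, 201:Tn] + 1   # diverge only after step 200
  o1 <- run_module(mod, x1, matrix(0, 3, Tn), rep(0, Tn), record = c(200, 300))
  o2 <- run_module(mod, x2, matrix(0, 3, Tn), rep(0, Tn), record = c(200, 300))
  expect_equal(o1$Z[, 1], o2$Z[, 1])
  expect_false(isTRUE(all.equal(o1$Z[, 2], o2$Z[, 2])))
})

test_that("the settled rest state is a fixed point of the module step", {
  mod <- small_module()
  # settle to the resting equilibrium (GPi carries tonic drive, so rest
  # is not the all-zero state)
  Tn <- 2000
  mod <- run_module(mod, matrix(0, 1, Tn), matrix(0, 3, Tn), rep(0, Tn))$mod
  out <- step_module(mod, 0, c(0, 0, 0), da = 0)
  expect_equal(out$ctx$u, mod$ctx$u, tolerance = 1e-9)
  expect_equal(out$bg$gpi$u, mod$bg$gpi$u, tolerance = 1e-9)
  expect_equal(out$tha$u, mod$tha$u, tolerance = 1e-9)
  expect_equal(max(abs(out$ctx$z)), 0)  # cortex silent at rest
})

test_that("raising one channel's thalamic drive lifts that sub-population", {
  r <- small_reservoir(n_units = 90)
  mod <- csntc_module(r)
  st <- layer_state(90)
  for (i in 1:300) {
    st <- step_cortex(r, st, x = 0.5, thal_drive = c(0, 0.8, 0))
  }
  pool <- vapply(r$partition$channels, function(ix) mean(st$z[ix]), 0)
  expect_gt(pool[2], pool[1])
  expect_gt(pool[2], pool[3])
})

test_that("read_out is the plain linear map", {
  z <- c(0.2, 0.5, 0.1)
  expect_equal(read_out(matrix(0, 2, 3), z), c(0, 0))
  sel <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(read_out(sel, z), z[c(1, 3)])
  set.seed(3)
  W <- matrix(rnorm(6), 2, 3)
  oracle <- c(sum(W[1, ] * z), sum(W[2, ] * z))
  expect_equal(read_out(W, z), oracle)
})

test_that("infeasible spectral targets are rejected", {
  expect_error(reservoir_spec(effective_spectral_radius = 0.85),
               "leak floor")
  expect_error(reservoir_spec(loop_fraction = 0.7, input_fraction = 0.4))
})
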