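test_that("striatal drives implement multiplicative dopamine modulation", {
  bp <- bg_params()
  c_in <- c(0.1, 0.3)
  x_in <- c(0.5, 0)
  inp <- bp$w_cs * c_in + bp$w_xs * x_in
  expect_equal(striatal_drive_d1(c_in, x_in, 0, bp), bp$bl_d1 * inp)
  expect_equal(striatal_drive_d2(c_in, x_in, 0, bp), inp / bp$bl_d2)
  # D1 affine (increasing) in dopamine, D2 hyperbolic (decreasing)
  das <- seq(0, 2, by = 0.25)
  d1 <- vapply(das, function(d) striatal_drive_d1(c_in, x_in, d, bp)[1], 0)
  expect_equal(diff(d1), rep(bp$da_d1 * 0.25 * inp[1], length(das) - 1))
  d2 <- vapply(das, function(d) striatal_drive_d2(c_in, x_in, d, bp)[1], 0)
  expect_true(all(diff(d2) < 0))
  # doubling the divisor halves the drive
  bp2 <- bg_params(bl_d2 = 2 * bp$bl_d2, da_d2 = 2 * bp$da_d2)
  expect_equal(striatal_drive_d2(c_in, x_in, 1, bp2),
               striatal_drive_d2(c_in, x_in, 1, bp) / 2)
  expect_equal(striatal_drive_d1(c_in, 0 * x_in, 2, bp)[2],
               (bp$bl_d1 + 2 * bp$da_d1) * bp$w_cs * c_in[2])
  expect_equal(striatal_drive_d1(0 * c_in, 0 * x_in, 1.3, bp), c(0, 0))
})

test_that("symmetric inputs yield identical rates on every channel", {
  st <- bg_steady(rep(0.2, 3), rep(0.6, 3), da = 1)
  for (layer in c("strd1", "strd2", "stn", "gpe", "gpi")) {
    expect_equal(diff(range(st[[layer]]$z)), 0, tolerance = 1e-12)
  }
})

test_that("the channel with the largest striatal input has minimal GPi rate", {
  for (name in c("bg2", "bg3")) {
    fx <- make_fixture(name)
    pl <- fx$payload
    st <- bg_steady(pl$c_in, pl$x_in, pl$da, pl$params)
    expect_equal(which.min(st$gpi$z), pl$expected_winner)
    others <- st$gpi$z[-pl$expected_winner]
    expect_true(all(others > st$gpi$z[pl$expected_winner]))
  }
})

test_that("stepped steady state matches the root-finding fixed point", {
  for (name in c("bg2", "bg3")) {
    fx <- make_fixture(name)
    pl <- fx$payload
    st <- bg_steady(pl$c_in, pl$x_in, pl$da, pl$params)
    fp <- bg_fixed_point(pl$c_in, pl$x_in, pl$da, pl$params,
                         u0 = c(st$strd1$u, st$strd2$u, st$stn$u,
                                st$gpe$u, st$gpi$u))
    for (layer in c("strd1", "strd2", "stn", "gpe", "gpi")) {
      expect_equal(st[[layer]]$u, fp[[layer]]$u, tolerance = 1e-4)
      expect_equal(st[[layer]]$z, fp[[layer]]$z, tolerance = 1e-4)
    }
  }
})

test_that("the circuit is equivariant under channel permutation", {
  perm <- c(3, 1, 2)
  c_in <- c(0.1, 0.25, 0.05)
  x_in <- c(0.9, 0.1, 0.4)
  st <- bg_steady(c_in, x_in, 1)
  stp <- bg_steady(c_in[perm], x_in[perm], 1)
  for (layer in c("strd1", "strd2", "stn", "gpe", "gpi")) {
    expect_equal(stp[[layer]]$z, st[[layer]]$z[perm], tolerance = 1e-9)
  }
})

test_that("gpi_to_thalamic_gate is proportional inhibition", {
  bp <- bg_params()
  expect_equal(gpi_to_thalamic_gate(c(0, 0.5, 1), bp),
               -bp$w_gpitha * c(0, 0.5, 1))
  g <- gpi_to_thalamic_gate(seq(0, 1, 0.1), bp)
  expect_true(all(diff(g) < 0))    # lower GPi rate, weaker inhibition
  expect_true(all(g <= 0))
})

test_that("parameter validation catches degenerate dopamine settings", {
  expect_error(bg_params(bl_d2 = 0))
  expect_error(bg_params(w_gpitha = -1), "non-negative")
  st <- bg_state(2)
  expect_error(step_bg(st, c(0.1, 0.1, 0.1), c(0, 0), 1), "length")
})
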