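test_that("forward kinematics matches hand-composed planar rotations", {
  arm <- arm_model()
  expect_equal(forward_kinematics(c(0, 0, 0), arm)$end, c(3, 0))
  expect_equal(forward_kinematics(c(pi / 2, 0, 0), arm)$end, c(0, 3))
  expect_equal(forward_kinematics(c(pi / 2, -pi / 2, 0), arm)$end, c(2, 1))
})

test_that("adding delta to joint 1 rotates the whole arm about the origin", {
  arm <- arm_model(lengths = c(1, 0.8, 0.6))
  q <- c(0.3, -0.2, 0.7)
  delta <- 0.45
  p0 <- forward_kinematics(q, arm)$end
  p1 <- forward_kinematics(q + c(delta, 0, 0), arm)$end
  R <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2)
  expect_equal(p1, as.numeric(R %*% p0), tolerance = 1e-12)
})

test_that("inverse kinematics round-trips the catalogue curves", {
  arm <- arm_model()
  for (shape in shape_catalogue()) {
    xy <- shape_curve(shape, n_samples = 50)
    q <- inverse_kinematics(xy[1, ], arm)
    for (i in seq_len(nrow(xy))) {
      q <- inverse_kinematics(xy[i, ], arm, init = q)
      expect_lt(sqrt(sum((forward_kinematics(q, arm)$end - xy[i, ])^2)), 1e-3)
    }
  }
})

test_that("unreachable targets are refused with the arm's reach", {
  expect_error(inverse_kinematics(c(4, 0)), "reach")
})

test_that("targets scale as similarity transforms and postures are constant", {
  xy1 <- shape_curve("square", 100, scale = 0.5)
  xy2 <- shape_curve("square", 100, scale = 0.25)
  ext <- function(m) apply(m, 2, function(v) diff(range(v)))
  expect_equal(ext(xy1) / ext(xy2), c(2, 2), tolerance = 1e-10)

  tg <- make_posture_target(c(0.2, 0.5, 0.1), n_samples = 20)
  expect_true(all(apply(tg$angles, 2, function(v) diff(range(v))) == 0))
  expect_equal(tg$kind, "endpoint")
})

test_that("catalogue shapes are reachable within default joint limits", {
  arm <- arm_model()
  for (shape in c("square", "figure8", "moon")) {
    tg <- make_target(shape, n_samples = 100, arm = arm)
    expect_true(all(tg$angles >= matrix(arm$joint_limits[, 1], 100, 3, TRUE)))
    expect_true(all(tg$angles <= matrix(arm$joint_limits[, 2], 100, 3, TRUE)))
    # round trip through the read-out rate map
    back <- t(apply(tg$rates, 1, rates_to_angles, arm = arm))
    expect_equal(back, tg$angles, tolerance = 1e-10)
    # FK of the recovered angles reproduces the curve
    xy <- forward_kinematics(tg$angles, arm)
    expect_lt(max(abs(xy - tg$xy)), 1e-3)
  }
})

test_that("nrmse has the documented exact values and invariances", {
  set.seed(21)
  tg <- matrix(rnorm(60), 20, 3)
  expect_equal(nrmse(tg, tg), 0)
  # constant offset: c / range per dimension, averaged
  off <- tg + 0.3
  expect_equal(nrmse(off, tg),
               mean(0.3 / apply(tg, 2, function(v) diff(range(v)))))
  # translation invariance (pred and target jointly shifted)
  pr <- tg + matrix(rnorm(60, sd = 0.1), 20)
  expect_equal(nrmse(pr + 5, tg + 5), nrmse(pr, tg))
  # independent two-pass oracle
  oracle <- {
    tot <- 0
    for (d in 1:3) {
      sse <- 0
      for (i in 1:20) sse <- sse + (pr[i, d] - tg[i, d])^2
      tot <- tot + sqrt(sse / 20) / (max(tg[, d]) - min(tg[, d]))
    }
    tot / 3
  }
  expect_equal(nrmse(pr, tg), oracle)
  expect_error(nrmse(tg, matrix(1, 20, 3)), "zero range")
})
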