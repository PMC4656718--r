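test_that("R step_module and the compiled kernel agree step for step", {
  mod <- small_module(seed = 4, n_units = 60)
  Tn <- 60
  set.seed(9)
  xc <- matrix(runif(Tn), 1)
  xs <- matrix(runif(3 * Tn, 0, 0.5), 3)
  da <- round(runif(Tn))
  modR <- mod
  for (t in seq_len(Tn)) modR <- step_module(modR, xc[, t], xs[, t], da[t])
  outC <- run_module(mod, xc, xs, da)
  expect_equal(modR$ctx$u, outC$mod$ctx$u, tolerance = 1e-12)
  expect_equal(modR$tha$u, outC$mod$tha$u, tolerance = 1e-12)
  for (layer in c("strd1", "strd2", "stn", "gpe", "gpi")) {
    expect_equal(modR$bg[[layer]]$u, outC$mod$bg[[layer]]$u, tolerance = 1e-12)
  }
})

test_that("the scripted schedule reproduces the selection event sequence", {
  fx <- make_fixture("lockin_schedule")
  out <- lockin_run(small_module(seed = 3, n_units = 100), fx)
  tr <- out$trace
  k <- fx$payload$channel
  Tn <- fx$payload$T
  da_on <- which(fx$payload$da > 0)[1]
  da_off <- fx$payload$da_off
  bias_off <- fx$payload$bias_off

  # (0) before dopamine: no striatal D1 activity, GPi tonic on all channels
  expect_lt(max(tr$strd1[, 1:(da_on - 1)]), 0.05)
  expect_gt(min(tr$gpi[, da_on - 1]), 0.5)

  after <- function(v, t0, pred) t0 + which(pred(v[t0:length(v)]))[1] - 1

  # (1) StrD1 of the biased channel rises after dopamine onset
  t_d1 <- after(tr$strd1[k, ], da_on, function(v) v > 0.5)
  expect_gt(t_d1, da_on)

  # (2) selective GPi dip follows the StrD1 rise
  t_gpi <- after(tr$gpi[k, ], da_on, function(v) v < 0.1)
  expect_gt(t_gpi, t_d1)
  expect_gt(min(tr$gpi[-k, t_gpi]), 0.5)  # other channels stay tonic

  # (3, 4) up-state lock-in: thalamus and cortical sub-population of the
  # selected channel high, persisting >= 500 ms beyond the bias offset
  t_lock <- after(tr$tha[k, ], da_on, function(v) v > 0.5)
  expect_gt(t_lock, t_gpi)
  expect_lt(t_lock, bias_off)
  hold <- bias_off:(bias_off + 500)
  expect_true(all(tr$tha[k, hold] > 0.5))
  pool_k <- tr$ctx[k, hold]
  expect_true(all(pool_k > apply(tr$ctx[-k, hold, drop = FALSE], 2, max)))

  # (5-7) unlock within 500 ms of dopamine offset: GPi differences fade
  # and the loop returns to the down state
  rel <- (da_off + 1):(da_off + 500)
  expect_lt(max(tr$tha[k, (da_off + 500):Tn]), 0.1)
  expect_lt(diff(range(tr$gpi[, Tn])), 0.05)
  expect_gt(min(tr$gpi[, Tn]), 0.5)
  t_unlock <- rel[which(tr$tha[k, rel] < 0.1)[1]]
  expect_lt(t_unlock, da_off + 500)
})

test_that("selection requires cortical background activity", {
  fx <- make_fixture("lockin_schedule")
  mod <- small_module(seed = 3, n_units = 100)
  silent <- fx$payload$x_ctx * 0
  out <- run_module(mod, silent, fx$payload$x_str, fx$payload$da, trace = TRUE)
  expect_equal(max(out$trace$tha), 0)
  expect_equal(max(out$trace$ctx), 0)
})

test_that("identical sinusoid with different selected channels gives
           distinct cortical trajectories", {
  fx <- make_fixture("lockin_schedule")
  mod <- small_module(seed = 3, n_units = 100)
  xs1 <- fx$payload$x_str
  xs2 <- xs1[c(2, 1, 3), ]   # move the bias to channel 1
  o1 <- run_module(mod, fx$payload$x_ctx, xs1, fx$payload$da,
                   record = 2000:2100)
  o2 <- run_module(mod, fx$payload$x_ctx, xs2, fx$payload$da,
                   record = 2000:2100)
  expect_gt(mean(abs(o1$Z - o2$Z)), 0.05)
})

test_that("lesions zero exactly the named bundles and reject unknown ones", {
  mod <- small_module()
  expect_identical(lesion(mod, character(0))$W_sx, mod$W_sx)
  l1 <- lesion(mod, "striatal_input")
  expect_true(all(l1$W_sx == 0))
  expect_identical(l1$frozen, "striatal_input")
  expect_error(lesion(mod, "no_such_bundle"), "unknown")

  sys <- csntc_system(n_units = 40, seed = 2)
  expect_error(lesion(sys, "readout"), "unknown")
  l2 <- lesion(sys, c("pfc_to_hl_striatum", "hlctx_to_pm_striatum"))
  expect_true(all(l2$G_code_hlstr == 0))
  expect_true(all(l2$W_sx == 0))
  # construction-time lesion spec gives the same frozen set
  sysf <- csntc_system(n_units = 40, seed = 2, lesion = "full")
  expect_setequal(sysf$frozen, l2$frozen)
  expect_true(all(sysf$G_code_hlstr == 0))
})

test_that("zeroing one channel's striatal input leaves other selections intact", {
  fx <- make_fixture("lockin_schedule")
  mod <- small_module(seed = 3, n_units = 100)
  # channel 3's input line cut; bias is on channel 2: selection unchanged
  mod_cut <- mod
  mod_cut$W_sx[3, 3] <- 0
  o1 <- run_module(mod, fx$payload$x_ctx, fx$payload$x_str, fx$payload$da,
                   trace = TRUE)
  o2 <- run_module(mod_cut, fx$payload$x_ctx, fx$payload$x_str, fx$payload$da,
                   trace = TRUE)
  expect_equal(o1$trace$gpi, o2$trace$gpi, tolerance = 1e-12)
})
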