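# Pipeline-level tests at reduced sizes; the full study conditions run in
# test-acceptance.R.

test_that("loop experiment records have the protocol's bookkeeping shape", {
  mod <- csntc_module(build_reservoir(reservoir_spec(n_units = 100, seed = 11)))
  targets <- lapply(c("square", "figure8", "moon"), make_target,
                    n_samples = 1000)
  p <- loop_protocol(seed = 5)
  res <- run_loop_experiment(mod, targets, p)
  r <- res$records
  expect_equal(nrow(r), p$n_test_sessions * p$n_tasks)
  # each session contains each task exactly once
  for (s in unique(r$session)) {
    expect_setequal(r$task[r$session == s], 1:3)
  }
  expect_true(all(r$nrmse >= 0))
  expect_equal(dim(res$W_oz), c(3L, 100L))
})

test_that("loop experiment is deterministic given config and seed", {
  mod <- csntc_module(build_reservoir(reservoir_spec(n_units = 80, seed = 2)))
  targets <- lapply(c("square", "figure8", "moon"), make_target,
                    n_samples = 1000)
  p <- loop_protocol(seed = 9, n_test_sessions = 1)
  r1 <- run_loop_experiment(mod, targets, p)
  r2 <- run_loop_experiment(mod, targets, p)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$W_oz, r2$W_oz)
})

test_that("the trained read-out beats the untrained null model", {
  mod <- csntc_module(build_reservoir(reservoir_spec(n_units = 100, seed = 11)))
  targets <- lapply(c("square", "figure8", "moon"), make_target,
                    n_samples = 1000)
  res <- run_loop_experiment(mod, targets, loop_protocol(seed = 5))
  trained <- res$records$nrmse[res$records$session == 3]
  null_model <- vapply(res$last_session, function(tr) {
    nrmse(tr$pred * 0, tr$target)
  }, 0)
  expect_true(all(trained < 0.5))
  expect_gt(min(null_model), 3 * max(trained))
})

test_that("online BPDC training reduces the running NRMSE across sessions", {
  mod <- csntc_module(build_reservoir(reservoir_spec(n_units = 100, seed = 11)))
  targets <- lapply(c("square", "figure8", "moon"), make_target,
                    n_samples = 1000)
  res <- run_loop_experiment(mod, targets,
                             loop_protocol(seed = 5, n_test_sessions = 1),
                             method = "bpdc", n_train_sessions = 12,
                             bpdc = bpdc_config(eta = 0.01))
  s <- res$session_nrmse
  # monotone trend over windows of sessions, not per-session
  w <- vapply(split(s, rep(1:4, each = 3)), mean, 0)
  expect_true(all(diff(w) < 0))
  expect_lt(w[4], 0.6 * w[1])
})

test_that("endpoint pipeline reaches permuted postures consistently", {
  mod <- csntc_module(build_reservoir(reservoir_spec(n_units = 100, seed = 11)))
  postures <- rbind(c(0.3, 0.6, -0.3), c(1.2, -0.4, 0.8), c(0.1, 1.0, 0.5))
  res <- run_endpoint_experiment(mod, postures, loop_protocol(seed = 5))
  expect_equal(dim(res$joint_errors), c(3L, 3L))
  expect_lt(max(res$joint_errors), 0.05)
  # permuting the task-channel assignment permutes the reached postures
  res_p <- run_endpoint_experiment(mod, postures[c(2, 3, 1), ],
                                   loop_protocol(seed = 5))
  expect_lt(max(res_p$joint_errors), 0.05)
})

test_that("system records are deterministic and correctly shaped", {
  rec <- run_system_experiment("baseline", n_repeats = 1, seed = 3,
                               n_units = 60, oja_sessions = 2,
                               protocol = system_protocol(n_test_sessions = 2))
  expect_equal(nrow(rec), 2 * 3)   # SAME and DIFF, one row per task
  expect_setequal(rec$condition, c("SAME", "DIFF"))
  expect_setequal(rec$task[rec$condition == "SAME"], 1:3)
  rec2 <- run_system_experiment("baseline", n_repeats = 1, seed = 3,
                                n_units = 60, oja_sessions = 2,
                                protocol = system_protocol(n_test_sessions = 2))
  expect_identical(rec, rec2)
})

test_that("lesion groups share networks within a repeat (same seeds)", {
  # the lesioned run must differ from baseline only through the lesion:
  # identical reservoirs are guaranteed by the shared structural seed
  s1 <- csntc_system(n_units = 40, seed = 7, lesion = "baseline")
  s2 <- csntc_system(n_units = 40, seed = 7, lesion = "partial")
  expect_identical(s1$pm$res$W_u, s2$pm$res$W_u)
  expect_identical(s1$W_hl_pmctx, s2$W_hl_pmctx)
  expect_identical(s1$G_code_hlstr, s2$G_code_hlstr)
  s3 <- csntc_system(n_units = 40, seed = 7, lesion = "full")
  expect_true(all(s3$G_code_hlstr == 0))
})

test_that("protocol invariants are enforced", {
  expect_error(loop_protocol(task_start = 400), "da_on < task_start")
  expect_error(loop_protocol(task_end = 3600))
  expect_error(loop_protocol(trial_ms = 4500))  # not a sine-period multiple
})

test_that("the architecture scales to four tasks on four channels", {
  mod <- csntc_module(build_reservoir(reservoir_spec(n_units = 200,
                                                     n_channels = 4,
                                                     seed = 11)))
  targets <- lapply(c("square", "figure8", "moon", "circle"), make_target,
                    n_samples = 1000)
  res <- run_loop_experiment(mod, targets,
                             loop_protocol(n_tasks = 4, seed = 5,
                                           n_test_sessions = 1))
  expect_equal(sort(res$records$task), 1:4)
  expect_true(all(res$records$nrmse < 0.2))
})
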