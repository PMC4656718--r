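#' Session/trial protocol for single-module experiments
#'
#' Timing of one trial and the composition of sessions.  Within each trial
#' the dopamine efflux switches on shortly after trial onset and off
#' before its end; a binary striatal bias selects the channel during an
#' early interval; the scored "task window" lies inside the dopamine
#' interval, after the selection has locked in.  A session recalls each
#' task once, in random order.  There is no state reset anywhere: sessions
#' and trials run as one continuous simulation.
#'
#' @param n_tasks number of tasks (= basal ganglia channels used).
#' @param trial_ms trial duration (ms); a multiple of `sine_period`, so
#'   the sinusoidal context signal has the same phase at the same offset
#'   of every trial.
#' @param da_on,da_off dopamine interval within the trial (ms).
#' @param bias_on,bias_off striatal bias interval (ms); the bias switches
#'   off well before the dopamine does, demonstrating lock-in.
#' @param task_start,task_end the scored task window (ms), strictly inside
#'   the dopamine interval and starting after the selection lock-in
#'   transient.
#' @param sine_period,sine_amp period (ms) and amplitude of the sinusoidal
#'   context input to the cortex: `x(t) = amp * (1 + sin(2 pi t / period))`.
#' @param bias_amp amplitude of the binary striatal bias.
#' @param n_test_sessions test sessions; only the last is scored (the
#'   first ones verify the behaviour is stable).
#' @param seed RNG seed for trial-order permutations.
#' @return An object of class `loop_protocol`.
#' @export
loop_protocol <- function(n_tasks = 3, trial_ms = 4000,
                          da_on = 500, da_off = 3500,
                          bias_on = 500, bias_off = 1500,
                          task_start = 1200, task_end = 3200,
                          sine_period = 1000, sine_amp = 0.5, bias_amp = 1,
                          n_test_sessions = 3, seed = 1L) {
  stopifnot(da_on < task_start, task_start < task_end, task_end < da_off,
            da_off < trial_ms, bias_on >= da_on, bias_off <= da_off,
            trial_ms %% sine_period == 0, n_tasks >= 1)
  structure(list(n_tasks = as.integer(n_tasks), trial_ms = trial_ms,
                 da_on = da_on, da_off = da_off,
                 bias_on = bias_on, bias_off = bias_off,
                 task_start = task_start, task_end = task_end,
                 sine_period = sine_period, sine_amp = sine_amp,
                 bias_amp = bias_amp,
                 n_test_sessions = as.integer(n_test_sessions),
                 seed = as.integer(seed)),
            class = "loop_protocol")
}

# Expand a list of per-session task orders into full input schedules.
# Returns per-step matrices/vectors covering all trials back to back.
# `amps`, when given, is a per-trial constant-input amplitude (second
# cortical input line) aligned with the unlisted task order.
loop_schedule <- function(protocol, session_tasks, amps = NULL, t0 = 0) {
  p <- protocol
  tasks <- unlist(session_tasks)
  n_trials <- length(tasks)
  Tn <- n_trials * p$trial_ms
  tt <- seq_len(Tn) + t0                     # global time, ms
  trial <- rep(seq_len(n_trials), each = p$trial_ms)
  toff <- (seq_len(Tn) - 1) %% p$trial_ms + 1  # time within trial
  m <- if (is.null(amps)) 1L else 2L
  X_ctx <- matrix(0, m, Tn)
  X_ctx[1, ] <- p$sine_amp * (1 + sin(2 * pi * tt / p$sine_period))
  if (!is.null(amps)) {
    stopifnot(length(amps) == n_trials)
    X_ctx[2, ] <- amps[trial]
  }
  X_str <- matrix(0, p$n_tasks, Tn)
  on_bias <- toff >= p$bias_on & toff < p$bias_off
  X_str[cbind(tasks[trial], seq_len(Tn))] <- ifelse(on_bias, p$bias_amp, 0)
  da <- as.numeric(toff >= p$da_on & toff < p$da_off)
  win <- toff >= p$task_start & toff < p$task_end
  phase <- ((tt - 1) %% p$sine_period) + 1   # 1..sine_period, global phase
  list(X_ctx = X_ctx, X_str = X_str, da = da, win = win,
       task = tasks[trial], trial = trial, phase = phase, Tn = Tn)
}

# Target read-out rates for the recorded window steps of one schedule.
# Each target_task supplies one row per ms of sine phase.
target_rows <- function(targets, sch, steps) {
  do.call(rbind, lapply(steps, function(t) {
    tg <- targets[[sch$task[t]]]
    tg$rates[(sch$phase[t] - 1) %% nrow(tg$rates) + 1, , drop = FALSE]
  }))
}

#' Run the rhythmic-trajectory (LOOP) experiment
#'
#' Trains read-out units to decode the selected cortical dynamics into
#' per-joint command rates, then tests recall.  Training is either batch
#' Tikhonov regression over one storage session (`method = "ridge"`) or
#' online backpropagation-decorrelation over many sessions
#' (`method = "bpdc"`).  The simulation is continuous: training and test
#' sessions run back to back with no state reset, and the scored errors
#' come from the last test session only.
#'
#' @param mod a [csntc_module()] whose channel count matches
#'   `protocol$n_tasks`.
#' @param targets list of [make_target()] tasks, one per channel, each
#'   with `sine_period` rows of read-out rates (one per ms of phase).
#' @param protocol a [loop_protocol()].
#' @param method `"ridge"` (batch, 1 storage session) or `"bpdc"`
#'   (online).
#' @param lambda ridge regularization.
#' @param n_train_sessions training sessions for the online method.
#' @param bpdc a [bpdc_config()].
#' @param amps optional per-trial constant-input amplitudes (see
#'   [run_generalization_experiment()]); vector parallel to the trials of
#'   one session, recycled across sessions.
#' @param nrmse_floor normalizer floor forwarded to [nrmse()] (needed for
#'   constant, end-point targets).
#' @return An object of class `loop_result`: `W_oz`, `records` (one row
#'   per test-trial task window: session, trial, task, nrmse),
#'   `last_session` (per-task predicted and target rate series), the
#'   final module, and for the online method `session_nrmse` (running
#'   per-training-session mean NRMSE).
#' @export
run_loop_experiment <- function(mod, targets, protocol = loop_protocol(),
                                method = c("ridge", "bpdc"), lambda = 0.5,
                                n_train_sessions = NULL,
                                bpdc = bpdc_config(), amps = NULL,
                                nrmse_floor = 0) {
  method <- match.arg(method)
  p <- protocol
  stopifnot(length(targets) == p$n_tasks,
            mod$bg$n_channels == p$n_tasks)
  n_out <- ncol(targets[[1]]$rates)
  set.seed(p$seed)
  n_train <- if (!is.null(n_train_sessions)) n_train_sessions else
    if (method == "ridge") 1L else 1000L
  order_of <- function(n) replicate(n, sample.int(p$n_tasks), simplify = FALSE)

  session_amps <- function(sessions) {
    if (is.null(amps)) NULL else {
      stopifnot(length(amps) == p$n_tasks)
      unlist(lapply(sessions, function(o) amps[o]))
    }
  }

  train_orders <- order_of(n_train)
  test_orders <- order_of(p$n_test_sessions)
  t0 <- 0
  session_nrmse <- NULL

  if (method == "ridge") {
    sch <- loop_schedule(p, train_orders, session_amps(train_orders), t0)
    t0 <- t0 + sch$Tn
    rec <- which(sch$win)
    out <- run_module(mod, sch$X_ctx, sch$X_str, sch$da, record = rec)
    mod <- out$mod
    X <- t(out$Z)
    Y <- target_rows(targets, sch, rec)
    W_oz <- ridge_fit(X, Y, lambda)
  } else {
    W_oz <- matrix(0, n_out, mod$res$spec$n_units)
    session_nrmse <- numeric(n_train)
    for (s in seq_len(n_train)) {
      sch <- loop_schedule(p, train_orders[s], session_amps(train_orders[s]), t0)
      t0 <- t0 + sch$Tn
      rec <- which(sch$win)
      Y <- matrix(0, n_out, sch$Tn)
      Y[, rec] <- t(target_rows(targets, sch, rec))
      out <- run_module_online(mod, sch$X_ctx, sch$X_str, sch$da,
                               W_oz, Y, sch$win, bpdc, record = rec)
      mod <- out$mod
      W_oz <- out$W_oz
      session_nrmse[s] <- nrmse(t(out$O), t(Y[, rec, drop = FALSE]),
                                range_floor = nrmse_floor)
    }
  }

  # --- test phase (continuous state, last session scored) ---
  records <- NULL
  last <- NULL
  for (s in seq_len(p$n_test_sessions)) {
    ord <- test_orders[[s]]
    sch <- loop_schedule(p, list(ord), session_amps(list(ord)), t0)
    t0 <- t0 + sch$Tn
    rec <- which(sch$win)
    if (method == "ridge") {
      out <- run_module(mod, sch$X_ctx, sch$X_str, sch$da, record = rec)
      O <- W_oz %*% out$Z
    } else {
      out <- run_module_online(mod, sch$X_ctx, sch$X_str, sch$da,
                               W_oz, matrix(0, n_out, sch$Tn),
                               rep(FALSE, sch$Tn), bpdc, record = rec)
      O <- out$O
    }
    mod <- out$mod
    Y <- t(target_rows(targets, sch, rec))
    tr_of_rec <- sch$trial[rec]
    for (tr in seq_len(p$n_tasks)) {
      i <- tr_of_rec == tr
      records <- rbind(records, data.frame(
        session = s, trial = tr, task = ord[tr],
        nrmse = nrmse(t(O[, i, drop = FALSE]), t(Y[, i, drop = FALSE]),
                      range_floor = nrmse_floor)))
    }
    if (s == p$n_test_sessions) {
      last <- lapply(seq_len(p$n_tasks), function(tr) {
        i <- tr_of_rec == tr
        list(task = ord[tr], pred = t(O[, i, drop = FALSE]),
             target = t(Y[, i, drop = FALSE]))
      })
    }
  }
  structure(list(W_oz = W_oz, records = records, last_session = last,
                 mod = mod, protocol = p, targets = targets,
                 method = method, session_nrmse = session_nrmse),
            class = "loop_result")
}

#' @export
print.loop_result <- function(x, ...) {
  cat(sprintf("LOOP experiment (%s read-out): %d tasks\n", x$method,
              x$protocol$n_tasks))
  sc <- x$records[x$records$session == max(x$records$session), ]
  cat("  last test session NRMSE by task:",
      paste(sprintf("task %d: %.3f", sc$task, sc$nrmse), collapse = ", "), "\n")
  invisible(x)
}

#' Run the end-point (posture) experiment
#'
#' Identical protocol to the rhythmic experiment, but the targets are
#' fixed postures: each selected channel must drive the arm to a constant
#' joint configuration.  The scored error is the absolute per-joint angle
#' error at the end of each task window of the last test session.
#'
#' @param mod a [csntc_module()].
#' @param postures `n_tasks x 3` matrix of target joint angles (rad).
#' @param protocol a [loop_protocol()].
#' @param arm an [arm_model()].
#' @param lambda ridge regularization.
#' @param settle_ms the end-of-window stretch (ms) averaged to read the
#'   reached posture.
#' @return A list of class `endpoint_result` with `records` (session,
#'   trial, task, per-joint absolute error, nrmse), `joint_errors`
#'   (n_tasks x 3, last session) and the trained `loop_result` fields.
#' @export
run_endpoint_experiment <- function(mod, postures, protocol = loop_protocol(),
                                    arm = arm_model(), lambda = 0.5,
                                    settle_ms = 50) {
  stopifnot(nrow(postures) == protocol$n_tasks, ncol(postures) == 3L)
  targets <- lapply(seq_len(nrow(postures)), function(i) {
    make_posture_target(postures[i, ], n_samples = protocol$sine_period, arm = arm)
  })
  res <- run_loop_experiment(mod, targets, protocol, method = "ridge",
                             lambda = lambda, nrmse_floor = 1)
  errs <- t(vapply(res$last_session, function(tr) {
    n <- nrow(tr$pred)
    reached <- colMeans(tr$pred[(n - settle_ms + 1):n, , drop = FALSE])
    reached_ang <- rates_to_angles(reached, arm)
    abs(reached_ang - postures[tr$task, ])
  }, numeric(3)))
  task_ids <- vapply(res$last_session, `[[`, 0L, "task")
  errs <- errs[order(task_ids), , drop = FALSE]
  structure(c(res, list(joint_errors = errs, postures = postures, arm = arm)),
            class = c("endpoint_result", "loop_result"))
}

#' Run the translation/scaling generalization experiment
#'
#' Each shape is learned at three amplitudes of an additional constant
#' cortical input; the amplitude encodes the shape's translation (variant
#' `"translate"`) or scale (variant `"scale"`).  The test recalls each
#' shape at an unseen intermediate amplitude; generalization holds when
#' the produced trajectory's centroid (translation) or extent (scale)
#' falls strictly between the values trained at the two flanking
#' amplitudes.
#'
#' @param mod a [csntc_module()] built with `n_inputs = 2` (sinusoid +
#'   constant line).
#' @param shape_ids one catalogue shape per channel.
#' @param variant `"translate"` or `"scale"`.
#' @param amps_train the three training amplitudes.
#' @param amp_test the intermediate test amplitude (strictly between two
#'   training amplitudes).
#' @param protocol a [loop_protocol()]; each training session presents
#'   every (shape, amplitude) combination once, in random order.
#' @param arm an [arm_model()].
#' @param lambda ridge regularization; the default is stiffer than in the
#'   plain rhythmic experiment because interpolation along the amplitude
#'   continuum benefits from a smoother read-out map.
#' @return A list of class `generalization_result`: per-task `measure_test`
#'   (centroid x or mean extent of the produced Cartesian trajectory at
#'   `amp_test`), `measure_train` (same measure of the target curves at the
#'   flanking amplitudes), and `between` (logical per task).
#' @export
run_generalization_experiment <- function(mod, shape_ids = c("circle", "square",
                                                             "figure8"),
                                          variant = c("translate", "scale"),
                                          amps_train = c(0.2, 0.5, 0.8),
                                          amp_test = 0.35,
                                          protocol = loop_protocol(),
                                          arm = arm_model(), lambda = 5) {
  variant <- match.arg(variant)
  p <- protocol
  stopifnot(length(shape_ids) == p$n_tasks, length(amps_train) == 3L)
  place <- function(a) {
    if (variant == "translate") list(center = c(0.9 + 0.6 * a, 1.2), scale = 0.3)
    else list(center = c(1.2, 1.2), scale = 0.18 + 0.35 * a)
  }
  tgt <- function(k, a) {
    pl <- place(a)
    make_target(shape_ids[k], n_samples = p$sine_period, arm = arm,
                center = pl$center, scale = pl$scale)
  }

  # training: one storage session holding all (task, amp) combinations
  combos <- expand.grid(task = seq_len(p$n_tasks), amp = amps_train)
  set.seed(p$seed)
  ord <- sample.int(nrow(combos))
  combos <- combos[ord, ]
  train_targets <- lapply(seq_len(nrow(combos)), function(i) {
    tgt(combos$task[i], combos$amp[i])
  })
  sch <- loop_schedule(p, list(combos$task), combos$amp, 0)
  rec <- which(sch$win)
  # targets indexed by trial here, not by channel
  Y <- do.call(rbind, lapply(rec, function(t) {
    tg <- train_targets[[sch$trial[t]]]
    tg$rates[(sch$phase[t] - 1) %% nrow(tg$rates) + 1, , drop = FALSE]
  }))
  out <- run_module(mod, sch$X_ctx, sch$X_str, sch$da, record = rec)
  mod <- out$mod
  W_oz <- ridge_fit(t(out$Z), Y, lambda)
  t0 <- sch$Tn

  # test: each task at the two flanking trained amplitudes and at the
  # unseen intermediate one (3 sessions, last scored); the comparison is
  # between *produced* trajectories, as in the behavioural read-out.
  # translation: trajectory centroid (x); scale: RMS radius about the
  # centroid (robust to pointwise jitter, proportional to curve size)
  measure <- function(xy) {
    if (variant == "translate") mean(xy[, 1]) else
      sqrt(mean(rowSums(sweep(xy, 2L, colMeans(xy))^2)))
  }
  fl <- sort(amps_train[order(abs(amps_train - amp_test))][1:2])
  stopifnot(amp_test > fl[1], amp_test < fl[2])
  res <- NULL
  for (s in seq_len(p$n_test_sessions)) {
    ct <- expand.grid(task = seq_len(p$n_tasks), amp = c(fl, amp_test))
    ct <- ct[sample.int(nrow(ct)), ]
    schT <- loop_schedule(p, list(ct$task), ct$amp, t0)
    t0 <- t0 + schT$Tn
    recT <- which(schT$win)
    outT <- run_module(mod, schT$X_ctx, schT$X_str, schT$da, record = recT)
    mod <- outT$mod
    O <- W_oz %*% outT$Z
    if (s == p$n_test_sessions) {
      m_of <- function(i) {
        ang <- rates_to_angles_mat(t(O[, i, drop = FALSE]), arm)
        measure(forward_kinematics(ang, arm))
      }
      tr_of_rec <- schT$trial[recT]
      res <- lapply(seq_len(p$n_tasks), function(k) {
        m <- vapply(c(fl, amp_test), function(a) {
          tr <- which(ct$task == k & ct$amp == a)
          m_of(tr_of_rec == tr)
        }, 0)
        list(task = k, measure_test = m[3], flanking = m[1:2],
             target_flanking = vapply(fl, function(a) measure(tgt(k, a)$xy), 0),
             between = m[3] > min(m[1:2]) && m[3] < max(m[1:2]))
      })
    }
  }
  structure(list(results = res, variant = variant, amps_train = amps_train,
                 amp_test = amp_test, W_oz = W_oz, mod = mod),
            class = "generalization_result")
}

# row-wise rates -> angles for a T x 3 matrix
rates_to_angles_mat <- function(rates, arm) {
  lo <- arm$joint_limits[, 1]
  hi <- arm$joint_limits[, 2]
  sweep(sweep(rates, 2L, hi - lo, `*`), 2L, lo, `+`)
}
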