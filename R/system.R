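#' Specification of the two-module system model
#'
#' The system-level architecture: a high-level motor CSNTC module, a
#' primary motor CSNTC module, and a plain somatosensory cortical module
#' (a reservoir not in loop with the basal ganglia).  Task information is
#' a 9-channel binary code in 3 groups: each group is hardwired onto one
#' high-level striatal channel (the abstracted product of reward-based
#' category learning), and every code line also reaches the high-level
#' cortex through fixed random weights.  The high-level cortex projects to
#' the primary cortex (fixed random weights) and to the primary striatum
#' through the only learnable cortico-striatal matrix `W_sx`
#' (Oja/kWTA rule).  The somatosensory module receives the sinusoidal
#' context signal and projects to the primary cortex and (weakly) the
#' primary striatum.
#'
#' @param n_units units per cortical module.
#' @param n_channels basal ganglia channels (= tasks = code groups).
#' @param seed structural seed (reservoirs and fixed random projections).
#' @param g_hl,g_som gains of the high-level/somatosensory projections to
#'   the primary cortex input partition.
#' @param code_ctx_scale scale of the fixed random weights carrying the
#'   task code into the high-level cortex (relative to the reservoir's
#'   own input scale).  The code must inform the cortical dynamics, but
#'   a large direct drive makes every downstream trajectory code-bound,
#'   which defeats the categorization the basal ganglia provide.
#' @param g_hl_str gain of the learnable high-level-cortex to
#'   primary-striatum pathway (applied on top of `W_sx`).
#' @param g_som_str gain of the fixed somatosensory to primary-striatum
#'   pathway.
#' @param oja an [oja_config()] for cortico-striatal learning.
#' @param sel_noise_mu,sel_noise_sigma mean and s.d. of the per-trial
#'   Gaussian perturbation of the primary striatal input during the
#'   cortico-striatal learning phase (drives random selection before
#'   `W_sx` carries information).
#' @param center_hl_drive deliver the learned cortico-striatal drive with
#'   its channel mean subtracted (feedforward lateral inhibition), so only
#'   task-specific deviations of the learned pathway compete for
#'   selection; without it the shared component of the learned weights
#'   co-activates every channel.
#' @param bgp a [bg_params()] shared by both CSNTC modules.
#' @param ctx_params cortical [layer_params()].
#' @param lesion one of `"baseline"`, `"partial"` (the high-level-cortex
#'   to primary-striatum bundle `hlctx_to_pm_striatum` zeroed and frozen
#'   before learning), `"full"` (additionally the prefrontal-to-high-level
#'   striatum map `pfc_to_hl_striatum` zeroed).
#' @return An object of class `csntc_system`.
#' @export
csntc_system <- function(n_units = 100, n_channels = 3, seed = 1L,
                         g_hl = 0.15, g_som = 0.5, code_ctx_scale = 1,
                         g_hl_str = 0.7, g_som_str = 0.3,
                         oja = oja_config(eta_sx = 1e-3, k_cortex = 16),
                         sel_noise_mu = 0, sel_noise_sigma = 0.4,
                         center_hl_drive = TRUE,
                         bgp = bg_params(), ctx_params = layer_params(),
                         lesion = c("baseline", "partial", "full")) {
  lesion <- match.arg(lesion)
  C <- as.integer(n_channels)
  n_code <- 3L * C
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sub <- sample.int(1e8, 3)

  som <- build_reservoir(reservoir_spec(n_units = n_units, n_inputs = 1,
                                        seed = sub[1]))
  hl <- csntc_module(build_reservoir(reservoir_spec(n_units = n_units,
                                                    n_inputs = n_code,
                                                    input_scale = code_ctx_scale,
                                                    seed = sub[2])),
                     bgp = bgp, ctx_params = ctx_params)
  pm <- csntc_module(build_reservoir(reservoir_spec(n_units = n_units,
                                                    n_inputs = 1,
                                                    seed = sub[3])),
                     bgp = bgp, ctx_params = ctx_params)

  # hardwired 3-group category map: every line of group g excites
  # high-level striatal channel g
  G <- matrix(0, C, n_code)
  for (g in seq_len(C)) G[g, ((g - 1) * 3 + 1):(g * 3)] <- 1

  inp <- pm$res$partition$input
  rand_proj <- function(n_from, gain) {
    W <- matrix(0, n_units, n_from)
    W[inp, ] <- stats::runif(length(inp) * n_from, -1, 1) * gain
    W
  }
  W_hl_pmctx <- rand_proj(n_units, g_hl)
  W_som_pmctx <- rand_proj(n_units, g_som)
  # somatosensory -> primary striatum: weak uniform positive projection,
  # normalized so the per-channel drive is O(g_som_str * mean rate)
  W_som_pmstr <- matrix(stats::runif(C * n_units), C, n_units) / n_units

  frozen <- character(0)
  if (lesion %in% c("partial", "full")) frozen <- c(frozen, "hlctx_to_pm_striatum")
  if (lesion == "full") {
    G[] <- 0
    frozen <- c(frozen, "pfc_to_hl_striatum")
  }

  structure(list(som = som, hl = hl, pm = pm,
                 G_code_hlstr = G,
                 W_hl_pmctx = W_hl_pmctx, W_som_pmctx = W_som_pmctx,
                 W_som_pmstr = W_som_pmstr,
                 W_sx = matrix(0, C, n_units),
                 g_hl_str = g_hl_str, g_som_str = g_som_str,
                 oja = oja, sel_noise_mu = sel_noise_mu,
                 sel_noise_sigma = sel_noise_sigma,
                 center_hl_drive = center_hl_drive,
                 n_channels = C, n_code = n_code, n_units = as.integer(n_units),
                 seed = as.integer(seed), lesion = lesion, frozen = frozen),
            class = "csntc_system")
}

#' @export
print.csntc_system <- function(x, ...) {
  cat(sprintf(paste0("CSNTC system model: high-level + primary motor modules ",
                     "(%d units, %d channels each),\n  somatosensory module, ",
                     "%d-line task code; lesion condition: %s\n"),
              x$n_units, x$n_channels, x$n_code, toupper(x$lesion)))
  invisible(x)
}

#' @rdname lesion
#' @export
lesion.csntc_system <- function(x, bundles, ...) {
  known <- c("pfc_to_hl_striatum", "hlctx_to_pm_striatum")
  bad <- setdiff(bundles, known)
  if (length(bad)) stop("unknown lesion bundle(s): ", paste(bad, collapse = ", "))
  if ("pfc_to_hl_striatum" %in% bundles) x$G_code_hlstr[] <- 0
  if ("hlctx_to_pm_striatum" %in% bundles) x$W_sx[] <- 0
  x$frozen <- union(x$frozen, bundles)
  x
}

# Engine-format list for one CSNTC module inside the system.
sys_module_list <- function(mod) {
  engine_model_list(mod)
}

sys_engine_list <- function(sys) {
  list(som = list(W_u = sys$som$W_u, W_ux = sys$som$W_ux,
                  state = list(u_ctx = sys$som_u %||% numeric(sys$n_units))),
       hl = engine_model_list(sys$hl),
       pm = engine_model_list(sys$pm),
       G_code_hlstr = sys$G_code_hlstr,
       W_hl_pmctx = sys$W_hl_pmctx, W_som_pmctx = sys$W_som_pmctx,
       W_sx = sys$W_sx, W_som_pmstr = sys$W_som_pmstr,
       cfg = list(g_hl_str = sys$g_hl_str, g_som_str = sys$g_som_str,
                  center_hl_drive = isTRUE(sys$center_hl_drive),
                  oja_src_mask = {
                    m <- numeric(sys$n_units)
                    m[sys$hl$res$partition$loop] <- 1
                    m
                  },
                  eta_sx = sys$oja$eta_sx,
                  k_striatum = as.integer(sys$oja$k_striatum),
                  k_cortex = as.integer(min(sys$oja$k_cortex, sys$n_units)),
                  sx_frozen = "hlctx_to_pm_striatum" %in% sys$frozen))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Step the system over a schedule
#'
#' Low-level driver used by [run_system_experiment()]: advances the whole
#' three-module system over `T` steps.
#'
#' @param sys a [csntc_system()].
#' @param code `n_code x T` binary task-code schedule.
#' @param sine `1 x T` sinusoidal context schedule.
#' @param da length-`T` dopamine schedule (shared by both modules).
#' @param window length-`T` logical task-window mask.
#' @param oja_on run the Oja cortico-striatal update inside windows.
#' @param noise_sel optional `C x T` striatal-input perturbation schedule.
#' @param record steps at which to record the primary cortical rates.
#' @return List with the updated `sys` and `Z` (primary cortical rates at
#'   the recorded steps).
#' @export
run_system <- function(sys, code, sine, da, window, oja_on = FALSE,
                       noise_sel = NULL, record = integer(0)) {
  Tn <- length(da)
  par <- engine_unit_params(sys$pm)
  noise_oja <- if (oja_on && sys$oja$noise_sigma > 0) {
    matrix(stats::rnorm(sys$n_channels * Tn, sys$oja$noise_mu,
                        sys$oja$noise_sigma), sys$n_channels, Tn)
  } else matrix(0, 0, 0)
  if (is.null(noise_sel)) noise_sel <- matrix(0, 0, 0)
  out <- .cpp_run_system(sys_engine_list(sys), par,
                         code, sine, da, da, oja_on,
                         noise_sel, noise_oja,
                         as.logical(window), as.integer(record))
  sys$som_u <- as.numeric(out$som_state$u_ctx)
  sys$hl <- engine_restore_state(sys$hl, out$hl_state)
  sys$pm <- engine_restore_state(sys$pm, out$pm_state)
  sys$W_sx <- out$W_sx
  list(sys = sys, Z = out$Z)
}

# Build code/sine/da/window schedules for a block of sessions of the
# system experiment.  `bit` selects which bit of each group carries the
# task: 1 for the SAME condition (training), 3 for DIFF.
system_schedule <- function(protocol, session_tasks, n_code, bit = 1, t0 = 0) {
  sch <- loop_schedule(protocol, session_tasks, NULL, t0)
  code <- matrix(0, n_code, sch$Tn)
  on <- sch$X_str[cbind(sch$task, seq_len(sch$Tn))] > 0
  line <- (sch$task - 1) * 3 + bit
  code[cbind(line, seq_len(sch$Tn))] <- ifelse(on, 1, 0)
  sch$code <- code
  sch
}

#' Run the two-module lesion experiment
#'
#' One full simulation of the system model in a given lesion condition:
#'
#' 1. *Cortico-striatal learning phase* (`oja_sessions` sessions): the
#'    high-level-cortex to primary-striatum weights learn by the Oja/kWTA
#'    rule while a per-trial Gaussian perturbation of the primary striatal
#'    input lets selection happen randomly at first.
#' 2. *Read-out training phase*: one storage session; primary cortical
#'    states inside the task windows train the read-out by Tikhonov
#'    regression.
#' 3. *Test phase*: SAME condition (task code identical to training: first
#'    bit per group) then DIFF condition (orthogonal code: last bit per
#'    group), three sessions each, the last session of each scored.
#'
#' Lesions are applied at construction, before any learning.  The whole
#' simulation is continuous (no state reset).
#'
#' @param lesion `"baseline"`, `"partial"` or `"full"`.
#' @param n_repeats independent simulations (different seeds).
#' @param seed base seed; repeat i uses structural and protocol seeds
#'   drawn from separate streams, so lesion groups share identical
#'   networks within a repeat.
#' @param protocol a [loop_protocol()]; the default system protocol uses a
#'   later task window than the single-module experiments because the
#'   selection must propagate through two chained modules.
#' @param oja_sessions cortico-striatal learning sessions.
#' @param shape_ids catalogue shapes serving as the three motor tasks.
#' @param n_units units per cortical module.
#' @param lambda ridge regularization for the read-out; stiffer than the
#'   single-module default so the fit leans on the strong selected
#'   dynamics rather than on weak code-bound components.
#' @param arm an [arm_model()].
#' @param oja an [oja_config()] forwarded to [csntc_system()].
#' @param ... further arguments to [csntc_system()].
#' @return A data.frame of class `system_records`: one row per scored
#'   test-trial (sim, lesion, condition, session, trial, task, nrmse).
#' @export
run_system_experiment <- function(lesion = c("baseline", "partial", "full"),
                                  n_repeats = 1, seed = 1L,
                                  protocol = system_protocol(),
                                  oja_sessions = 30L,
                                  shape_ids = c("square", "figure8", "moon"),
                                  n_units = 100, lambda = 5,
                                  arm = arm_model(),
                                  oja = oja_config(eta_sx = 1e-3, k_cortex = 16),
                                  ...) {
  lesion <- match.arg(lesion)
  p <- protocol
  C <- p$n_tasks
  set.seed(seed)
  struct_seeds <- sample.int(1e8, n_repeats)
  proto_seeds <- sample.int(1e8, n_repeats)
  targets <- lapply(shape_ids, make_target, n_samples = p$sine_period, arm = arm)

  records <- NULL
  for (i in seq_len(n_repeats)) {
    rec <- run_system_once(lesion, struct_seeds[i], proto_seeds[i], p,
                           oja_sessions, targets, n_units, lambda, oja = oja, ...)
    rec$sim <- i
    records <- rbind(records, rec)
  }
  records$lesion <- toupper(lesion)
  class(records) <- c("system_records", class(records))
  records
}

#' Default protocol of the system experiment
#'
#' Same trial structure as [loop_protocol()] with a later task window
#' (selection has to travel code -> high-level module -> primary module
#' before the primary dynamics are locked in).
#'
#' @param bias_on,bias_off,task_start,task_end,da_off system-model timing
#'   defaults (ms).
#' @param ... further overrides passed to [loop_protocol()].
#' @export
system_protocol <- function(bias_on = 500, bias_off = 3400,
                            task_start = 1900, task_end = 3400,
                            da_off = 3500, ...) {
  loop_protocol(bias_on = bias_on, bias_off = bias_off,
                task_start = task_start, task_end = task_end,
                da_off = da_off, ...)
}

run_system_once <- function(lesion, struct_seed, proto_seed, p,
                            oja_sessions, targets, n_units, lambda,
                            oja = oja_config(eta_sx = 1e-3, k_cortex = 16),
                            ...) {
  C <- p$n_tasks
  sys <- csntc_system(n_units = n_units, n_channels = C, seed = struct_seed,
                      lesion = lesion, oja = oja, ...)
  n_out <- ncol(targets[[1]]$rates)
  set.seed(proto_seed)
  t0 <- 0

  run_block <- function(sys, n_sessions, bit, oja_on, noisy, record_win) {
    orders <- replicate(n_sessions, sample.int(C), simplify = FALSE)
    sch <- system_schedule(p, orders, sys$n_code, bit, t0)
    t0 <<- t0 + sch$Tn
    noise_sel <- NULL
    if (noisy && sys$sel_noise_sigma > 0) {
      # per-trial constant perturbation, applied while dopamine is on
      ntr <- n_sessions * C
      drw <- matrix(stats::rnorm(C * ntr, sys$sel_noise_mu,
                                 sys$sel_noise_sigma), C, ntr)
      noise_sel <- drw[, sch$trial, drop = FALSE] *
        rep(sch$da, each = C)
    }
    rec <- if (record_win) which(sch$win) else integer(0)
    out <- run_system(sys, sch$code, matrix(sch$X_ctx[1, ], 1), sch$da,
                      sch$win, oja_on = oja_on, noise_sel = noise_sel,
                      record = rec)
    list(sys = out$sys, Z = out$Z, sch = sch, rec = rec, orders = orders)
  }

  # phase 1: cortico-striatal learning under striatal perturbation
  if (oja_sessions > 0) {
    b <- run_block(sys, oja_sessions, 1, oja_on = TRUE, noisy = TRUE,
                   record_win = FALSE)
    sys <- b$sys
  }
  # phase 2: read-out storage session
  b <- run_block(sys, 1, 1, oja_on = FALSE, noisy = FALSE, record_win = TRUE)
  sys <- b$sys
  Y <- target_rows(targets, b$sch, b$rec)
  W_oz <- ridge_fit(t(b$Z), Y, lambda)

  # phase 3: SAME then DIFF tests, last session of each scored
  score <- function(bit, label) {
    b <- run_block(sys, p$n_test_sessions, bit, oja_on = FALSE,
                   noisy = FALSE, record_win = TRUE)
    sys <<- b$sys
    rec_sess <- ceiling(b$rec / (C * p$trial_ms))
    last <- rec_sess == p$n_test_sessions
    O <- W_oz %*% b$Z[, last, drop = FALSE]
    Yt <- t(target_rows(targets, b$sch, b$rec[last]))
    tr <- b$sch$trial[b$rec[last]]
    out <- NULL
    for (trial in unique(tr)) {
      i <- tr == trial
      task <- b$sch$task[b$rec[last][i]][1]
      out <- rbind(out, data.frame(
        condition = label, session = p$n_test_sessions,
        trial = trial - (p$n_test_sessions - 1) * C, task = task,
        nrmse = nrmse(t(O[, i, drop = FALSE]), t(Yt[, i, drop = FALSE]))))
    }
    out
  }
  rbind(score(1, "SAME"), score(3, "DIFF"))
}
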