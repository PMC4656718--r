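#' Basal ganglia parameters
#'
#' Gains and dopamine coefficients of the C-channel selection circuit
#' (StrD1, StrD2, STN, GPe, GPi).  Dopamine acts multiplicatively on the
#' striatal input: excitatory on D1 units (`bl_d1 + da_d1 * da` scales
#' their drive) and inhibitory on D2 units (their drive is divided by
#' `bl_d2 + da_d2 * da`).  All inter-layer connections are one-to-one per
#' channel except the STN efferents, which reach every GPe and GPi unit
#' (the diffuse hyper-direct pathway).  The default gains put the circuit
#' in the selection regime: symmetric inputs leave all GPi channels at
#' their tonic rate, a modest input advantage under high dopamine drives
#' the winning channel's GPi below the others and, with cortical
#' background activity present, locks the loop in an up state until
#' dopamine drops.
#'
#' @param bl_d1,da_d1 baseline and dopamine-dependent responsiveness of D1
#'   striatal units (dimensionless; `bl_d1 > 0`).
#' @param bl_d2,da_d2 same for D2 units; the divisor `bl_d2 + da_d2 * da`
#'   must stay positive.
#' @param w_cs cortex-to-striatum gain (per-channel pooled cortical rate).
#' @param w_xs external-input-to-striatum gain.
#' @param w_cstn cortex-to-STN gain (within-loop only; no out-of-loop
#'   input reaches the STN).
#' @param w_gpestn GPe-to-STN inhibitory gain.
#' @param w_stngpe,w_stngpi diffuse STN excitatory gains (applied to the
#'   summed STN rate).
#' @param w_strgpe StrD2-to-GPe inhibitory gain (indirect pathway).
#' @param w_strgpi StrD1-to-GPi inhibitory gain (direct pathway).
#' @param w_gpegpi GPe-to-GPi inhibitory gain.
#' @param gpi_tonic tonic GPi drive (sets the resting inhibition of
#'   thalamus).
#' @param w_gpitha GPi-to-thalamus inhibitory gain.
#' @param w_cttha cortex-to-thalamus excitatory gain (pooled loop
#'   sub-population rate; thalamic activity requires cortical background).
#' @param tha_tonic small tonic thalamic bias.
#' @param w_thact thalamo-cortical gain (drive broadcast to the loop
#'   sub-population).
#' @param params [layer_params()] shared by all basal ganglia and thalamic
#'   layers.
#' @return An object of class `bg_params`.
#' @export
bg_params <- function(bl_d1 = 0.4, da_d1 = 1.0,
                      bl_d2 = 0.2, da_d2 = 4.0,
                      w_cs = 1.0, w_xs = 1.0, w_cstn = 1.0, w_gpestn = 1.0,
                      w_stngpe = 0.9, w_stngpi = 0.9,
                      w_strgpe = 1.0, w_strgpi = 1.6, w_gpegpi = 0.3,
                      gpi_tonic = 0.6, w_gpitha = 7.0, w_cttha = 5.0,
                      tha_tonic = 0.09, w_thact = 1.0,
                      params = layer_params()) {
  stopifnot(bl_d1 > 0, bl_d2 > 0, da_d2 >= 0)
  gains <- c(w_cs = w_cs, w_xs = w_xs, w_cstn = w_cstn, w_gpestn = w_gpestn,
             w_stngpe = w_stngpe, w_stngpi = w_stngpi, w_strgpe = w_strgpe,
             w_strgpi = w_strgpi, w_gpegpi = w_gpegpi, gpi_tonic = gpi_tonic,
             w_gpitha = w_gpitha, w_cttha = w_cttha, tha_tonic = tha_tonic,
             w_thact = w_thact)
  if (any(gains < 0)) stop("all gain magnitudes must be non-negative")
  structure(c(list(bl_d1 = bl_d1, da_d1 = da_d1, bl_d2 = bl_d2, da_d2 = da_d2),
              as.list(gains), list(params = params)),
            class = "bg_params")
}

#' Basal ganglia state
#'
#' One [layer_state()] per nucleus, each of length `n_channels`.
#'
#' @param n_channels number of channels C.
#' @param params a [bg_params()] (for the unit transfer at rest).
#' @return An object of class `bg_state` with elements `strd1`, `strd2`,
#'   `stn`, `gpe`, `gpi`.
#' @export
bg_state <- function(n_channels = 3, params = bg_params()) {
  mk <- function() layer_state(n_channels, params$params)
  structure(list(strd1 = mk(), strd2 = mk(), stn = mk(), gpe = mk(), gpi = mk(),
                 n_channels = as.integer(n_channels)),
            class = "bg_state")
}

#' Dopamine-modulated striatal drives
#'
#' Input drive to the D1 (direct-pathway) and D2 (indirect-pathway)
#' striatal populations.  Dopamine multiplies the D1 drive
#' (`(bl_d1 + da_d1 * da) * input`) and divides the D2 drive
#' (`input / (bl_d2 + da_d2 * da)`), so high dopamine favours the direct
#' pathway and silences the indirect one.
#'
#' @param c_in per-channel cortical input vector (pooled loop
#'   sub-population rates).
#' @param x_in per-channel external input vector (out-of-loop afferents).
#' @param da dopamine level (scalar, >= 0).
#' @param params a [bg_params()].
#' @return Per-channel potential drive vector.
#' @export
striatal_drive_d1 <- function(c_in, x_in, da, params = bg_params()) {
  stopifnot(da >= 0)
  (params$bl_d1 + params$da_d1 * da) * (params$w_cs * c_in + params$w_xs * x_in)
}

#' @rdname striatal_drive_d1
#' @export
striatal_drive_d2 <- function(c_in, x_in, da, params = bg_params()) {
  div <- params$bl_d2 + params$da_d2 * da
  if (div <= 0) stop("bl_d2 + da_d2 * da must be positive")
  (params$w_cs * c_in + params$w_xs * x_in) / div
}

#' One synchronous step of the basal ganglia circuit
#'
#' All layer drives are computed from pre-step rates, then every layer
#' takes one Euler step, so the update is order-independent.  Wiring:
#' cortex excites StrD1, StrD2 and STN one-to-one per channel; StrD1
#' inhibits GPi and StrD2 inhibits GPe one-to-one; the STN excites all
#' GPe and GPi units; GPe inhibits STN and GPi one-to-one; GPi carries a
#' tonic drive.
#'
#' @param state a [bg_state()].
#' @param c_in per-channel cortical input (length C).
#' @param x_in per-channel external input (length C).
#' @param da dopamine level.
#' @param params a [bg_params()].
#' @param dt integration step (ms).
#' @return The updated `bg_state`.
#' @export
step_bg <- function(state, c_in, x_in, da, params = bg_params(), dt = 1) {
  C <- state$n_channels
  stopifnot(length(c_in) == C, length(x_in) == C)
  lp <- params$params
  d <- bg_drives(state, c_in, x_in, da, params)
  out <- state
  out$strd1 <- step_layer(state$strd1, d$strd1, lp, dt)
  out$strd2 <- step_layer(state$strd2, d$strd2, lp, dt)
  out$stn   <- step_layer(state$stn,   d$stn,   lp, dt)
  out$gpe   <- step_layer(state$gpe,   d$gpe,   lp, dt)
  out$gpi   <- step_layer(state$gpi,   d$gpi,   lp, dt)
  out
}

# Right-hand-side drives of every nucleus from pre-step rates; shared by
# the stepper and by fixed-point analyses.
bg_drives <- function(state, c_in, x_in, da, params) {
  stn_sum <- sum(state$stn$z)
  list(
    strd1 = striatal_drive_d1(c_in, x_in, da, params),
    strd2 = striatal_drive_d2(c_in, x_in, da, params),
    stn   = params$w_cstn * c_in - params$w_gpestn * state$gpe$z,
    gpe   = params$w_stngpe * stn_sum - params$w_strgpe * state$strd2$z,
    gpi   = params$gpi_tonic + params$w_stngpi * stn_sum -
            params$w_strgpi * state$strd1$z - params$w_gpegpi * state$gpe$z
  )
}

#' GPi gating of the thalamus
#'
#' Converts per-channel GPi rates into the (non-positive) inhibitory drive
#' each thalamic unit receives: proportional to the channel's GPi rate,
#' so a silenced GPi channel releases its thalamic unit (disinhibition).
#'
#' @param gpi_rates per-channel GPi rate vector.
#' @param params a [bg_params()].
#' @return Per-channel inhibitory drive (<= 0 elementwise).
#' @export
gpi_to_thalamic_gate <- function(gpi_rates, params = bg_params()) {
  -params$w_gpitha * gpi_rates
}

#' Steady state of the basal ganglia under constant input
#'
#' Root-solve of the circuit's fixed-point equations (potentials at which
#' every layer's leak balances its drive) under constant cortical and
#' external input.  Used as an independent check of the stepped dynamics.
#'
#' @param c_in,x_in,da,params as in [step_bg()].
#' @param n_channels number of channels.
#' @param u0 optional stacked initial potentials (length 5 C).
#' @return A `bg_state` at the fixed point.
#' @export
bg_fixed_point <- function(c_in, x_in, da, params = bg_params(),
                           n_channels = length(c_in), u0 = NULL) {
  C <- n_channels
  unpack <- function(u) {
    st <- bg_state(C, params)
    lp <- params$params
    nm <- c("strd1", "strd2", "stn", "gpe", "gpi")
    for (i in seq_along(nm)) {
      ui <- u[((i - 1) * C + 1):(i * C)]
      st[[nm[i]]] <- structure(list(u = ui, z = transfer(ui, lp)),
                               class = "layer_state")
    }
    st
  }
  rhs <- function(u) {
    st <- unpack(u)
    d <- bg_drives(st, c_in, x_in, da, params)
    u - c(d$strd1, d$strd2, d$stn, d$gpe, d$gpi)
  }
  if (is.null(u0)) u0 <- rep(0.1, 5 * C)
  sol <- pracma::fsolve(rhs, u0, tol = 1e-12)
  unpack(sol$x)
}
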