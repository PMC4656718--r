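#' Cortical reservoir specification
#'
#' Describes the size, unit partition and spectral normalization of a
#' cortical echo-state reservoir.  Units are partitioned into three
#' disjoint groups: *loop* units (in loop with the thalamus, split into
#' `n_channels` equal sub-populations, one per basal ganglia channel),
#' *input* units (the only ones receiving external cortico-cortical
#' input), and the remaining *free* units.
#'
#' @param n_units reservoir size.
#' @param n_inputs number of external input lines.
#' @param n_channels number of thalamo-cortical loop sub-populations.
#' @param loop_fraction fraction of units belonging to thalamic loops.
#' @param input_fraction fraction of units receiving external input.
#' @param sparsity connection probability of the recurrent matrix.
#' @param effective_spectral_radius target spectral radius of the
#'   leaky-effective matrix `(1 - dt/tau) I + (dt/tau) W_u`; must lie in
#'   `(1 - dt/tau, 1)` for the leak used.
#' @param input_scale half-width of the uniform input-weight distribution.
#' @param asymmetry amount of the symmetric component removed from the raw
#'   recurrent matrix before normalization (`W - c (W + W')/2`); 0 gives
#'   plain echo-state normalization.  Richer transient dynamics come from
#'   a more asymmetric matrix.
#' @param dt,tau integration step and cortical time constant used in the
#'   leaky-effective matrix (ms).
#' @param seed RNG seed making the construction reproducible.
#' @return An object of class `reservoir_spec`.
#' @export
reservoir_spec <- function(n_units = 200, n_inputs = 1, n_channels = 3,
                           loop_fraction = 0.5, input_fraction = 0.2,
                           sparsity = 0.1, effective_spectral_radius = 0.93,
                           input_scale = 1, asymmetry = 0.5,
                           dt = 1, tau = 10, seed = 1L) {
  stopifnot(n_units >= n_channels, n_inputs >= 1, n_channels >= 1,
            loop_fraction >= 0, input_fraction >= 0,
            loop_fraction + input_fraction <= 1,
            sparsity > 0, sparsity <= 1,
            effective_spectral_radius > 0, effective_spectral_radius < 1,
            asymmetry >= 0, asymmetry <= 1, dt > 0, dt < tau)
  if (effective_spectral_radius <= 1 - dt / tau) {
    stop(sprintf(paste0("effective_spectral_radius must exceed the leak floor ",
                        "1 - dt/tau = %g"), 1 - dt / tau))
  }
  structure(list(n_units = as.integer(n_units), n_inputs = as.integer(n_inputs),
                 n_channels = as.integer(n_channels),
                 loop_fraction = loop_fraction, input_fraction = input_fraction,
                 sparsity = sparsity,
                 effective_spectral_radius = effective_spectral_radius,
                 input_scale = input_scale, asymmetry = asymmetry,
                 dt = dt, tau = tau, seed = as.integer(seed)),
            class = "reservoir_spec")
}

#' Effective spectral radius of a leaky reservoir
#'
#' Spectral radius of `(1 - dt/tau) I + (dt/tau) W`, the one-step linear
#' propagator of the leaky dynamics around the origin.
#'
#' @param W recurrent weight matrix.
#' @param dt,tau integration step and time constant (ms).
#' @return The spectral radius (non-negative scalar).
#' @export
effective_radius <- function(W, dt, tau) {
  k <- dt / tau
  max(Mod(eigen((1 - k) * diag(nrow(W)) + k * W, only.values = TRUE)$values))
}

#' Build a cortical reservoir
#'
#' Draws a sparse random recurrent matrix, optionally removes part of its
#' symmetric component, and rescales it so the leaky-effective matrix
#' `(1 - dt/tau) I + (dt/tau) W_u` has exactly the target spectral radius
#' (the echo-state normalization for leaky units; eigenvalues of the
#' effective matrix are affine in the scale factor, so the scale is found
#' by a 1-D root solve).  Input weights are uniform on
#' `[-input_scale, input_scale]` and connect only to the input partition.
#'
#' @param spec a [reservoir_spec()].
#' @return An object of class `reservoir` with elements `W_u`, `W_ux`,
#'   `partition` (list of index vectors: `loop`, per-channel `channels`,
#'   `input`, `free`) and the spec.
#' @examples
#' r <- build_reservoir(reservoir_spec(n_units = 50, seed = 7))
#' effective_radius(r$W_u, 1, 10)   # the requested radius, by construction
#' @export
build_reservoir <- function(spec = reservoir_spec()) {
  stopifnot(inherits(spec, "reservoir_spec"))
  n <- spec$n_units
  k <- spec$dt / spec$tau
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  for (attempt in 1:5) {
    mask <- matrix(stats::runif(n * n) < spec$sparsity, n, n)
    W <- matrix(stats::rnorm(n * n), n, n) * mask
    diag(W) <- 0
    if (spec$asymmetry > 0) W <- W - spec$asymmetry * (W + t(W)) / 2
    ev <- eigen(W, only.values = TRUE)$values
    if (max(Mod(ev)) > 1e-12) break
    warning("raw recurrent matrix numerically nilpotent; redrawing")
  }
  # scale c solves max_i |(1 - k) + k c lambda_i| = rho_target
  f <- function(cc) max(Mod((1 - k) + k * cc * ev)) - spec$effective_spectral_radius
  up <- 1
  while (f(up) < 0) up <- up * 2
  cc <- stats::uniroot(f, c(0, up), tol = 1e-12)$root
  W <- cc * W

  W_ux <- matrix(0, n, spec$n_inputs)
  n_loop <- floor(spec$loop_fraction * n / spec$n_channels) * spec$n_channels
  n_input <- round(spec$input_fraction * n)
  loop_idx <- seq_len(n_loop)
  input_idx <- seq.int(n - n_input + 1L, length.out = n_input)
  free_idx <- setdiff(seq_len(n), c(loop_idx, input_idx))
  channels <- split(loop_idx, rep(seq_len(spec$n_channels),
                                  each = n_loop / spec$n_channels))
  W_ux[input_idx, ] <- stats::runif(n_input * spec$n_inputs, -1, 1) * spec$input_scale

  structure(list(W_u = W, W_ux = W_ux,
                 partition = list(loop = loop_idx, channels = channels,
                                  input = input_idx, free = free_idx),
                 spec = spec),
            class = "reservoir")
}

#' @export
print.reservoir <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("Cortical reservoir: %d units (%d loop in %d channels, ",
                     "%d input, %d free), %d input lines\n"),
              s$n_units, length(x$partition$loop), s$n_channels,
              length(x$partition$input), length(x$partition$free), s$n_inputs))
  cat(sprintf("  effective spectral radius %.4f (dt = %g ms, tau = %g ms), seed %d\n",
              effective_radius(x$W_u, s$dt, s$tau), s$dt, s$tau, s$seed))
  invisible(x)
}

#' One step of the cortical reservoir
#'
#' Drive is the sum of external input through `W_ux`, recurrent input
#' through `W_u` (from pre-step rates), and the per-channel thalamic drive
#' broadcast uniformly onto the corresponding loop sub-population.
#'
#' @param reservoir a [build_reservoir()] object.
#' @param state a [layer_state()] of length `n_units`.
#' @param x external input vector (length `n_inputs`).
#' @param thal_drive per-channel thalamic drive (length `n_channels`),
#'   already scaled by the thalamo-cortical gain.
#' @param params cortical [layer_params()].
#' @param dt integration step (ms).
#' @return The updated `layer_state`.
#' @export
step_cortex <- function(reservoir, state, x, thal_drive,
                        params = layer_params(), dt = 1) {
  spec <- reservoir$spec
  stopifnot(length(state$u) == spec$n_units, length(x) == spec$n_inputs,
            length(thal_drive) == spec$n_channels)
  drive <- as.numeric(reservoir$W_ux %*% x + reservoir$W_u %*% state$z)
  for (ch in seq_len(spec$n_channels)) {
    idx <- reservoir$partition$channels[[ch]]
    drive[idx] <- drive[idx] + thal_drive[ch]
  }
  step_layer(state, drive, params, dt)
}

#' Linear read-out
#'
#' Batch-mode read-out: the instantaneous linear map `o = W_oz z`.
#' (Online-mode read-outs are leaky dynamic units without lateral
#' connections; see [run_loop_experiment()] with `method = "bpdc"`.)
#'
#' @param W_oz read-out weight matrix (outputs x units), e.g. from
#'   [ridge_fit()].
#' @param z reservoir rate vector.
#' @return Output vector of length `nrow(W_oz)`.
#' @export
read_out <- function(W_oz, z) {
  as.numeric(W_oz %*% z)
}

# Save/restore the global RNG state so seeded constructors do not disturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
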