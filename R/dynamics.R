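#' Leaky rate-unit parameters
#'
#' Parameters of the universal leaky-integrator rate unit used by every
#' layer of the model (cortex, striatum, STN, pallidum, thalamus, dynamic
#' read-outs).  A unit integrates its drive with time constant `tau` and
#' emits a rate through a positive-part tanh transfer with slope `alpha`
#' and threshold `th`:
#'
#' \deqn{\tau \dot u = -u + \mathrm{drive}, \qquad
#'       z = [\tanh(\alpha (u - th))]^{+}}
#'
#' @param tau membrane time constant, ms; must be positive.
#' @param alpha transfer slope (dimensionless, > 0).
#' @param th transfer threshold, in potential units.
#' @return An object of class `layer_params`.
#' @examples
#' p <- layer_params()
#' transfer(c(-1, 0, 0.5, 2), p)
#' @export
layer_params <- function(tau = 10, alpha = 2, th = 0.1) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(th), length(th) == 1L, is.finite(th))
  structure(list(tau = tau, alpha = alpha, th = th), class = "layer_params")
}

#' @export
print.layer_params <- function(x, ...) {
  cat(sprintf("Leaky rate-unit parameters: tau = %g ms, alpha = %g, th = %g\n",
              x$tau, x$alpha, x$th))
  invisible(x)
}

#' Layer state (potentials and rates)
#'
#' @param n number of units, or a numeric vector of initial potentials.
#' @param params a [layer_params()] object used to compute initial rates.
#' @return A `layer_state` list with elements `u` (potentials) and `z`
#'   (rates, always consistent with `u` through [transfer()]).
#' @export
layer_state <- function(n, params = layer_params()) {
  u <- if (length(n) == 1L && n >= 1 && n == round(n)) numeric(n) else as.numeric(n)
  structure(list(u = u, z = transfer(u, params)), class = "layer_state")
}

#' Positive-part tanh transfer function
#'
#' Maps activation potentials to population firing rates.  Rates are
#' clipped at zero from below (a population cannot have negative activity)
#' and saturate below 1.
#'
#' @param u numeric vector of activation potentials.
#' @param params a [layer_params()] object.
#' @return Rate vector in `[0, 1)`, same length as `u`.
#' @export
transfer <- function(u, params = layer_params()) {
  if (!all(is.finite(u))) {
    stop("non-finite activation potentials: numerical blow-up in the dynamics")
  }
  pmax(tanh(params$alpha * (u - params$th)), 0)
}

#' One forward-Euler step of a leaky layer
#'
#' Advances `u` by `dt` under \eqn{\tau \dot u = -u + d} and refreshes the
#' rates.  The explicit scheme requires `dt < tau`.
#'
#' @param state a [layer_state()] object.
#' @param drive numeric drive vector (same length as `state$u`).
#' @param params a [layer_params()] object.
#' @param dt integration step, ms; `0 < dt < tau`.
#' @return The updated `layer_state`.
#' @export
step_layer <- function(state, drive, params = layer_params(), dt = 1) {
  stopifnot(inherits(state, "layer_state"), length(drive) == length(state$u))
  if (!(dt > 0 && dt < params$tau)) {
    stop(sprintf("dt = %g must satisfy 0 < dt < tau = %g (explicit Euler stability)",
                 dt, params$tau))
  }
  u <- state$u + (dt / params$tau) * (-state$u + drive)
  structure(list(u = u, z = transfer(u, params)), class = "layer_state")
}
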