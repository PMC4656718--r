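#' Tikhonov-regularized (ridge) read-out regression
#'
#' Batch learning of linear read-out weights from stacked reservoir states.
#' Rows of `X` are reservoir rate vectors at training timepoints (all
#' trajectories concatenated), rows of `Y` the desired read-out values at
#' the same timepoints.  The solution is
#' \deqn{W_{oz} = (X^\top X + \lambda^2 I)^{-1} X^\top Y}
#' returned transposed so that read-out output is `W_oz %*% z`.
#'
#' @param X numeric matrix, timepoints x units.
#' @param Y numeric matrix (or vector), timepoints x outputs.
#' @param lambda regularization parameter \eqn{\lambda \ge 0}; the penalty
#'   applied to the normal equations is \eqn{\lambda^2}.
#' @return Read-out weight matrix, outputs x units.
#' @examples
#' X <- diag(3); Y <- matrix(1:3)
#' ridge_fit(X, Y, lambda = 0)   # identity design recovers Y
#' @export
ridge_fit <- function(X, Y, lambda = 0.5) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  A <- crossprod(X) + lambda^2 * diag(ncol(X))
  W <- tryCatch(solve(A, crossprod(X, Y)),
                error = function(e) {
                  stop(sprintf(paste0("normal equations are singular at lambda = %g; ",
                                      "use lambda > 0"), lambda))
                })
  t(W)
}

#' Backpropagation-decorrelation (BPDC) read-out update
#'
#' One step of the simplified online BPDC rule for feed-forward read-out
#' units (no read-out autoconnections, so the backpropagation term reduces
#' to a finite difference of errors):
#' \deqn{\Delta W = \frac{\eta}{\Delta t}\, g_{t+1}\, d_t^\top, \quad
#'       d_t = \frac{z_t}{z_t^\top z_t + x_t^\top x_t + \beta}, \quad
#'       g_{t+1} = (1 - \Delta t)\, e_t - e_{t+1}}
#' where \eqn{e_t = o_t - y_t} is the read-out error.
#'
#' @param z_t reservoir rate vector at time t.
#' @param x_t external input vector at time t.
#' @param e_t,e_t1 error vectors (output minus target) at times t and t+1.
#' @param cfg list with `eta` (learning rate > 0), `beta` (regularizer > 0)
#'   and `dt` (the rule's step, dimensionless; see [bpdc_config()]).
#' @return The weight increment, outputs x units.
#' @export
bpdc_update <- function(z_t, x_t, e_t, e_t1, cfg = bpdc_config()) {
  stopifnot(length(e_t) == length(e_t1))
  d <- z_t / (sum(z_t^2) + sum(x_t^2) + cfg$beta)
  g <- (1 - cfg$dt) * e_t - e_t1
  (cfg$eta / cfg$dt) * tcrossprod(g, d)
}

#' BPDC configuration
#'
#' @param eta learning rate (> 0).
#' @param beta decorrelation regularizer (> 0), bounds the denominator of
#'   the decorrelation factor away from zero.
#' @param dt the rule's time step as a fraction of the unit time constant
#'   (dimensionless, in (0, 1)); with the default integration step of 1 ms
#'   and tau = 10 ms this is 0.1.
#' @return A list of class `bpdc_config`.
#' @export
bpdc_config <- function(eta = 0.01, beta = 1, dt = 0.1) {
  stopifnot(eta > 0, beta > 0, dt > 0, dt < 1)
  structure(list(eta = eta, beta = beta, dt = dt), class = "bpdc_config")
}

#' k-winner-take-all filter
#'
#' Keeps the k largest entries of `v` at their original values and zeroes
#' the rest.  Ties are broken by lowest index, so the result is
#' deterministic.
#'
#' @param v numeric vector.
#' @param k number of winners, `1 <= k <= length(v)`.
#' @return Filtered vector, same length as `v`.
#' @examples
#' kwta(c(3, 1, 2), 1)
#' @export
kwta <- function(v, k) {
  n <- length(v)
  if (!(is.numeric(k) && length(k) == 1L && k >= 1 && k <= n)) {
    stop(sprintf("k must be in [1, %d], got %s", n, format(k)))
  }
  k <- as.integer(k)
  if (k == n) return(v)
  keep <- order(v, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(k)]
  out <- numeric(n)
  out[keep] <- v[keep]
  out
}

#' Oja configuration for cortico-striatal learning
#'
#' @param eta_sx learning rate (> 0).
#' @param k_striatum winners kept in the post-synaptic striatal vector
#'   (default 1: a single selected channel learns).
#' @param k_cortex winners kept in the pre-synaptic cortical rate vector
#'   (default 30).
#' @param noise_mu,noise_sigma Gaussian perturbation added to striatal
#'   activations during the cortico-striatal learning phase, so selection
#'   can happen randomly before the weights carry information.
#' @return A list of class `oja_config`.
#' @export
oja_config <- function(eta_sx = 0.05, k_striatum = 1, k_cortex = 30,
                       noise_mu = 0, noise_sigma = 0.1) {
  stopifnot(eta_sx > 0, k_striatum >= 1, k_cortex >= 1, noise_sigma >= 0)
  structure(list(eta_sx = eta_sx, k_striatum = k_striatum, k_cortex = k_cortex,
                 noise_mu = noise_mu, noise_sigma = noise_sigma),
            class = "oja_config")
}

#' Oja/kWTA cortico-striatal weight update
#'
#' Unsupervised Hebbian update with Oja's self-normalizing decay, applied
#' to the weights from a cortical rate vector onto striatal units:
#' \deqn{\Delta W = \eta_{sx}\left( s c^\top -
#'       ((s \odot s) 1^\top) \odot W \right)}
#' where `s` is the striatal vector after adding Gaussian noise and
#' k-winner-take-all filtering (k = `k_striatum`) and `c` the cortical
#' vector after k-winner-take-all filtering (k = `k_cortex`).  Noise uses
#' the current R RNG stream.
#'
#' @param W current weight matrix, striatal units x cortical units.
#' @param s_raw raw striatal rate vector (rows of `W`).
#' @param c_raw raw cortical rate vector (columns of `W`).
#' @param cfg an [oja_config()] object.
#' @param noise logical; add the configured Gaussian perturbation to
#'   `s_raw` before the kWTA filter (the learning-phase condition).
#' @return The weight increment, same shape as `W`.
#' @export
oja_kwta_update <- function(W, s_raw, c_raw, cfg = oja_config(), noise = TRUE) {
  stopifnot(nrow(W) == length(s_raw), ncol(W) == length(c_raw))
  s_in <- if (noise && cfg$noise_sigma > 0) {
    s_raw + stats::rnorm(length(s_raw), cfg$noise_mu, cfg$noise_sigma)
  } else {
    s_raw
  }
  s <- kwta(s_in, min(cfg$k_striatum, length(s_in)))
  cc <- kwta(c_raw, min(cfg$k_cortex, length(c_raw)))
  cfg$eta_sx * (tcrossprod(s, cc) - (s^2) * W)
}
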