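# R wrappers around the compiled simulation kernels.  The kernels replicate
# the synchronous update of step_module(); a parity test keeps them honest.

channel_index_vector <- function(reservoir) {
  ch <- integer(reservoir$spec$n_units)
  for (k in seq_along(reservoir$partition$channels)) {
    ch[reservoir$partition$channels[[k]]] <- k
  }
  ch
}

engine_unit_params <- function(mod) {
  p <- mod$ctx_params
  bp <- mod$bgp$params
  if (!isTRUE(all.equal(unclass(p), unclass(bp)))) {
    stop("the compiled engine assumes cortical and basal ganglia layers share layer_params")
  }
  list(dt = mod$dt, tau = p$tau, alpha = p$alpha, th = p$th)
}

engine_model_list <- function(mod) {
  list(W_u = mod$res$W_u, W_ux = mod$res$W_ux,
       ch = channel_index_vector(mod$res),
       C = mod$bg$n_channels,
       bgp = mod$bgp[setdiff(names(mod$bgp), "params")],
       state = list(u_ctx = mod$ctx$u,
                    u_strd1 = mod$bg$strd1$u, u_strd2 = mod$bg$strd2$u,
                    u_stn = mod$bg$stn$u, u_gpe = mod$bg$gpe$u,
                    u_gpi = mod$bg$gpi$u, u_tha = mod$tha$u))
}

engine_restore_state <- function(mod, st) {
  lp <- mod$ctx_params
  bp <- mod$bgp$params
  as_state <- function(u, p) structure(list(u = as.numeric(u),
                                            z = transfer(as.numeric(u), p)),
                                       class = "layer_state")
  mod$ctx <- as_state(st$u_ctx, lp)
  mod$bg$strd1 <- as_state(st$u_strd1, bp)
  mod$bg$strd2 <- as_state(st$u_strd2, bp)
  mod$bg$stn <- as_state(st$u_stn, bp)
  mod$bg$gpe <- as_state(st$u_gpe, bp)
  mod$bg$gpi <- as_state(st$u_gpi, bp)
  mod$tha <- as_state(st$u_tha, bp)
  mod
}

#' Run a CSNTC module over an input schedule
#'
#' Steps the module through `T = length(da)` synchronous updates using the
#' compiled kernel, optionally recording cortical rate vectors and full
#' per-layer traces.
#'
#' @param mod a [csntc_module()].
#' @param X_ctx external cortical input, `n_inputs x T` matrix (a vector is
#'   treated as one input line).
#' @param X_str external striatal input, `ncol(W_sx) x T` matrix.
#' @param da dopamine schedule, length-`T` vector.
#' @param record integer steps (1-based) at which to record the cortical
#'   rate vector.
#' @param trace logical; record per-step rates of every basal ganglia
#'   layer, the thalamus and the pooled cortical channels.
#' @return List with `mod` (the module with final state), `Z` (units x
#'   recorded-steps matrix) and, if requested, `trace` (list of
#'   `C x T` rate matrices: `strd1`, `strd2`, `stn`, `gpe`, `gpi`, `tha`,
#'   `ctx`).
#' @export
run_module <- function(mod, X_ctx, X_str, da, record = integer(0),
                       trace = FALSE) {
  X_ctx <- to_schedule(X_ctx, mod$res$spec$n_inputs, length(da), "X_ctx")
  X_str <- to_schedule(X_str, ncol(mod$W_sx), length(da), "X_str")
  out <- .cpp_run_module(engine_model_list(mod), engine_unit_params(mod),
                         X_ctx, X_str, as.numeric(da), mod$W_sx,
                         as.integer(record), trace)
  res <- list(mod = engine_restore_state(mod, out$state), Z = out$Z)
  if (trace) res$trace <- out$trace
  res
}

#' @rdname run_module
#' @param W_oz initial read-out weights (outputs x units).
#' @param Y target schedule for the read-outs, `outputs x T`.
#' @param learn logical length-`T` vector; the BPDC update runs where TRUE
#'   (the task windows).
#' @param cfg a [bpdc_config()].
#' @export
run_module_online <- function(mod, X_ctx, X_str, da, W_oz, Y, learn,
                              cfg = bpdc_config(), record = integer(0)) {
  X_ctx <- to_schedule(X_ctx, mod$res$spec$n_inputs, length(da), "X_ctx")
  X_str <- to_schedule(X_str, ncol(mod$W_sx), length(da), "X_str")
  Y <- to_schedule(Y, nrow(W_oz), length(da), "Y")
  out <- .cpp_run_module_online(engine_model_list(mod), engine_unit_params(mod),
                                X_ctx, X_str, as.numeric(da), mod$W_sx,
                                W_oz, Y, as.logical(learn),
                                cfg$eta, cfg$beta, cfg$dt,
                                as.integer(record))
  list(mod = engine_restore_state(mod, out$state), W_oz = out$W_oz, O = out$O)
}

to_schedule <- function(X, rows, T, what) {
  if (is.null(dim(X))) {
    if (rows == 1L) X <- matrix(X, 1L) else
      if (length(X) == rows) X <- matrix(X, rows, T) else
        stop(sprintf("%s: cannot interpret vector of length %d", what, length(X)))
  }
  if (nrow(X) != rows || ncol(X) != T) {
    stop(sprintf("%s must be %d x %d, got %d x %d", what, rows, T,
                 nrow(X), ncol(X)))
  }
  X
}
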