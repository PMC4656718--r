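#' Construct a CSNTC module
#'
#' Composes a cortical reservoir, a C-channel basal ganglia circuit and C
#' thalamic units into one closed cortico-striato-nigro-thalamo-cortical
#' loop.  Channel k's cortical loop sub-population excites (only) channel
#' k's striatal and STN units (pooled as the sub-population mean rate) and
#' its thalamic unit; the thalamic unit is inhibited by channel k's GPi
#' and projects back uniformly onto the same cortical sub-population.
#'
#' @param reservoir a [build_reservoir()] object (or a [reservoir_spec()],
#'   which is built on the fly).
#' @param bgp a [bg_params()].
#' @param ctx_params cortical [layer_params()].
#' @param n_x_striatum dimension of the external striatal input; the
#'   striatal input map `W_sx` defaults to the `C x C` identity (one bias
#'   line per channel), and is replaced by a learnable matrix in
#'   system-level models.
#' @param dt integration step (ms).
#' @return An object of class `csntc_module` holding the reservoir, the
#'   layer states (`ctx`, `bg`, `tha`), the parameters and `W_sx`.
#' @export
csntc_module <- function(reservoir = build_reservoir(),
                         bgp = bg_params(),
                         ctx_params = layer_params(),
                         n_x_striatum = NULL,
                         dt = 1) {
  if (inherits(reservoir, "reservoir_spec")) reservoir <- build_reservoir(reservoir)
  stopifnot(inherits(reservoir, "reservoir"))
  C <- reservoir$spec$n_channels
  if (is.null(n_x_striatum)) n_x_striatum <- C
  W_sx <- if (n_x_striatum == C) diag(C) else matrix(0, C, n_x_striatum)
  structure(list(res = reservoir,
                 ctx = layer_state(reservoir$spec$n_units, ctx_params),
                 bg = bg_state(C, bgp),
                 tha = layer_state(C, bgp$params),
                 bgp = bgp, ctx_params = ctx_params,
                 W_sx = W_sx, dt = dt,
                 frozen = character(0)),
            class = "csntc_module")
}

#' @export
print.csntc_module <- function(x, ...) {
  cat(sprintf("CSNTC module: %d cortical units, %d basal ganglia channels, dt = %g ms\n",
              x$res$spec$n_units, x$bg$n_channels, x$dt))
  if (length(x$frozen)) cat("  lesioned bundles:", paste(x$frozen, collapse = ", "), "\n")
  invisible(x)
}

#' Pooled per-channel cortical rates
#'
#' Mean rate of each thalamo-cortical loop sub-population; this is the
#' cortical signal each basal ganglia channel and thalamic unit sees.
#'
#' @param mod a [csntc_module()].
#' @return Numeric vector of length C.
#' @export
channel_rates <- function(mod) {
  unname(vapply(mod$res$partition$channels, function(idx) mean(mod$ctx$z[idx]), 0))
}

#' One synchronous step of a CSNTC module
#'
#' Cortex, basal ganglia and thalamus all step from pre-step rates, so the
#' update order is immaterial.
#'
#' @param mod a [csntc_module()].
#' @param x_cortex external cortical input (length `n_inputs`).
#' @param x_striatum external striatal input (length `ncol(W_sx)`).
#' @param da dopamine level (scalar >= 0).
#' @param dt integration step; defaults to the module's.
#' @return The updated module.
#' @export
step_module <- function(mod, x_cortex, x_striatum, da, dt = mod$dt) {
  bgp <- mod$bgp
  C <- mod$bg$n_channels
  stopifnot(length(x_striatum) == ncol(mod$W_sx))
  c_pool <- channel_rates(mod)
  x_str <- as.numeric(mod$W_sx %*% x_striatum)
  tha_drive <- bgp$tha_tonic + bgp$w_cttha * c_pool +
    gpi_to_thalamic_gate(mod$bg$gpi$z, bgp)
  thal_to_ctx <- bgp$w_thact * mod$tha$z
  out <- mod
  out$bg <- step_bg(mod$bg, c_pool, x_str, da, bgp, dt)
  out$tha <- step_layer(mod$tha, tha_drive, bgp$params, dt)
  out$ctx <- step_cortex(mod$res, mod$ctx, x_cortex, thal_to_ctx,
                         mod$ctx_params, dt)
  out
}

#' Lesion named connection bundles
#'
#' Zeroes and freezes the named weight bundles; frozen bundles are
#' excluded from any subsequent learning.  Bundle names for a single
#' module: `"striatal_input"` (the module's `W_sx`), `"readout"`,
#' `"thalamocortical"`.  System-level bundle names (see
#' [run_system_experiment()]): `"pfc_to_hl_striatum"`,
#' `"hlctx_to_pm_striatum"`.
#'
#' @param x a `csntc_module` or `csntc_system` object.
#' @param bundles character vector of bundle names (may be empty).
#' @param ... unused.
#' @return The lesioned object.
#' @export
lesion <- function(x, bundles, ...) UseMethod("lesion")

#' @rdname lesion
#' @export
lesion.csntc_module <- function(x, bundles, ...) {
  known <- c("striatal_input", "readout", "thalamocortical")
  bad <- setdiff(bundles, known)
  if (length(bad)) stop("unknown lesion bundle(s): ", paste(bad, collapse = ", "))
  for (b in bundles) {
    if (b == "striatal_input") x$W_sx[] <- 0
    if (b == "readout" && !is.null(x$W_oz)) x$W_oz[] <- 0
    if (b == "thalamocortical") x$bgp$w_thact <- 0
  }
  x$frozen <- union(x$frozen, bundles)
  x
}
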