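#' Export layer traces as tidy CSV
#'
#' Converts the `trace` element of [run_module()] into a long data frame
#' (time, layer, channel, rate) and optionally writes it to CSV, the
#' format used for selection time-course figures.
#'
#' @param trace the `trace` list returned by `run_module(..., trace = TRUE)`.
#' @param file optional path; when given the data frame is also written.
#' @return The tidy data frame (invisibly when `file` is given).
#' @export
trace_to_df <- function(trace, file = NULL) {
  out <- do.call(rbind, lapply(names(trace), function(layer) {
    m <- trace[[layer]]
    data.frame(time = rep(seq_len(ncol(m)), each = nrow(m)),
               layer = layer,
               channel = rep(seq_len(nrow(m)), ncol(m)),
               rate = as.numeric(m))
  }))
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Save and load a CSNTC module snapshot
#'
#' Serializes a module to a directory of portable text files: a JSON
#' manifest (reservoir spec, basal ganglia and unit parameters, partition,
#' current state, lesions) plus CSV weight matrices (`W_u`, `W_ux`,
#' `W_sx`, and the read-out `W_oz` when present).
#'
#' @param mod a [csntc_module()].
#' @param dir destination directory (created if needed).
#' @return `snapshot_save` returns `dir` invisibly; `snapshot_load`
#'   returns the reconstructed module.
#' @export
snapshot_save <- function(mod, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, name) {
    utils::write.csv(m, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  wm(mod$res$W_u, "W_u")
  wm(mod$res$W_ux, "W_ux")
  wm(mod$W_sx, "W_sx")
  if (!is.null(mod$W_oz)) wm(mod$W_oz, "W_oz")
  manifest <- list(
    spec = unclass(mod$res$spec),
    bgp = mod$bgp[setdiff(names(mod$bgp), "params")],
    unit_params = unclass(mod$bgp$params),
    ctx_params = unclass(mod$ctx_params),
    dt = mod$dt,
    frozen = mod$frozen,
    has_readout = !is.null(mod$W_oz),
    state = list(u_ctx = mod$ctx$u,
                 u_strd1 = mod$bg$strd1$u, u_strd2 = mod$bg$strd2$u,
                 u_stn = mod$bg$stn$u, u_gpe = mod$bg$gpe$u,
                 u_gpi = mod$bg$gpi$u, u_tha = mod$tha$u))
  jsonlite::write_json(manifest, file.path(dir, "module.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname snapshot_save
#' @export
snapshot_load <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "module.json"), simplifyVector = TRUE)
  rm_ <- function(name) {
    as.matrix(utils::read.csv(file.path(dir, paste0(name, ".csv"))))
  }
  spec <- do.call(reservoir_spec, man$spec)
  res <- build_reservoir(spec)   # partition layout is seed-determined
  res$W_u <- unname(rm_("W_u"))
  res$W_ux <- unname(rm_("W_ux"))
  lp <- do.call(layer_params, man$unit_params)
  bgp <- do.call(bg_params, c(man$bgp, list(params = lp)))
  mod <- csntc_module(res, bgp = bgp,
                      ctx_params = do.call(layer_params, man$ctx_params),
                      n_x_striatum = ncol(rm_("W_sx")), dt = man$dt)
  mod$W_sx <- unname(rm_("W_sx"))
  if (isTRUE(man$has_readout)) mod$W_oz <- unname(rm_("W_oz"))
  mod$frozen <- as.character(man$frozen)
  mod <- engine_restore_state(mod, man$state)
  mod
}
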