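# Shared small model instances (built once per test run).

small_reservoir <- function(seed = 3, n_units = 60, ...) {
  build_reservoir(reservoir_spec(n_units = n_units, seed = seed, ...))
}

small_module <- function(seed = 3, n_units = 60, ...) {
  csntc_module(small_reservoir(seed = seed, n_units = n_units, ...))
}

# Step the basal ganglia alone to its steady state under constant input.
bg_steady <- function(c_in, x_in, da, params = bg_params(), C = length(c_in),
                      t_max = 5000, dt = 1, tol = 1e-10) {
  st <- bg_state(C, params)
  for (t in seq_len(t_max)) {
    st2 <- step_bg(st, c_in, x_in, da, params, dt)
    del <- max(abs(st2$gpi$u - st$gpi$u), abs(st2$strd1$u - st$strd1$u),
               abs(st2$gpe$u - st$gpe$u), abs(st2$stn$u - st$stn$u),
               abs(st2$strd2$u - st$strd2$u))
    st <- st2
    if (del < tol) break
  }
  st
}

# Canonical lock-in schedule (the scripted dopamine/bias time course).
lockin_run <- function(mod = small_module(n_units = 100), fx = make_fixture("lockin_schedule")) {
  run_module(mod, fx$payload$x_ctx, fx$payload$x_str, fx$payload$da,
             trace = TRUE)
}
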