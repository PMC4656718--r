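#' Deterministic test fixtures
#'
#' Small, seeded model instances and problems used by the test suite and
#' for debugging; regeneration with the same seed is reproducible on any
#' platform.  Available names:
#'
#' * `"bg2"` — 2-channel basal ganglia instance with a biased constant
#'   input (channel 1 strongest) and high dopamine; expected winner 1.
#' * `"bg3"` — 3-channel variant, channel 2 biased.
#' * `"ridge_small"` — 20 x 5 regression problem with a 2-column target.
#' * `"lockin_schedule"` — the scripted dopamine/bias/sinusoid time course
#'   that elicits the canonical selection event sequence (StrD1 rise on
#'   dopamine onset, selective GPi dip, up-state lock-in persisting after
#'   input offset, unlock after dopamine offset).
#' * `"small_reservoir"` — a 60-unit reservoir spec for fast tests.
#' * `"anova_2x2"` — a 2 x 2, n = 3 table with hand-checkable sums of
#'   squares.
#'
#' @param name fixture name (see above).
#' @param seed RNG seed.
#' @return A list of class `csntc_fixture` with `name`, `seed` and
#'   `payload`.
#' @export
make_fixture <- function(name, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  payload <- switch(name,
    bg2 = list(params = bg_params(),
               c_in = c(0.05, 0.05),
               x_in = c(0.4, 0.1),
               da = 1,
               expected_winner = 1L),
    bg3 = list(params = bg_params(),
               c_in = rep(0.05, 3),
               x_in = c(0.1, 0.4, 0.1),
               da = 1,
               expected_winner = 2L),
    ridge_small = list(X = matrix(rnorm(100), 20, 5),
                       Y = matrix(rnorm(40), 20, 2),
                       lambda = 0.1),
    lockin_schedule = {
      Tn <- 4000
      list(T = Tn,
           x_ctx = matrix(0.5 * (1 + sin(2 * pi * (1:Tn) / 1000)), 1),
           x_str = {
             xs <- matrix(0, 3, Tn)
             xs[2, 600:1500] <- 1
             xs
           },
           da = as.numeric(1:Tn >= 500 & 1:Tn < 3000),
           channel = 2L,
           bias_off = 1500L, da_off = 3000L)
    },
    small_reservoir = reservoir_spec(n_units = 60, seed = seed),
    anova_2x2 = {
      d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
      d <- d[rep(seq_len(4), each = 3), ]
      d$y <- c(1, 2, 3,  4, 5, 6,  2, 3, 4,  9, 10, 11)
      d
    },
    stop(sprintf("unknown fixture '%s'", name))
  )
  structure(list(name = name, seed = as.integer(seed), payload = payload),
            class = "csntc_fixture")
}

#' @export
print.csntc_fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s' (seed %d)\n", x$name, x$seed))
  utils::str(x$payload, max.level = 1)
  invisible(x)
}
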