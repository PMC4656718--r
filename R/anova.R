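#' Two-way fixed-effects ANOVA from sums of squares
#'
#' Classical balanced two-factor analysis of variance with interaction,
#' computed directly from the sums of squares (no model-fitting
#' machinery), as used to analyse the lesion experiment: factor A is the
#' test condition (SAME vs DIFF), factor B the lesion group, observations
#' the per-simulation NRMSE.
#'
#' For a balanced design with cell counts n:
#' \deqn{SS_A = n b \sum_a (\bar y_{a\cdot} - \bar y)^2, \quad
#'       SS_B = n a \sum_b (\bar y_{\cdot b} - \bar y)^2,}
#' \deqn{SS_{AB} = n \sum_{ab} (\bar y_{ab} - \bar y_{a\cdot}
#'       - \bar y_{\cdot b} + \bar y)^2, \quad
#'       SS_E = \sum_{abi} (y_{abi} - \bar y_{ab})^2.}
#'
#' @param y numeric response vector.
#' @param A,B factors (or vectors coercible to factors) of the same
#'   length as `y`.
#' @return A list of class `anova2` with `F_A`, `F_B`, `F_AB`, `p_A`,
#'   `p_B`, `p_AB`, degrees of freedom `df` (named vector) and the sums
#'   of squares.
#' @examples
#' set.seed(1)
#' d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), i = 1:5)
#' y <- rnorm(nrow(d)) + (d$A == "a2") * (d$B == "b2")
#' anova_two_way(y, d$A, d$B)
#' @export
anova_two_way <- function(y, A, B) {
  A <- factor(A)
  B <- factor(B)
  stopifnot(length(y) == length(A), length(y) == length(B))
  cell_n <- table(A, B)
  if (any(cell_n < 2)) stop("every factor-level cell needs at least 2 observations")
  if (max(cell_n) != min(cell_n)) {
    warning("unbalanced design; sums of squares computed from cell means")
  }
  n <- mean(cell_n)
  a <- nlevels(A)
  b <- nlevels(B)
  gm <- mean(y)
  m_a <- tapply(y, A, mean)
  m_b <- tapply(y, B, mean)
  m_ab <- tapply(y, list(A, B), mean)

  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                    outer(rep(1, a), m_b) + gm)^2)
  ss_e <- sum((y - m_ab[cbind(A, B)])^2)

  df <- c(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1),
          error = length(y) - a * b)
  ms <- c(ss_a, ss_b, ss_ab) / df[1:3]
  mse <- ss_e / df["error"]
  Fv <- ms / mse
  pv <- stats::pf(Fv, df[1:3], df["error"], lower.tail = FALSE)

  structure(list(F_A = unname(Fv[1]), F_B = unname(Fv[2]), F_AB = unname(Fv[3]),
                 p_A = unname(pv[1]), p_B = unname(pv[2]), p_AB = unname(pv[3]),
                 df = df, ss = c(A = ss_a, B = ss_b, AB = ss_ab, error = ss_e)),
            class = "anova2")
}

#' @export
print.anova2 <- function(x, ...) {
  cat("Two-way fixed-effects ANOVA\n")
  cat(sprintf("  A:    F(%d,%d) = %.3f, p = %.4g\n", x$df["A"], x$df["error"],
              x$F_A, x$p_A))
  cat(sprintf("  B:    F(%d,%d) = %.3f, p = %.4g\n", x$df["B"], x$df["error"],
              x$F_B, x$p_B))
  cat(sprintf("  AxB:  F(%d,%d) = %.3f, p = %.4g\n", x$df["AB"], x$df["error"],
              x$F_AB, x$p_AB))
  invisible(x)
}

#' Interaction ANOVA of lesion-experiment records
#'
#' Aggregates [run_system_experiment()] records to one NRMSE per
#' simulation and condition, then runs the TEST x LESION two-way ANOVA
#' comparing one lesion group against another (typically BASELINE).
#'
#' @param records_a,records_b `system_records` data.frames from two runs
#'   of [run_system_experiment()] (e.g. BASELINE and PARTIAL_LESION).
#' @return The [anova_two_way()] result; factor A is TEST (SAME/DIFF),
#'   factor B is LESION.
#' @export
lesion_anova <- function(records_a, records_b) {
  per_sim <- function(r) {
    agg <- stats::aggregate(nrmse ~ sim + condition + lesion, data = r, FUN = mean)
    agg
  }
  d <- rbind(per_sim(records_a), per_sim(records_b))
  anova_two_way(d$nrmse, d$condition, d$lesion)
}
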