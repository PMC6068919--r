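# Closed-form payoff algebra for the three-strategy repeated game.
#
# g_n is the expected fraction of the population acting cooperatively in
# round n: g_1 = x1 + p*x3, and g_n = x1 + g_{n-1}*x3 for n >= 2, whose
# closed form is g_n = a + x3^n * (p - a) with a = x1/(1 - x3).
#
# All internal evaluators take bare (x1, x3) coordinates so that the
# equilibrium solvers can evaluate the same algebra at points outside the
# simplex (the relaxed branch); the exported functions validate a proper
# population_state first. The closed forms divide by (1 - x3) (and the
# squared-sum form by 1 - x3^2), so within 1e-9 of either pole every sum
# is computed by the always-finite recursion instead.

.POLE_TOL <- 1e-9

.near_pole <- function(x3) min(abs(1 - x3), abs(1 + x3)) < .POLE_TOL

# g_1..g_nmax by direct iteration of the recursion; finite for any real
# (x1, x3).
.g_seq <- function(params, x1, x3, n_max) {
  g <- numeric(n_max)
  g[1] <- x1 + params$p * x3
  if (n_max >= 2) {
    for (n in 2:n_max) g[n] <- x1 + g[n - 1] * x3
  }
  g
}

# Sum_{n=2}^{N} g_n and Sum_{n=2}^{N} g_n^2, closed form away from the
# poles, recursion otherwise.
.g_sums <- function(params, x1, x3) {
  N <- params$N
  p <- params$p
  if (N < 2) return(list(sg = 0, sg2 = 0))
  if (.near_pole(x3)) {
    g <- .g_seq(params, x1, x3, N)
    return(list(sg = sum(g[-1]), sg2 = sum(g[-1]^2)))
  }
  a <- x1 / (1 - x3)
  s1 <- (x3^2 - x3^(N + 1)) / (1 - x3)
  s2 <- (x3^4 - x3^(2 * (N + 1))) / (1 - x3^2)
  list(sg  = (N - 1) * a + (p - a) * s1,
       sg2 = (N - 1) * a^2 + 2 * a * (p - a) * s1 + (p - a)^2 * s2)
}

# Relative payoffs (differences from the defector) on the relaxed domain.
.rhat1 <- function(params, x1, x3) {
  N <- params$N; piv <- params$pi; cc <- params$c
  th <- params$theta; p <- params$p
  -N * cc + N * th * piv + N * (1 - 2 * th) * x1 * piv +
    (N * (1 - th) + p + th - 1 - 2 * p * th) * x3 * piv
}

.rhat3 <- function(params, x1, x3) {
  N <- params$N; piv <- params$pi; cc <- params$c
  th <- params$theta; p <- params$p
  s <- .g_sums(params, x1, x3)
  -cc * p + p * th * piv + (p + th - 2 * p * th - N * th) * x1 * piv +
    (1 - 2 * th) * p^2 * x3 * piv +
    (piv + th * piv - cc) * s$sg - th * piv * s$sg2
}

#' Expected cooperation fraction in round n
#'
#' `coop_fraction()` evaluates the closed form
#' \eqn{g_n = \frac{x_1}{1-x_3} + x_3^n\left(p - \frac{x_1}{1-x_3}\right)},
#' falling back to the recursion near the singular point \eqn{x_3 = 1}.
#' `coop_fraction_recursive()` iterates the defining recursion
#' \eqn{g_1 = x_1 + p x_3}, \eqn{g_n = x_1 + g_{n-1} x_3} directly and
#' serves as the independent oracle for the closed form.
#'
#' @param params A [game_parameters()] object.
#' @param state A [population_state()].
#' @param n Round index (\eqn{\ge 1}); `coop_fraction()` accepts a vector
#'   of indices, the recursive form a single index.
#' @return The expected fraction(s) of the population acting
#'   cooperatively in round `n`, in `[0, 1]`.
#' @examples
#' params <- game_parameters(100, 1e6, 0.5e6, 0.75, 0.5)
#' st <- population_state(0.3, 0.3, 0.4)
#' coop_fraction(params, st, 1)   # 0.3 + 0.5 * 0.4 = 0.5
#' coop_fraction(params, st, 1:5)
#' @export
coop_fraction <- function(params, state, n) {
  .check_params(params)
  if (any(n < 1) || any(n != round(n)))
    stop("round index n must be a positive integer", call. = FALSE)
  xs <- .state_x13(state)
  x1 <- xs[1]; x3 <- xs[2]
  if (.near_pole(x3)) {
    g <- .g_seq(params, x1, x3, max(n))
    return(g[n])
  }
  a <- x1 / (1 - x3)
  a + x3^n * (params$p - a)
}

#' @rdname coop_fraction
#' @export
coop_fraction_recursive <- function(params, state, n) {
  .check_params(params)
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("round index n must be a single positive integer", call. = FALSE)
  xs <- .state_x13(state)
  .g_seq(params, xs[1], xs[2], n)[n]
}

#' Closed-form sums of the cooperation fractions
#'
#' `sum_g()` returns \eqn{\sum_{n=2}^{N} g_n} and `sum_g_sq()` returns
#' \eqn{\sum_{n=2}^{N} g_n^2}, using the geometric-series closed forms
#' away from \eqn{x_3 = 1} and direct summation of the recursion there.
#' These are the building blocks of the discriminator's total payoff.
#'
#' @inheritParams coop_fraction
#' @return A single numeric value (dimensionless).
#' @export
sum_g <- function(params, state) {
  .check_params(params)
  xs <- .state_x13(state)
  .g_sums(params, xs[1], xs[2])$sg
}

#' @rdname sum_g
#' @export
sum_g_sq <- function(params, state) {
  .check_params(params)
  xs <- .state_x13(state)
  .g_sums(params, xs[1], xs[2])$sg2
}

# Per-round expected payoffs on bare coordinates. For n >= 2 the caller
# may pass a precomputed g_n (used by the summation oracle so that it
# never touches the closed form).
.round_payoffs_x13 <- function(params, x1, x3, n, g_n = NULL) {
  piv <- params$pi; cc <- params$c; th <- params$theta; p <- params$p
  if (n == 1) {
    q <- x1 + p * x3  # chance the partner cooperates in round 1
    r1 <- -cc + th * piv + (1 - th) * q * piv
    r2 <- q * th * piv
    r3 <- -cc * p + p * th * piv + (p + th - 2 * p * th) * q * piv
  } else {
    if (is.null(g_n)) {
      g_n <- if (.near_pole(x3)) {
        .g_seq(params, x1, x3, n)[n]
      } else {
        a <- x1 / (1 - x3)
        a + x3^n * (p - a)
      }
    }
    r1 <- -cc + th * piv + (x1 + x3) * (1 - th) * piv
    r2 <- x1 * th * piv
    r3 <- g_n * (1 + th - th * g_n) * piv - cc * g_n
  }
  c(r1 = r1, r2 = r2, r3 = r3)
}

.payoff_triple <- function(r, round = NA_integer_) {
  structure(list(r1 = unname(r[1]), r2 = unname(r[2]), r3 = unname(r[3]),
                 round = round),
            class = "payoff_triple")
}

#' @export
print.payoff_triple <- function(x, ...) {
  lbl <- if (is.na(x$round)) "total payoffs over N rounds"
         else sprintf("expected payoffs in round %d", x$round)
  cat(lbl, "\n")
  cat(sprintf("  cooperator    R1 = %.6g\n", x$r1))
  cat(sprintf("  defector      R2 = %.6g\n", x$r2))
  cat(sprintf("  discriminator R3 = %.6g\n", x$r3))
  invisible(x)
}

#' Expected payoffs of the three strategies in a single round
#'
#' Round 1 uses the pre-reputation expressions (a discriminator
#' cooperates with probability `p`); rounds \eqn{n \ge 2} use the
#' stationary per-round expressions in which the discriminator's payoff
#' is \eqn{g_n(1 + \theta - \theta g_n)\pi - c\,g_n}.
#'
#' @inheritParams coop_fraction
#' @param n Single round index (\eqn{\ge 1}).
#' @return A `payoff_triple` with elements `r1` (cooperator), `r2`
#'   (defector), `r3` (discriminator), in payoff units.
#' @export
round_payoffs <- function(params, state, n) {
  .check_params(params)
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("round index n must be a single positive integer", call. = FALSE)
  xs <- .state_x13(state)
  .payoff_triple(.round_payoffs_x13(params, xs[1], xs[2], n),
                 round = as.integer(n))
}

# Total payoffs on bare coordinates (printed closed forms).
.total_x13 <- function(params, x1, x3) {
  N <- params$N; piv <- params$pi; cc <- params$c
  th <- params$theta; p <- params$p
  s <- .g_sums(params, x1, x3)
  r1 <- -N * cc + N * th * piv + N * (1 - th) * (x1 + x3) * piv -
    (1 - p) * (1 - th) * x3 * piv
  r2 <- N * x1 * th * piv + p * x3 * th * piv
  r3 <- -cc * p + p * th * piv + (p + th - 2 * p * th) * (x1 + p * x3) * piv +
    (piv + th * piv - cc) * s$sg - th * piv * s$sg2
  c(r1 = r1, r2 = r2, r3 = r3)
}

#' Total expected payoffs over all N rounds
#'
#' `total_payoffs()` evaluates the closed-form totals R1, R2, R3 (the
#' geometric sums \eqn{\sum g_n} and \eqn{\sum g_n^2} are collapsed
#' analytically). `total_payoffs_by_summation()` accumulates
#' [round_payoffs()] over rounds `1..N` with `g_n` obtained purely by
#' recursion; it contains none of the closed-form sum algebra and is the
#' cross-check oracle used throughout the test-suite.
#'
#' @inheritParams coop_fraction
#' @return A `payoff_triple` of cumulative expected payoffs (payoff
#'   units).
#' @examples
#' params <- game_parameters(100, 1e6, 0.5e6, 0.75, 0.5)
#' total_payoffs(params, simplex_vertex("e1"))$r1  # N * (pi - c) = 5e7
#' @export
total_payoffs <- function(params, state) {
  .check_params(params)
  xs <- .state_x13(state)
  .payoff_triple(.total_x13(params, xs[1], xs[2]))
}

#' @rdname total_payoffs
#' @export
total_payoffs_by_summation <- function(params, state) {
  .check_params(params)
  xs <- .state_x13(state)
  x1 <- xs[1]; x3 <- xs[2]
  g <- .g_seq(params, x1, x3, params$N)
  tot <- c(r1 = 0, r2 = 0, r3 = 0)
  for (n in seq_len(params$N)) {
    tot <- tot + .round_payoffs_x13(params, x1, x3, n, g_n = g[n])
  }
  .payoff_triple(tot)
}

#' Payoffs relative to the defector
#'
#' Returns \eqn{\hat R_1 = R_1 - R_2}, \eqn{\hat R_2 = 0},
#' \eqn{\hat R_3 = R_3 - R_2} in their expanded closed forms, together
#' with the mean relative payoff \eqn{\bar R = x_1 \hat R_1 + x_3 \hat
#' R_3} that drives the replicator dynamics.
#'
#' @inheritParams coop_fraction
#' @return An object of class `relative_payoffs` with elements `rhat1`,
#'   `rhat2` (identically 0), `rhat3`, and `rbar` (payoff units).
#' @export
relative_payoffs <- function(params, state) {
  .check_params(params)
  xs <- .state_x13(state)
  r1h <- .rhat1(params, xs[1], xs[2])
  r3h <- .rhat3(params, xs[1], xs[2])
  structure(list(rhat1 = r1h, rhat2 = 0, rhat3 = r3h,
                 rbar = xs[1] * r1h + xs[2] * r3h),
            class = "relative_payoffs")
}

#' @export
print.relative_payoffs <- function(x, ...) {
  cat("payoffs relative to the defector\n")
  cat(sprintf("  Rhat1 = %.6g\n  Rhat2 = 0\n  Rhat3 = %.6g\n  Rbar  = %.6g\n",
              x$rhat1, x$rhat3, x$rbar))
  invisible(x)
}
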