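#' Game parameters for the indirect-reciprocity game
#'
#' Constructs and validates the constants of the repeated three-strategy
#' game. In every round players are pairwise matched at random. If both
#' partners cooperate each obtains benefit `pi` at cost `c`; if exactly one
#' cooperates, both obtain the cross benefit `v = theta * pi` but only the
#' cooperator pays `c`; if both defect, payoffs are zero. Discriminators
#' have no reputation information in round 1 and cooperate there with
#' probability `p`; from round 2 onward they copy their current partner's
#' publicly observed action from the previous round.
#'
#' @param N Number of rounds played (positive integer).
#' @param pi Mutual-cooperation benefit, in payoff units. Must exceed `c`.
#' @param c Cost of cooperating, in payoff units. Must be positive.
#' @param theta Defection-benefit ratio in (0, 1); the unilateral
#'   cross benefit is `v = theta * pi`, so `v < pi` always holds.
#' @param p Probability that a discriminator cooperates in round 1,
#'   in `[0, 1]`.
#'
#' @return An object of class `game_parameters`: a list with elements
#'   `N`, `pi`, `c`, `theta`, `p` and the derived cross benefit `v`.
#'   `v` is always computed as `theta * pi`, never stored independently.
#'
#' @examples
#' params <- game_parameters(N = 100, pi = 1e6, c = 0.5e6, theta = 0.75, p = 0.5)
#' params$v  # 7.5e5
#' @export
game_parameters <- function(N, pi, c, theta, p) {
  for (nm in c("N", "pi", "c", "theta", "p")) {
    val <- get(nm, inherits = FALSE)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (N < 1 || N != round(N))
    stop("round count N must be a positive integer", call. = FALSE)
  if (c <= 0)
    stop("cooperation cost c must be positive", call. = FALSE)
  if (pi <= c)
    stop("mutual-cooperation benefit pi must exceed the cost c", call. = FALSE)
  if (theta <= 0 || theta >= 1)
    stop("defection-benefit ratio theta must lie strictly between 0 and 1",
         call. = FALSE)
  if (p < 0 || p > 1)
    stop("round-1 discriminator cooperation probability p must lie in [0, 1]",
         call. = FALSE)
  structure(
    list(N = as.integer(N), pi = pi, c = c, theta = theta, p = p,
         v = theta * pi),
    class = "game_parameters"
  )
}

#' @export
print.game_parameters <- function(x, ...) {
  cat("Indirect-reciprocity game parameters\n")
  cat(sprintf("  rounds N       : %d\n", x$N))
  cat(sprintf("  benefit pi     : %g\n", x$pi))
  cat(sprintf("  cost c         : %g\n", x$c))
  cat(sprintf("  theta          : %g  (cross benefit v = theta*pi = %g)\n",
              x$theta, x$v))
  cat(sprintf("  round-1 p      : %g\n", x$p))
  invisible(x)
}

#' Population state on the strategy simplex
#'
#' A point \eqn{(x_1, x_2, x_3)} of the 2-simplex giving the population
#' fractions of cooperators, defectors, and discriminators. The
#' coordinates must be in `[0, 1]` and sum to 1 within `1e-12`; after
#' validation they are clamped into `[0, 1]` exactly.
#'
#' @param x1 Cooperator fraction.
#' @param x2 Defector fraction.
#' @param x3 Discriminator fraction.
#' @return An object of class `population_state`: a named numeric vector
#'   `c(x1, x2, x3)`.
#' @examples
#' population_state(0.3, 0.3, 0.4)
#' simplex_vertex("e1")  # pure cooperator population
#' @export
population_state <- function(x1, x2, x3) {
  x <- c(x1 = x1, x2 = x2, x3 = x3)
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop("state coordinates must be three finite numbers", call. = FALSE)
  if (any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("each population fraction must lie in [0, 1]", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-12)
    stop(sprintf("population fractions must sum to 1 (got %.15g)", sum(x)),
         call. = FALSE)
  x <- pmin(pmax(x, 0), 1)
  structure(x, class = "population_state")
}

#' @rdname population_state
#' @param vertex One of `"e1"`, `"e2"`, `"e3"`: the pure-cooperator,
#'   pure-defector, and pure-discriminator corners of the simplex.
#' @export
simplex_vertex <- function(vertex = c("e1", "e2", "e3")) {
  vertex <- match.arg(vertex)
  switch(vertex,
         e1 = population_state(1, 0, 0),
         e2 = population_state(0, 1, 0),
         e3 = population_state(0, 0, 1))
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population state (x1, x2, x3) = (%g, %g, %g)\n",
              x[["x1"]], x[["x2"]], x[["x3"]]))
  invisible(x)
}

# Internal: coerce a population_state (or bare length-3 numeric on the
# simplex) to its (x1, x3) coordinates used by the algebraic core.
.state_x13 <- function(state) {
  if (!inherits(state, "population_state")) {
    state <- population_state(state[[1]], state[[2]], state[[3]])
  }
  c(unname(state[1]), unname(state[3]))
}

.check_params <- function(params) {
  if (!inherits(params, "game_parameters"))
    stop("'params' must be created by game_parameters()", call. = FALSE)
  params
}
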