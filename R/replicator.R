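# Replicator dynamics on the strategy simplex:
#   xdot_i = x_i * (Rhat_i - Rbar),  Rbar = x1*Rhat1 + x3*Rhat3.
# The payoff scale is O(N * pi); by default the field is normalised by pi
# (a pure time reparameterisation that leaves orbits unchanged).

# Flow of the full 3-vector y (which may drift off the simplex by
# roundoff during integration): Rbar uses y1 and y3, the defector term
# uses the actual y2, so sum(flow) = (1 - sum(y)) * Rbar ~ 0.
.flow3 <- function(params, y, normalize = FALSE) {
  r1h <- .rhat1(params, y[1], y[3])
  r3h <- .rhat3(params, y[1], y[3])
  rbar <- y[1] * r1h + y[3] * r3h
  v <- c(y[1] * (r1h - rbar), -y[2] * rbar, y[3] * (r3h - rbar))
  if (normalize) v / params$pi else v
}

# Flow restricted to (x1, x3) coordinates with x2 = 1 - x1 - x3; the
# relaxed branch used by the tangent-plane Jacobian.
.flow_x13 <- function(params, x1, x3, normalize = TRUE) {
  r1h <- .rhat1(params, x1, x3)
  r3h <- .rhat3(params, x1, x3)
  rbar <- x1 * r1h + x3 * r3h
  v <- c(x1 * (r1h - rbar), x3 * (r3h - rbar))
  if (normalize) v / params$pi else v
}

#' Replicator vector field
#'
#' Evaluates \eqn{\dot x_i = x_i(\hat R_i - \bar R)} at a simplex state.
#' The three components sum to zero (the flow conserves the simplex);
#' vertices are fixed points.
#'
#' @inheritParams coop_fraction
#' @param normalize_by_pi If `TRUE` (default `FALSE`), divide the field
#'   by `pi`, rescaling time so that velocities are O(N) rather than
#'   O(N * pi).
#' @return Named numeric vector `c(dx1, dx2, dx3)`.
#' @export
vector_field <- function(params, state, normalize_by_pi = FALSE) {
  .check_params(params)
  if (!inherits(state, "population_state"))
    state <- population_state(state[[1]], state[[2]], state[[3]])
  v <- .flow3(params, unclass(state), normalize = normalize_by_pi)
  names(v) <- c("dx1", "dx2", "dx3")
  v
}

#' Integrate a replicator trajectory
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of the
#' replicator flow. After every step the state is checked for
#' divergence (any coordinate beyond `[-0.1, 1.1]` aborts), its drift
#' off the simplex (|sum - 1|) is asserted below `1e-9`, and it is then
#' clamped to `[0, 1]` and renormalised to sum exactly 1.
#'
#' @inheritParams coop_fraction
#' @param start Initial [population_state()].
#' @param step Time increment per step (> 0), in normalised evolutionary
#'   time when `normalize_by_pi` is `TRUE`.
#' @param n_steps Number of steps (>= 1).
#' @param normalize_by_pi Integrate the pi-normalised field (default
#'   `TRUE`; an orbit-invariant time rescaling that keeps step sizes
#'   O(1) instead of O(1/pi)).
#' @return An object of class `trajectory`: list with `times` (length
#'   `n_steps + 1`), `states` (matrix with columns `x1`, `x2`, `x3`),
#'   `params`, and `settings` (step, n_steps, normalisation, maximum
#'   observed per-step drift).
#' @examples
#' params <- game_parameters(100, 1e6, 0.5e6, 0.75, 0.5)
#' tr <- integrate_trajectory(params, population_state(1/3, 1/3, 1/3),
#'                            step = 1e-3, n_steps = 100)
#' tail(tr$states, 1)
#' @export
integrate_trajectory <- function(params, start, step, n_steps,
                                 normalize_by_pi = TRUE) {
  .check_params(params)
  if (!inherits(start, "population_state"))
    start <- population_state(start[[1]], start[[2]], start[[3]])
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a single positive time increment", call. = FALSE)
  if (n_steps < 1 || n_steps != round(n_steps))
    stop("'n_steps' must be a positive integer", call. = FALSE)

  f <- function(y) .flow3(params, y, normalize = normalize_by_pi)
  states <- matrix(NA_real_, nrow = n_steps + 1, ncol = 3,
                   dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- unclass(start)
  states[1, ] <- y
  max_drift <- 0
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + step / 2 * k1)
    k3 <- f(y + step / 2 * k2)
    k4 <- f(y + step * k3)
    y_new <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(abs(y_new) > 1.1) || any(!is.finite(y_new)))
      stop(sprintf(
        "trajectory diverged at step %d (state %s); reduce the step size",
        i, paste(signif(y_new, 4), collapse = ", ")), call. = FALSE)
    drift <- abs(sum(y_new) - 1)
    if (drift > 1e-9)
      stop(sprintf("simplex drift %.3e at step %d exceeds 1e-9", drift, i),
           call. = FALSE)
    max_drift <- max(max_drift, drift)
    y <- pmin(pmax(y_new, 0), 1)
    y <- y / sum(y)
    states[i + 1, ] <- y
  }
  structure(
    list(times = step * (0:n_steps),
         states = states,
         params = params,
         settings = list(step = step, n_steps = as.integer(n_steps),
                         normalize_by_pi = normalize_by_pi,
                         max_drift = max_drift)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("replicator trajectory: %d states, t in [0, %g]%s\n",
              n, x$times[n],
              if (x$settings$normalize_by_pi) " (pi-normalised time)" else ""))
  cat(sprintf("  start (%.4f, %.4f, %.4f) -> end (%.4f, %.4f, %.4f)\n",
              x$states[1, 1], x$states[1, 2], x$states[1, 3],
              x$states[n, 1], x$states[n, 2], x$states[n, 3]))
  cat(sprintf("  max per-step simplex drift %.2e\n", x$settings$max_drift))
  invisible(x)
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' The CSV holds only the columns `t, x1, x2, x3` (so that identical
#' runs produce byte-identical files); the game parameters and
#' integrator settings go to `<stem>_meta.json` next to it.
#'
#' @param trajectory A [integrate_trajectory()] result.
#' @param path Output CSV path.
#' @return Invisibly, a character vector of the two files written.
#' @export
write_trajectory <- function(trajectory, path) {
  if (!inherits(trajectory, "trajectory"))
    stop("'trajectory' must be an integrate_trajectory() result", call. = FALSE)
  df <- data.frame(t = trajectory$times, trajectory$states)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta_path <- paste0(tools::file_path_sans_ext(path), "_meta.json")
  meta <- list(parameters = unclass(trajectory$params),
               integrator = trajectory$settings)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, meta_path))
}

#' Classify a fixed point of the replicator flow
#'
#' Checks that the candidate is stationary (maximum pi-normalised
#' velocity below `tol`), then computes the central-difference Jacobian
#' of the flow restricted to the simplex tangent plane (coordinates
#' \eqn{(x_1, x_3)} with \eqn{x_2 = 1 - x_1 - x_3}) and labels the point
#' by the real parts of its two eigenvalues: `stable` if both are below
#' `-1e-8`, `unstable` if both above `+1e-8`, `saddle` for mixed signs,
#' otherwise `center/inconclusive`.
#'
#' @inheritParams coop_fraction
#' @param candidate A [population_state()] expected to be stationary.
#' @param fd_step Finite-difference perturbation size (default `1e-6`).
#' @param tol Stationarity tolerance on the pi-normalised residual
#'   (default `1e-6`).
#' @return An object of class `fixed_point_report`: `location`,
#'   `residual`, `eigenvalues` (complex, length 2), `label`.
#' @examples
#' params <- game_parameters(100, 1e6, 0.5e6, 0.75, 0.5)
#' classify_fixed_point(params, population_state(0.5, 0.5, 0))
#' @export
classify_fixed_point <- function(params, candidate, fd_step = 1e-6,
                                 tol = 1e-6) {
  .check_params(params)
  if (!inherits(candidate, "population_state"))
    candidate <- population_state(candidate[[1]], candidate[[2]], candidate[[3]])
  v <- .flow3(params, unclass(candidate), normalize = TRUE)
  residual <- max(abs(v))
  if (residual > tol) {
    stop(structure(
      class = c("indirep_not_stationary", "error", "condition"),
      list(message = sprintf(
             "candidate is not stationary: max |xdot|/pi = %.3e > %.1e",
             residual, tol),
           call = NULL, residual = residual)))
  }
  x1 <- unname(candidate[1]); x3 <- unname(candidate[3])
  h <- fd_step
  J <- matrix(0, 2, 2)
  J[, 1] <- (.flow_x13(params, x1 + h, x3) -
             .flow_x13(params, x1 - h, x3)) / (2 * h)
  J[, 2] <- (.flow_x13(params, x1, x3 + h) -
             .flow_x13(params, x1, x3 - h)) / (2 * h)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  thr <- 1e-8
  label <- if (all(re < -thr)) "stable"
           else if (all(re > thr)) "unstable"
           else if (any(re > thr) && any(re < -thr)) "saddle"
           else "center/inconclusive"
  structure(list(location = unclass(candidate),
                 residual = residual,
                 eigenvalues = as.complex(ev),
                 label = label,
                 fd_step = fd_step),
            class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat(sprintf("fixed point at (%.6g, %.6g, %.6g): %s\n",
              x$location[1], x$location[2], x$location[3], x$label))
  cat(sprintf("  residual max|xdot|/pi = %.3e\n", x$residual))
  cat(sprintf("  tangent-plane eigenvalues: %s\n",
              paste(format(x$eigenvalues, digits = 6), collapse = ", ")))
  invisible(x)
}
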