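# Equilibrium analysis: interior roots of Rhat1 = Rhat3 = 0, the three
# boundary-edge equations, and the one-shot Nash classification.
#
# Rhat1 is exactly linear in x1 (coefficient N*(1-2*theta)*pi), so the
# interior system is reduced to one dimension: x1 is eliminated, the
# substituted Rhat3 is scanned for sign changes on a grid, and each
# bracket is polished by Brent's method. Because admissibility is part
# of the question (not a constraint on the algebra), the scan range
# deliberately extends beyond the simplex; roots outside [0, 1] are
# returned with admissible = FALSE. Residuals are reported after
# normalisation by pi, which is valid because every payoff expression is
# homogeneous of degree 1 in (pi, c).

new_equilibrium_root <- function(x1, x3, context, residual) {
  x2 <- 1 - x1 - x3
  structure(
    list(x1 = x1, x2 = x2, x3 = x3,
         admissible = all(c(x1, x2, x3) >= -1e-9 & c(x1, x2, x3) <= 1 + 1e-9),
         context = context,
         residual = residual,
         stability = NA_character_),
    class = "equilibrium_root")
}

#' @export
print.equilibrium_root <- function(x, ...) {
  cat(sprintf("%s root: (x1, x2, x3) = (%.6g, %.6g, %.6g)  %s  residual %.2e%s\n",
              x$context, x$x1, x$x2, x$x3,
              if (x$admissible) "[admissible]" else "[inadmissible]",
              x$residual,
              if (is.na(x$stability)) "" else paste0("  ", x$stability)))
  invisible(x)
}

.roots_list <- function(roots) structure(roots, class = "equilibrium_roots")

#' @export
print.equilibrium_roots <- function(x, ...) {
  if (length(x) == 0) {
    cat("no roots found in scan range\n")
  } else {
    for (r in x) print(r)
  }
  invisible(x)
}

#' @export
as.data.frame.equilibrium_roots <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(x1 = numeric(0), x2 = numeric(0), x3 = numeric(0),
                      admissible = logical(0), context = character(0),
                      residual = numeric(0), stability = character(0)))
  }
  do.call(rbind, lapply(x, function(r)
    data.frame(x1 = r$x1, x2 = r$x2, x3 = r$x3, admissible = r$admissible,
               context = r$context, residual = r$residual,
               stability = r$stability)))
}

# Bracketed sign-change scan with pole exclusion, polished by uniroot to
# 1e-12. Brackets straddling a pole are skipped.
.scan_roots <- function(f, lo, hi, grid, poles = c(-1, 1), margin = 1e-6) {
  xs <- seq(lo, hi, length.out = grid)
  for (pole in poles) xs <- xs[abs(xs - pole) > margin]
  fs <- vapply(xs, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(xs) - 1L)) {
    if (!is.finite(fs[i]) || !is.finite(fs[i + 1])) next
    if (any(poles > xs[i] & poles < xs[i + 1])) next
    if (fs[i] == 0) { roots <- c(roots, xs[i]); next }
    if (fs[i] * fs[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(f, c(xs[i], xs[i + 1]),
                                       tol = 1e-12)$root)
    }
  }
  if (length(roots) > 1) {
    roots <- sort(roots)
    roots <- roots[c(TRUE, diff(roots) > 1e-9)]
  }
  roots
}

.degenerate_theta <- function(params) abs(1 - 2 * params$theta) < 1e-12

#' Interior equilibria of the replicator dynamics
#'
#' Solves the system \eqn{\hat R_1 = 0, \hat R_3 = 0}. \eqn{\hat R_1} is
#' linear in \eqn{x_1}, so \eqn{x_1(x_3)} is eliminated in closed form
#' and the substituted \eqn{\hat R_3} is scanned for sign changes over
#' `x3_scan`, each bracket polished to `1e-12`. The scan range extends
#' beyond the simplex on purpose: roots with any coordinate outside
#' `[0, 1]` are returned flagged inadmissible, which is how the
#' no-interior-equilibrium conclusion is established.
#'
#' @inheritParams coop_fraction
#' @param x3_scan Numeric length-2 scan interval for `x3` (default
#'   `c(-1.5, 1.5)`); must stay at least `1e-6` away from the pole at
#'   `x3 = 1`.
#' @param grid Number of scan points (default 3000).
#' @return An `equilibrium_roots` list of `equilibrium_root` objects
#'   (context `"interior"`), ordered by `x1` ascending. Residuals are
#'   `max(|Rhat1|, |Rhat3|)/pi` at the root.
#' @examples
#' params <- game_parameters(100, 1e6, 0.5e6, 0.75, 0.5)
#' solve_interior(params)
#' @export
solve_interior <- function(params, x3_scan = c(-1.5, 1.5), grid = 3000) {
  .check_params(params)
  if (.degenerate_theta(params)) {
    stop(structure(
      class = c("indirep_degenerate_theta", "error", "condition"),
      list(message = paste(
             "theta = 1/2 makes Rhat1 independent of x1",
             "(coefficient N*(1-2*theta)*pi vanishes); the linear",
             "elimination does not apply and a direct 2-D root search",
             "would be required"),
           call = NULL)))
  }
  N <- params$N; piv <- params$pi; cc <- params$c
  th <- params$theta; p <- params$p
  A <- -N * cc + N * th * piv
  B <- N * (1 - 2 * th) * piv
  C <- (N * (1 - th) + p + th - 1 - 2 * p * th) * piv
  x1_of <- function(x3) -(A + C * x3) / B
  h <- function(x3) .rhat3(params, x1_of(x3), x3)
  x3_roots <- .scan_roots(h, x3_scan[1], x3_scan[2], grid)
  roots <- lapply(x3_roots, function(x3) {
    x1 <- x1_of(x3)
    res <- max(abs(.rhat1(params, x1, x3)), abs(.rhat3(params, x1, x3))) / piv
    new_equilibrium_root(x1, x3, "interior", res)
  })
  roots <- roots[order(vapply(roots, `[[`, numeric(1), "x1"))]
  .roots_list(roots)
}

# The x1 = 0 edge equation (defectors vs discriminators), as a function
# whose roots are the candidate equilibria:
#   p(2t-1)pi x3 + p t pi S2 - (pi + t pi - c) S1 - (t pi - c) = 0
# with S1 = (x3^2 - x3^(N+1))/(1-x3), S2 = (x3^4 - x3^(2N+2))/(1-x3^2).
.edge_no_coop_fn <- function(params) {
  N <- params$N; piv <- params$pi; cc <- params$c
  th <- params$theta; p <- params$p
  function(x3) {
    s1 <- (x3^2 - x3^(N + 1)) / (1 - x3)
    s2 <- (x3^4 - x3^(2 * (N + 1))) / (1 - x3^2)
    p * (2 * th - 1) * piv * x3 + p * th * piv * s2 -
      (piv + th * piv - cc) * s1 - (th * piv - cc)
  }
}

#' Boundary-edge equilibrium analyses
#'
#' Each edge of the simplex is analysed with the strategy absent from it
#' held at zero. `solve_edge_no_cooperator()` solves the
#' defector-discriminator edge equation (equivalent to
#' \eqn{\hat R_3 = 0} at \eqn{x_1 = 0}); `solve_edge_no_defector()`
#' solves the cooperator-discriminator edge equation at
#' \eqn{x_1 = 1 - x_3}; `solve_edge_no_discriminator()` evaluates the
#' closed-form mixed point on the cooperator-defector face from the
#' ratio \eqn{(c - \theta\pi)/((1 - 2\theta)\pi)}. Roots outside
#' `[0, 1]` are flagged inadmissible; an empty admissible set on an open
#' edge means the flow along that edge cannot stall between the
#' vertices.
#'
#' @inheritParams solve_interior
#' @param scan Scan interval in `x3` (default `c(-1.5, 1.5)`); the poles
#'   at `x3 = -1, 1` are excluded by a `1e-6` margin.
#' @return For the two scan-based edges, an `equilibrium_roots` list
#'   (contexts `"edge_e2e3"` and `"edge_e1e3"`; residuals are the edge
#'   equation residual normalised by pi). `solve_edge_no_discriminator()`
#'   returns a list with elements `root` (context `"edge_e1e2"`) and
#'   `nash` (a `nash_classification`).
#' @examples
#' params <- game_parameters(100, 1e6, 0.5e6, 0.75, 0.5)
#' solve_edge_no_cooperator(params)
#' solve_edge_no_discriminator(params)$root
#' @export
solve_edge_no_cooperator <- function(params, scan = c(-1.5, 1.5),
                                     grid = 3000) {
  .check_params(params)
  f <- .edge_no_coop_fn(params)
  roots <- .scan_roots(f, scan[1], scan[2], grid)
  .roots_list(lapply(roots, function(x3)
    new_equilibrium_root(0, x3, "edge_e2e3", abs(f(x3)) / params$pi)))
}

# The x2 = 0 edge equation (cooperators vs discriminators, x1 = 1 - x3),
# in its stated closed form, moved to one side.
.edge_no_def_fn <- function(params) {
  N <- params$N; piv <- params$pi; cc <- params$c
  th <- params$theta; p <- params$p
  function(x3) {
    s1 <- (x3^2 - x3^(N + 1)) / (1 - x3)
    s2 <- (x3^4 - x3^(2 * (N + 1))) / (1 - x3^2)
    (1 - p)^2 * (1 - 2 * th) * piv * x3 +
      th * piv * ((1 - p)^2 * s2 - 2 * (1 - p) * s1) -
      (piv + th * piv - cc) * (1 - p) * s1 -
      (cc * (1 - p) + (1 + p * th - p - th) * piv)
  }
}

#' @rdname solve_edge_no_cooperator
#' @export
solve_edge_no_defector <- function(params, scan = c(-1.5, 1.5), grid = 3000) {
  .check_params(params)
  if (params$p >= 1) {
    stop(structure(
      class = c("indirep_degenerate_p", "error", "condition"),
      list(message = paste(
             "p = 1 degenerates the cooperator-discriminator edge equation",
             "(every (1 - p) term vanishes); on this edge discriminators",
             "then behave identically to cooperators and every point is",
             "neutrally stationary"),
           call = NULL)))
  }
  f <- .edge_no_def_fn(params)
  roots <- .scan_roots(f, scan[1], scan[2], grid)
  .roots_list(lapply(roots, function(x3)
    new_equilibrium_root(1 - x3, x3, "edge_e1e3", abs(f(x3)) / params$pi)))
}

new_nash_classification <- function(regime, boundary_point, ratio,
                                    boundary = FALSE) {
  structure(list(regime = regime, boundary_point = boundary_point,
                 ratio = ratio, boundary = boundary),
            class = "nash_classification")
}

#' @export
print.nash_classification <- function(x, ...) {
  cat(sprintf("one-shot game regime: %s%s\n", x$regime,
              if (isTRUE(x$boundary)) " (boundary case)" else ""))
  cat(sprintf("  ratio (c - theta*pi)/((1 - 2*theta)*pi) = %s\n",
              if (is.na(x$ratio)) "undefined (theta = 1/2)"
              else format(x$ratio)))
  cat(sprintf("  x3 = 0 face point: (%.6g, %.6g, %.6g)\n",
              x$boundary_point[1], x$boundary_point[2], x$boundary_point[3]))
  invisible(x)
}

#' @rdname solve_edge_no_cooperator
#' @export
solve_edge_no_discriminator <- function(params) {
  .check_params(params)
  if (.degenerate_theta(params)) {
    stop(structure(
      class = c("indirep_degenerate_theta", "error", "condition"),
      list(message = paste(
             "theta = 1/2 makes the face ratio",
             "(c - theta*pi)/((1 - 2*theta)*pi) undefined (division by zero)"),
           call = NULL)))
  }
  ratio <- (params$c - params$theta * params$pi) /
    ((1 - 2 * params$theta) * params$pi)
  if (ratio > 0 && ratio < 1) {
    pt <- c(ratio, 1 - ratio, 0)
    regime <- "mixed"
  } else if (ratio <= 0) {
    pt <- c(0, 1, 0)
    regime <- "all_defect"
  } else {
    pt <- c(1, 0, 0)
    regime <- "all_cooperate"
  }
  res <- max(abs(.flow3(params, pt, normalize = TRUE)))
  list(root = new_equilibrium_root(pt[1], 0, "edge_e1e2", res),
       nash = new_nash_classification(regime, pt, ratio,
                                      boundary = ratio %in% c(0, 1)))
}

#' Classify the one-shot two-player game
#'
#' Best-response classification of the single-round payoff matrix
#' (mutual cooperation \eqn{\pi - c}; unilateral cooperation \eqn{v - c}
#' against \eqn{v}; mutual defection 0, with \eqn{v = \theta\pi}):
#' `mixed` when \eqn{v > \pi - c} and \eqn{v > c} (no pure equilibrium);
#' `all_defect` when defection dominates (\eqn{v > \pi - c},
#' \eqn{v < c}); `all_cooperate` otherwise, covering both the
#' cooperation-dominant case and the coordination case, where the
#' payoff-dominant equilibrium (cooperation, cooperation) is selected.
#' Ties (\eqn{v = \pi - c} or \eqn{v = c}) are resolved toward the
#' defect-leaning regime and flagged `boundary`.
#'
#' @inheritParams coop_fraction
#' @return A `nash_classification`: `regime`, the corresponding
#'   `boundary_point` on the \eqn{x_3 = 0} face, the face `ratio`
#'   \eqn{(c - \theta\pi)/((1-2\theta)\pi)} (`NA` when
#'   \eqn{\theta = 1/2}), and a `boundary` flag.
#' @examples
#' classify_static_game(game_parameters(100, 1e6, 0.5e6, 0.75, 0.5))
#' @export
classify_static_game <- function(params) {
  .check_params(params)
  v <- params$v; piv <- params$pi; cc <- params$c
  tie <- (v == piv - cc) || (v == cc)
  defect_from_cc <- v >= piv - cc   # deviating from mutual cooperation pays
  coop_vs_dd <- v > cc              # cooperating against a defector pays
  regime <- if (defect_from_cc && coop_vs_dd) "mixed"
            else if (defect_from_cc && !coop_vs_dd) "all_defect"
            else "all_cooperate"
  ratio <- if (.degenerate_theta(params)) NA_real_
           else (cc - params$theta * piv) / ((1 - 2 * params$theta) * piv)
  pt <- switch(regime,
               mixed = c(ratio, 1 - ratio, 0),
               all_defect = c(0, 1, 0),
               all_cooperate = c(1, 0, 0))
  new_nash_classification(regime, pt, ratio, boundary = tie)
}

#' Full equilibrium report
#'
#' Runs the complete equilibrium analysis for one parameter set: the
#' interior system, the three boundary edges, and the one-shot
#' classification. Every admissible root is additionally classified by
#' [classify_fixed_point()]; the headline summary flag
#' `no_stable_off_face` records whether any admissible, stable
#' equilibrium exists in the interior or on the open
#' defector-discriminator / cooperator-discriminator edges.
#'
#' @inheritParams solve_interior
#' @return An object of class `equilibrium_report` with elements
#'   `params`, `interior`, `edge_e2e3`, `edge_e1e3`, `face` (root +
#'   nash), `static`, and `no_stable_off_face`.
#' @examples
#' params <- game_parameters(100, 1e6, 0.5e6, 0.75, 0.5)
#' rep <- equilibrium_report(params)
#' rep
#' @export
equilibrium_report <- function(params, x3_scan = c(-1.5, 1.5), grid = 3000) {
  .check_params(params)
  interior <- solve_interior(params, x3_scan, grid)
  e23 <- solve_edge_no_cooperator(params, x3_scan, grid)
  e13 <- solve_edge_no_defector(params, x3_scan, grid)
  face <- solve_edge_no_discriminator(params)
  static <- classify_static_game(params)

  attach_stability <- function(root) {
    if (!root$admissible) return(root)
    rep <- tryCatch(
      classify_fixed_point(params,
                           population_state(root$x1, root$x2, root$x3)),
      indirep_not_stationary = function(e) NULL)
    root$stability <- if (is.null(rep)) "not_stationary" else rep$label
    root
  }
  interior <- .roots_list(lapply(interior, attach_stability))
  e23 <- .roots_list(lapply(e23, attach_stability))
  e13 <- .roots_list(lapply(e13, attach_stability))
  face$root <- attach_stability(face$root)

  off_face <- c(interior, e23, e13)
  stable_off_face <- vapply(off_face, function(r)
    isTRUE(r$admissible) && identical(r$stability, "stable"), logical(1))
  structure(
    list(params = params,
         interior = interior,
         edge_e2e3 = e23,
         edge_e1e3 = e13,
         face = face,
         static = static,
         no_stable_off_face = !any(stable_off_face)),
    class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("==== equilibrium report ====\n")
  cat("interior (Rhat1 = Rhat3 = 0):\n"); print(x$interior)
  cat("edge e2-e3 (no cooperator):\n"); print(x$edge_e2e3)
  cat("edge e1-e3 (no defector):\n"); print(x$edge_e1e3)
  cat("face x3 = 0 (no discriminator):\n"); print(x$face$root)
  print(x$face$nash)
  cat("static game: "); print(x$static)
  cat(sprintf(
    "admissible stable equilibrium off the x3 = 0 face: %s\n",
    if (x$no_stable_off_face) "none found" else "FOUND"))
  invisible(x)
}

#' Write an equilibrium report to JSON
#'
#' @param report An [equilibrium_report()] result.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_equilibrium_report <- function(report, path) {
  if (!inherits(report, "equilibrium_report"))
    stop("'report' must be an equilibrium_report() result", call. = FALSE)
  roots_json <- function(roots) lapply(roots, function(r)
    list(x1 = r$x1, x2 = r$x2, x3 = r$x3, admissible = r$admissible,
         context = r$context, residual = r$residual,
         stability = r$stability))
  out <- list(
    parameters = unclass(report$params),
    interior = roots_json(report$interior),
    edge_e2e3 = roots_json(report$edge_e2e3),
    edge_e1e3 = roots_json(report$edge_e1e3),
    face = c(roots_json(list(report$face$root))[[1]],
             list(regime = report$face$nash$regime,
                  ratio = report$face$nash$ratio)),
    static_game = list(regime = report$static$regime,
                       ratio = report$static$ratio,
                       boundary = report$static$boundary),
    no_stable_off_face = report$no_stable_off_face)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
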