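# Ternary phase-portrait plotting in base graphics. Barycentric
# convention: e1 (cooperator) bottom-left at (0,0), e2 (defector)
# bottom-right at (1,0), e3 (discriminator) top at (1/2, sqrt(3)/2).

.TERN_VERTS <- matrix(c(0, 0,
                        1, 0,
                        0.5, sqrt(3) / 2),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("e1", "e2", "e3"), c("x", "y")))

#' Map simplex states to Cartesian plot coordinates
#'
#' Barycentric mapping: a state \eqn{(x_1, x_2, x_3)} is sent to
#' \eqn{x_1 e_1 + x_2 e_2 + x_3 e_3} with the triangle corners
#' \eqn{e_1 = (0,0)}, \eqn{e_2 = (1,0)}, \eqn{e_3 = (1/2, \sqrt3/2)};
#' the centroid `(1/3, 1/3, 1/3)` maps to the triangle's centroid.
#'
#' @param states A length-3 numeric vector or an n-by-3 matrix of
#'   simplex states.
#' @return An n-by-2 matrix of plot coordinates (columns `x`, `y`).
#' @export
simplex_to_cartesian <- function(states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  if (ncol(states) != 3)
    stop("'states' must have three columns (x1, x2, x3)", call. = FALSE)
  xy <- unclass(states) %*% .TERN_VERTS
  colnames(xy) <- c("x", "y")
  xy
}

#' Ternary phase portrait of the replicator dynamics
#'
#' Draws the strategy simplex with trajectories (direction arrows at
#' their midpoints), admissible equilibrium roots, and -- when `params`
#' is supplied -- small arrows along each edge showing the direction of
#' the boundary flow.
#'
#' @param trajectories A `trajectory` or list of them (may be empty).
#' @param roots A list of `equilibrium_root` objects (e.g. the
#'   concatenated output of the solvers); only admissible roots are
#'   drawn.
#' @param path Output image path; the extension selects the device
#'   (`.png`, `.svg`, or `.pdf`).
#' @param params Optional [game_parameters()]; enables the edge-flow
#'   arrows.
#' @param main Plot title.
#' @return Invisibly, `path`.
#' @export
plot_simplex_phase <- function(trajectories = list(), roots = list(), path,
                               params = NULL, main = "replicator phase portrait") {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (inherits(roots, "equilibrium_root")) roots <- list(roots)
  if (length(trajectories) == 0 && length(roots) == 0)
    stop("nothing to plot: supply at least one trajectory or root",
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = 7, height = 6.4, units = "in",
                              res = 150),
         svg = grDevices::svg(path, width = 7, height = 6.4),
         pdf = grDevices::pdf(path, width = 7, height = 6.4),
         stop(sprintf("unsupported image extension '%s'", ext),
              call. = FALSE))
  on.exit(grDevices::dev.off(), add = TRUE)

  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.12, 1.12), ylim = c(-0.1, 1.0),
                        asp = 1)
  graphics::title(main = main)
  graphics::polygon(.TERN_VERTS[, 1], .TERN_VERTS[, 2], border = "grey30")
  lab <- c("e1 (cooperator)", "e2 (defector)", "e3 (discriminator)")
  off <- matrix(c(-0.02, -0.035, 0.02, -0.035, 0, 0.04), nrow = 3,
                byrow = TRUE)
  for (k in 1:3)
    graphics::text(.TERN_VERTS[k, 1] + off[k, 1],
                   .TERN_VERTS[k, 2] + off[k, 2], lab[k], cex = 0.9)

  for (tr in trajectories) {
    xy <- simplex_to_cartesian(tr$states)
    n <- nrow(xy)
    travel <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
    if (travel < 1e-6) {
      graphics::points(xy[1, 1], xy[1, 2], pch = 4, col = "steelblue",
                       cex = 1.2, lwd = 2)
      next
    }
    graphics::lines(xy[, 1], xy[, 2], col = "steelblue")
    m <- max(2, floor(n / 2))
    graphics::arrows(xy[m - 1, 1], xy[m - 1, 2], xy[m, 1], xy[m, 2],
                     length = 0.08, col = "steelblue")
  }

  for (r in roots) {
    if (!isTRUE(r$admissible)) next
    xy <- simplex_to_cartesian(c(r$x1, r$x2, r$x3))
    graphics::points(xy[1, 1], xy[1, 2], pch = 19, col = "firebrick")
  }

  if (!is.null(params)) {
    .check_params(params)
    edges <- list(e1e2 = function(t) c(1 - t, t, 0),
                  e2e3 = function(t) c(0, 1 - t, t),
                  e3e1 = function(t) c(t, 0, 1 - t))
    for (edge in edges) {
      for (t in c(0.25, 0.5, 0.75)) {
        st <- edge(t)
        v <- .flow3(params, st, normalize = TRUE)
        if (max(abs(v)) < 1e-12) next
        v <- v / sqrt(sum(v^2))
        p0 <- simplex_to_cartesian(st)
        p1 <- simplex_to_cartesian(st + 0.045 * v)
        graphics::arrows(p0[1, 1], p0[1, 2], p1[1, 1], p1[1, 2],
                         length = 0.06, col = "grey40", lwd = 1.5)
      }
    }
  }
  invisible(path)
}
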