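test_that("the interior system has exactly two real roots, both inadmissible", {
  params <- printed_params()
  roots <- solve_interior(params)
  expect_length(roots, 2)
  # frozen values from an independent scan-and-polish of the reduced
  # one-dimensional system
  expect_equal(roots[[1]]$x1, 0.244756, tolerance = 1e-5)
  expect_equal(roots[[1]]$x3, -0.520905, tolerance = 1e-5)
  expect_equal(roots[[2]]$x1, 0.664970, tolerance = 1e-5)
  expect_equal(roots[[2]]$x3, 0.336673, tolerance = 1e-5)
  for (r in roots) {
    expect_false(r$admissible)
    expect_lt(r$residual, 1e-8)
    expect_identical(r$context, "interior")
  }
  # roots are ordered by x1 and x2 is the simplex complement
  expect_lt(roots[[1]]$x1, roots[[2]]$x1)
  expect_equal(roots[[1]]$x2, 1 - roots[[1]]$x1 - roots[[1]]$x3)
})

test_that("interior roots satisfy both relative-payoff equations directly", {
  params <- printed_params()
  for (r in solve_interior(params)) {
    rel1 <- indirep:::.rhat1(params, r$x1, r$x3)
    rel3 <- indirep:::.rhat3(params, r$x1, r$x3)
    expect_lt(abs(rel1), 1e-6 * params$pi)
    expect_lt(abs(rel3), 1e-6 * params$pi)
  }
})

test_that("the interior scan is robust to its grid and range settings", {
  params <- printed_params()
  expect_length(solve_interior(params, x3_scan = c(0, 0.3)), 0)
  n_default <- length(solve_interior(params))
  n_fine <- length(solve_interior(params, grid = 6000))
  expect_identical(n_default, n_fine)
})

test_that("theta = 1/2 degenerates the linear elimination and is reported", {
  params <- game_parameters(100, 1e6, 0.4e6, 0.5, 0.5)
  expect_error(solve_interior(params), class = "indirep_degenerate_theta")
  expect_error(solve_edge_no_discriminator(params),
               class = "indirep_degenerate_theta")
})

test_that("the defector-discriminator edge has no equilibrium inside (0,1)", {
  params <- printed_params()
  roots <- solve_edge_no_cooperator(params)
  x3s <- sapply(roots, `[[`, "x3")
  # the root just outside the simplex (frozen from an independent scan)
  expect_true(any(abs(x3s - 1.017363) < 1e-5))
  expect_false(any(x3s > 1e-9 & x3s < 1 - 1e-9))
  for (r in roots) {
    expect_lt(r$residual, 1e-8)
    expect_identical(r$context, "edge_e2e3")
    expect_identical(r$x1, 0)
  }
})

test_that("the cooperator-discriminator edge has no equilibrium inside (0,1)", {
  params <- printed_params()
  roots <- solve_edge_no_defector(params)
  x3s <- sort(sapply(roots, `[[`, "x3"))
  expect_length(x3s, 2)
  expect_equal(x3s[1], -0.919382, tolerance = 1e-5)
  expect_equal(x3s[2], 1.026340, tolerance = 1e-5)
  expect_false(any(x3s > 1e-9 & x3s < 1 - 1e-9))
  for (r in roots) {
    expect_lt(r$residual, 1e-8)
    expect_equal(r$x1, 1 - r$x3)
  }
  # p = 1 collapses every (1 - p) term; flagged, not solved
  expect_error(
    solve_edge_no_defector(game_parameters(100, 1e6, 0.5e6, 0.75, 1)),
    class = "indirep_degenerate_p")
})

test_that("the cooperator-defector face point follows the closed-form ratio", {
  params <- printed_params()
  face <- solve_edge_no_discriminator(params)
  expect_equal(face$nash$ratio, 0.5)
  expect_identical(face$nash$regime, "mixed")
  expect_equal(c(face$root$x1, face$root$x2, face$root$x3), c(0.5, 0.5, 0))
  # the mixed point is defined by R1 = R2, i.e. Rhat1 = 0 on the face
  expect_equal(indirep:::.rhat1(params, face$root$x1, 0), 0)
  # negative ratio: defection takes the face
  low <- game_parameters(100, 1e6, 0.1e6, 0.25, 0.5)
  face_low <- solve_edge_no_discriminator(low)
  expect_equal((0.1e6 - 0.25e6) / (0.5 * 1e6), -0.3)  # ratio by hand
  expect_identical(face_low$nash$regime, "all_defect")
  expect_equal(c(face_low$root$x1, face_low$root$x2, face_low$root$x3),
               c(0, 1, 0))
})

test_that("the one-shot game classifies by best responses with a tie rule", {
  expect_identical(classify_static_game(printed_params())$regime, "mixed")
  # v < pi - c and v < c: cooperation prevails
  coop <- classify_static_game(game_parameters(100, 1e6, 0.6e6, 0.25, 0.5))
  expect_identical(coop$regime, "all_cooperate")
  expect_false(coop$boundary)
  # theta*pi = c exactly: boundary, resolved toward defection
  tie <- classify_static_game(game_parameters(100, 1e6, 0.75e6, 0.75, 0.5))
  expect_identical(tie$regime, "all_defect")
  expect_true(tie$boundary)
})

test_that("the full report finds no stable equilibrium off the x3 = 0 face", {
  params <- printed_params()
  rep <- equilibrium_report(params)
  expect_true(rep$no_stable_off_face)
  expect_length(rep$interior, 2)
  expect_false(any(sapply(rep$interior, `[[`, "admissible")))
  # the face point's stability is computed, not guessed
  expect_false(is.na(rep$face$root$stability))
  path <- tempfile(fileext = ".json")
  write_equilibrium_report(rep, path)
  out <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_length(out$interior, 2)
  expect_equal(out$face$x1, 0.5)
  expect_true(out$no_stable_off_face)
  unlink(path)
})
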