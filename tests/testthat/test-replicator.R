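test_that("the three pure-population vertices are fixed points", {
  params <- printed_params()
  for (v in c("e1", "e2", "e3")) {
    vel <- vector_field(params, simplex_vertex(v), normalize_by_pi = TRUE)
    expect_lt(max(abs(vel)), 1e-9)
  }
})

test_that("the flow conserves the simplex and composes from relative payoffs", {
  params <- printed_params()
  states <- random_simplex_states(20, seed = 7)
  for (i in seq_len(nrow(states))) {
    s <- as_state(states[i, ])
    v <- vector_field(params, s)
    expect_lt(abs(sum(v)), 1e-9 * max(abs(v), 1))
  }
  # independent composition: xdot_i = x_i * (Rhat_i - Rbar)
  s <- population_state(0.3, 0.3, 0.4)
  rel <- relative_payoffs(params, s)
  expected <- c(s[[1]] * (rel$rhat1 - rel$rbar),
                s[[2]] * (0 - rel$rbar),
                s[[3]] * (rel$rhat3 - rel$rbar))
  expect_equal(unname(vector_field(params, s)), expected)
})

test_that("trajectories stay on the simplex and keep absent types absent", {
  params <- printed_params()
  # a vertex start never moves
  tr <- integrate_trajectory(params, simplex_vertex("e1"), 1e-3, 50)
  expect_true(all(abs(tr$states[, "x1"] - 1) < 1e-12))
  # faces are invariant: replicator dynamics cannot resurrect a type
  tr2 <- integrate_trajectory(params, population_state(0.1, 0, 0.9),
                              1e-3, 200)
  expect_true(all(tr2$states[, "x2"] == 0))
  tr3 <- integrate_trajectory(params, population_state(0, 0.5, 0.5),
                              1e-3, 200)
  expect_true(all(tr3$states[, "x1"] == 0))
  # simplex invariants along an interior trajectory
  tr4 <- integrate_trajectory(params, population_state(1/3, 1/3, 1/3),
                              1e-3, 300)
  expect_true(all(abs(rowSums(tr4$states) - 1) < 1e-12))
  expect_true(all(tr4$states >= 0 & tr4$states <= 1))
  expect_lt(tr4$settings$max_drift, 1e-9)
  expect_true(all(diff(tr4$times) > 0))
})

test_that("halving the integration step leaves the terminal state unchanged", {
  params <- printed_params()
  start <- population_state(1/3, 1/3, 1/3)
  coarse <- integrate_trajectory(params, start, 2e-3, 500)
  fine <- integrate_trajectory(params, start, 1e-3, 1000)
  expect_lt(max(abs(coarse$states[501, ] - fine$states[1001, ])), 1e-4)
})

test_that("the defector-discriminator edge flows from e2 toward e3", {
  params <- printed_params()
  for (x3 in seq(0.1, 0.9, by = 0.2)) {
    v <- vector_field(params, population_state(0, 1 - x3, x3))
    expect_gt(v[["dx3"]], 0)
  }
})

test_that("fixed-point classification reports residuals and eigenvalues", {
  params <- printed_params()
  # the cooperator-defector face point solves Rhat1 = 0 on x3 = 0
  rep <- classify_fixed_point(params, population_state(0.5, 0.5, 0))
  expect_lt(rep$residual, 1e-9)
  expect_length(rep$eigenvalues, 2)
  expect_true(rep$label %in%
              c("stable", "unstable", "saddle", "center/inconclusive"))
  # a vertex is stationary even at the closed-form pole x3 = 1
  rep3 <- classify_fixed_point(params, simplex_vertex("e3"))
  expect_lt(rep3$residual, 1e-9)
  # an interior non-equilibrium point is rejected, carrying its residual
  err <- tryCatch(classify_fixed_point(params, population_state(0.3, 0.3, 0.4)),
                  indirep_not_stationary = function(e) e)
  expect_s3_class(err, "indirep_not_stationary")
  expect_gt(err$residual, 1e-6)
})

test_that("the trajectory writer produces a faithful CSV plus metadata", {
  params <- printed_params()
  tr <- integrate_trajectory(params, population_state(0.2, 0.5, 0.3),
                             1e-3, 20)
  csv <- tempfile(fileext = ".csv")
  paths <- write_trajectory(tr, csv)
  df <- read.csv(csv)
  expect_identical(names(df), c("t", "x1", "x2", "x3"))
  expect_equal(df$t, tr$times)
  expect_equal(as.matrix(df[, 2:4]), tr$states, ignore_attr = TRUE,
               tolerance = 1e-12)
  meta <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(meta$parameters$N, 100)
  expect_equal(meta$integrator$step, 1e-3)
  unlink(paths)
})
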