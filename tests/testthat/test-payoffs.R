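test_that("the closed-form cooperation fraction matches the recursion oracle", {
  params <- printed_params()
  st <- population_state(0.3, 0.3, 0.4)
  expect_equal(coop_fraction(params, st, 1), 0.5)  # x1 + p*x3

  states <- rbind(random_simplex_states(12, seed = 11),
                  c(0.5, 0.5, 0), c(0.1, 0, 0.9), c(0, 0.2, 0.8))
  for (i in seq_len(nrow(states))) {
    s <- as_state(states[i, ])
    for (n in c(1, 2, 3, 7, 25, 200)) {
      expect_lt(abs(coop_fraction(params, s, n) -
                    coop_fraction_recursive(params, s, n)), 1e-12)
    }
  }
})

test_that("degenerate compositions collapse the recursion as expected", {
  params <- printed_params()
  # no discriminators: g_n = x1 for every round
  s0 <- population_state(0.35, 0.65, 0)
  expect_equal(coop_fraction(params, s0, 1), 0.35)
  expect_equal(coop_fraction(params, s0, 17), 0.35)
  # pure discriminators: g_n = p is a fixed point of g_n = g_{n-1}
  e3 <- simplex_vertex("e3")
  expect_equal(coop_fraction_recursive(params, e3, 3), params$p)
  expect_equal(coop_fraction(params, e3, 50), params$p)
  # arbitrary mixed state stays inside [0, 1]
  s <- population_state(0.24, 0.28, 0.48)
  g10 <- coop_fraction_recursive(params, s, 10)
  expect_true(is.finite(g10) && g10 >= 0 && g10 <= 1)
  expect_error(coop_fraction(params, s, 0), "positive integer")
})

test_that("g_n approaches x1/(1 - x3) geometrically at rate x3", {
  params <- printed_params()
  s <- population_state(0.2, 0.4, 0.4)
  target <- 0.2 / (1 - 0.4)
  gaps <- sapply(1:10, function(n)
    abs(coop_fraction_recursive(params, s, n) - target))
  expect_equal(gaps[-1] / gaps[-10], rep(0.4, 9), tolerance = 1e-10)
})

test_that("closed-form sums of g_n and g_n^2 match direct summation", {
  params <- printed_params()
  states <- random_simplex_states(20, seed = 23)
  for (i in seq_len(nrow(states))) {
    s <- as_state(states[i, ])
    g <- sapply(2:params$N, function(n) coop_fraction_recursive(params, s, n))
    expect_equal(sum_g(params, s), sum(g), tolerance = 1e-10)
    expect_equal(sum_g_sq(params, s), sum(g^2), tolerance = 1e-10)
  }
  # no discriminators: every g_n = x1, so the sums are (N-1)*x1, (N-1)*x1^2
  s0 <- population_state(0.4, 0.6, 0)
  expect_equal(sum_g(params, s0), 99 * 0.4)
  expect_equal(sum_g_sq(params, s0), 99 * 0.16)
  e2 <- simplex_vertex("e2")
  expect_equal(sum_g(params, e2), 0)
  expect_equal(sum_g_sq(params, e2), 0)
})

test_that("per-round payoffs reproduce the expected-revenue expressions", {
  params <- printed_params()
  # all-cooperator population, any later round: pi - c for the cooperator
  r <- round_payoffs(params, simplex_vertex("e1"), 2)
  expect_equal(r$r1, params$pi - params$c)
  # defectors earn nothing in a defector-only population
  for (n in c(1, 5)) {
    expect_equal(round_payoffs(params, simplex_vertex("e2"), n)$r2, 0)
  }
  # mixed state, round 3: assemble the three expressions independently
  s <- population_state(0.3, 0.3, 0.4)
  x1 <- 0.3; x3 <- 0.4
  th <- params$theta; piv <- params$pi; cc <- params$c; p <- params$p
  g3 <- x1 + (x1 + (x1 + p * x3) * x3) * x3
  r3 <- round_payoffs(params, s, 3)
  expect_equal(r3$r1, -cc + th * piv + (x1 + x3) * (1 - th) * piv)
  expect_equal(r3$r2, x1 * th * piv)
  expect_equal(r3$r3, g3 * (1 + th - th * g3) * piv - cc * g3)
  # round 1 uses the pre-reputation forms
  q <- x1 + p * x3
  r1 <- round_payoffs(params, s, 1)
  expect_equal(r1$r1, -cc + th * piv + (1 - th) * q * piv)
  expect_equal(r1$r2, q * th * piv)
  expect_equal(r1$r3, -cc * p + p * th * piv + (p + th - 2 * p * th) * q * piv)
})

test_that("closed-form totals agree with round-by-round summation", {
  params <- printed_params()
  states <- rbind(random_simplex_states(50, seed = 37),
                  c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0), c(0, 0.5, 0.5))
  for (i in seq_len(nrow(states))) {
    s <- as_state(states[i, ])
    a <- total_payoffs(params, s)
    b <- total_payoffs_by_summation(params, s)
    scale <- max(abs(c(b$r1, b$r2, b$r3, 1)))
    expect_lt(max(abs(c(a$r1 - b$r1, a$r2 - b$r2, a$r3 - b$r3))) / scale,
              1e-6)
  }
  expect_equal(total_payoffs(params, simplex_vertex("e1"))$r1, 5e7)
  expect_equal(total_payoffs(params, simplex_vertex("e2"))$r2, 0)
})

test_that("a pure discriminator population with p = 1 cooperates forever", {
  params <- game_parameters(100, 1e6, 0.5e6, 0.75, 1)
  r <- total_payoffs_by_summation(params, simplex_vertex("e3"))
  expect_equal(r$r3, 100 * (1e6 - 0.5e6))
})

test_that("relative payoffs equal pairwise differences of the totals", {
  params <- printed_params()
  states <- rbind(random_simplex_states(20, seed = 53), c(0.3, 0.3, 0.4))
  for (i in seq_len(nrow(states))) {
    s <- as_state(states[i, ])
    rel <- relative_payoffs(params, s)
    tot <- total_payoffs(params, s)
    scale <- max(abs(c(tot$r1, tot$r2, tot$r3, 1)))
    expect_lt(abs(rel$rhat1 - (tot$r1 - tot$r2)) / scale, 1e-6)
    expect_lt(abs(rel$rhat3 - (tot$r3 - tot$r2)) / scale, 1e-6)
    expect_identical(rel$rhat2, 0)
    expect_equal(rel$rbar, s[[1]] * rel$rhat1 + s[[3]] * rel$rhat3)
  }
  expect_equal(relative_payoffs(params, simplex_vertex("e2"))$rbar, 0)
})
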