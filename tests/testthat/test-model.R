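test_that("one-day update matches the direct two-line arithmetic", {
  # degenerate maps
  zero <- model_params(0, 0, 0, 0, 0, 0)
  expect_equal(step_day(zero, 5, 3, 7), c(A = 0, D = 0))
  pers <- model_params(0, 1, 0, 0, 0, 0)
  expect_equal(step_day(pers, 5, 3, 7), c(A = 5, D = 0))

  # population parameters at the reference median initial state
  expected_D <- pop[["d1"]] * 4 + pop[["d2"]] * 7 + pop[["d3"]] * (4 - 8.4)
  expected_A <- pop[["a1"]] * (expected_D - 7) + pop[["a2"]] * 4 +
    pop[["a3"]] * (4 - 8.4)
  s <- step_day(pop, A_prev = 4, A_prev2 = 8.4, D_prev = 7)
  expect_equal(s[["A"]], expected_A, tolerance = 1e-12)
  expect_equal(s[["D"]], expected_D, tolerance = 1e-12)
  # the same update rounded to 4 decimals is the reference value pair
  expect_equal(round(s[["A"]], 4), 5.7998)
  expect_equal(round(s[["D"]], 4), 6.3814)

  expect_error(step_day(pop, Inf, 3, 7), "finite")
  expect_error(model_params(-0.1, 1, 0, 1, 0.5, 0), "nonnegative")
})

test_that("desire is computed before alcohol (same-day coupling order)", {
  set.seed(7)
  for (k in 1:50) {
    p <- c(a1 = runif(1), a2 = runif(1), a3 = rnorm(1),
           d1 = runif(1), d2 = runif(1), d3 = rnorm(1))
    st <- runif(3, 0, 10)
    expect_equal(step_day(p, st[1], st[2], st[3]),
                 oracle_step(p, st[1], st[2], st[3]), tolerance = 1e-12)
  }
  # an A-first evaluation (using yesterday's desire change) must disagree
  # whenever a1 couples to a changing desire
  p <- model_params(0.5, 0.9, 0, 0.8, 0.4, 0)
  a_first_A <- p[["a2"]] * 4  # a1 * 0 if stale desire change were used
  expect_false(isTRUE(all.equal(step_day(p, 4, 4, 7)[["A"]], a_first_A)))
})

test_that("simulate iterates the update from the three initial conditions", {
  zero <- model_params(0, 0, 0, 0, 0, 0)
  tr <- simulate_trajectory(zero, median_ics, horizon = 5)
  expect_equal(tr$A, c(4, 0, 0, 0, 0))
  expect_equal(tr$D, c(7, 0, 0, 0, 0))

  # two hand iterations at population parameters
  tr <- simulate_trajectory(pop, median_ics, horizon = 3)
  d2v <- oracle_step(pop, 4, 8.4, 7)
  d3v <- oracle_step(pop, d2v[["A"]], 4, d2v[["D"]])
  expect_equal(tr$A[2:3], c(d2v[["A"]], d3v[["A"]]), tolerance = 1e-12)
  expect_equal(tr$D[2:3], c(d2v[["D"]], d3v[["D"]]), tolerance = 1e-12)

  expect_error(simulate_trajectory(pop, median_ics, horizon = 1),
               "horizon")
})

test_that("constant-drinking regime drives desire geometrically to its limit", {
  # a2 = 1 with no other alcohol couplings keeps A at A1; desire approaches
  # d1*A1/(1-d2) with exact geometric decay of the gap
  p <- model_params(0, 1, 0, d1 = 0.8, d2 = 0.6, 0)
  ics <- initial_conditions(A0 = 4, A1 = 4, D1 = 1)
  tr <- simulate_trajectory(p, ics, horizon = 60)
  expect_true(all(abs(tr$A - 4) < 1e-12))
  lim <- 0.8 * 4 / (1 - 0.6)
  gap <- tr$D - lim
  expect_equal(gap[2:60], gap[1] * 0.6^(1:59), tolerance = 1e-10)
  expect_true(all(diff(tr$D) > 0))  # monotone approach from below
})

test_that("simulation is linear in initial conditions and fixes the origin", {
  set.seed(11)
  for (k in 1:20) {
    p <- c(a1 = runif(1), a2 = runif(1, 0, 1.1), a3 = rnorm(1, 0, 0.5),
           d1 = runif(1), d2 = runif(1), d3 = rnorm(1, 0, 0.3))
    ics <- c(A0 = runif(1, 0, 10), A1 = runif(1, 0, 10), D1 = runif(1, 0, 12))
    t1 <- simulate_trajectory(p, ics, 40)
    t2 <- simulate_trajectory(p, 2.5 * ics, 40)
    expect_equal(t2$A, 2.5 * t1$A, tolerance = 1e-9)
    expect_equal(t2$D, 2.5 * t1$D, tolerance = 1e-9)
  }
  t0 <- simulate_trajectory(pop, c(A0 = 0, A1 = 0, D1 = 0), 50)
  expect_true(all(t0$A == 0) && all(t0$D == 0))
})

test_that("non-negativity clipping floors every state at zero", {
  set.seed(13)
  for (k in 1:20) {
    p <- c(a1 = runif(1), a2 = runif(1, 0, 1.2), a3 = rnorm(1),
           d1 = runif(1), d2 = runif(1), d3 = rnorm(1))
    ics <- c(A0 = runif(1, 0, 10), A1 = runif(1, 0, 10), D1 = runif(1, 0, 12))
    tr <- simulate_trajectory(p, ics, 60, clip_nonneg = TRUE)
    expect_true(all(tr$A >= 0) && all(tr$D >= 0))
    # and matches an independent clipped iteration
    or <- oracle_traj(p, ics, 60, clip = TRUE)
    expect_equal(tr$A, or$A, tolerance = 1e-12)
    expect_equal(tr$D, or$D, tolerance = 1e-12)
  }
})

test_that("equilibrium classification distinguishes E0, E1, E2", {
  r <- classify_equilibrium(model_params(0.3, 0.5, 0, 0.8, 0.5, 0))
  expect_equal(r$kind, "none-of-special-cases")
  expect_equal(c(r$Astar, r$Dstar), c(0, 0))

  r <- classify_equilibrium(model_params(0.3, 0.5, 0, 0.8, 1, 0))
  expect_equal(r$kind, "E1-line")

  p <- subject_params("1677")
  p[["a2"]] <- 1
  r <- classify_equilibrium(p, Astar = 2.6)
  expect_equal(r$kind, "E2-line")
  expect_equal(r$Dstar, 0.8144 * 2.6 / (1 - 0.7055), tolerance = 1e-12)
  expect_equal(round(r$Dstar, 2), 7.19)
})

test_that("companion matrix reproduces the one-step state transition", {
  set.seed(17)
  for (k in 1:20) {
    p <- c(a1 = runif(1), a2 = runif(1), a3 = rnorm(1),
           d1 = runif(1), d2 = runif(1, 0, 0.9), d3 = rnorm(1))
    ics <- c(A0 = runif(1, 0, 8), A1 = runif(1, 0, 8), D1 = runif(1, 0, 12))
    tr <- simulate_trajectory(p, ics, 4)
    M <- companion_matrix(p)
    x1 <- c(tr$A[1], ics[["A0"]], tr$D[1])
    x2 <- M %*% x1
    expect_equal(as.numeric(x2), c(tr$A[2], tr$A[1], tr$D[2]),
                 tolerance = 1e-12)
    x3 <- M %*% x2
    expect_equal(as.numeric(x3), c(tr$A[3], tr$A[2], tr$D[3]),
                 tolerance = 1e-12)
  }
})

test_that("qualitative behavior labels match the dynamics", {
  zero <- model_params(0, 0, 0, 0, 0, 0)
  expect_equal(classify_behavior(zero, median_ics, 50)$label, "constant")

  grow <- model_params(0, 1.05, 0, 0, 0, 0)
  b <- classify_behavior(grow, initial_conditions(4, 4, 0), 80)
  expect_equal(b$label, "growing")
  expect_equal(b$rho, 1.05, tolerance = 1e-9)

  b <- classify_behavior(pop, median_ics, 100)
  expect_equal(b$label, "damped-oscillatory")
  # cross-check the dominant modulus against a direct eigendecomposition
  rho_oracle <- max(Mod(eigen(companion_matrix(pop))$values))
  expect_equal(b$rho, rho_oracle, tolerance = 1e-12)
  expect_lt(b$rho, 1)

  decay <- model_params(0, 0.9, 0, 0, 0, 0)
  expect_equal(classify_behavior(decay, initial_conditions(4, 4, 0), 60)$label,
               "monotone-decreasing")
  expect_error(classify_behavior(pop, median_ics, 5), "horizon")
})
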