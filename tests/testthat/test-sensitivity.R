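test_that("default sampling ranges apply the floors and stated maxima", {
  rng <- default_ranges()
  gr <- function(k) unlist(rng[rng$input == k, c("lower", "upper")],
                           use.names = FALSE)
  expect_equal(gr("a1"), c(0.001, 1.0015))
  expect_equal(gr("d1"), c(0.001, 2.2742))
  # d2: mean 0.4110, sd 0.2168; lower floored at 0.001
  expect_equal(gr("d2"), c(0.001, 0.4110 + 2 * 0.2168))
  expect_equal(gr("a3"), c(-0.4539 - 2 * 0.4475, -0.4539 + 2 * 0.4475))
  # A0's mean - 2 sd is negative, so the lower bound floors at 0.001
  expect_equal(gr("A0"), c(0.001, 9.4622 + 2 * 5.9181))
  expect_equal(gr("A1")[1], 0.001)   # floored (mean - 2 sd < 0)

  # a zero-sd input without an override collapses its range
  sp <- data.frame(parameter = names(population_params()),
                   mean = unname(population_params()),
                   sd = param_spread()$sd)
  sp$sd[sp$parameter == "a3"] <- 0
  expect_error(default_ranges(sp), "degenerate")
})

test_that("latin hypercube designs stratify every column exactly", {
  rng <- default_ranges()
  for (seed in c(1, 2, 3)) {
    n <- 50
    d <- lhs_design(rng, n, seed = seed)
    expect_equal(dim(d), c(n, 9L))
    for (j in seq_len(ncol(d))) {
      lo <- rng$lower[j]; hi <- rng$upper[j]
      stratum <- floor((d[, j] - lo) / (hi - lo) * n)
      expect_setequal(stratum, 0:(n - 1))  # exactly one point per stratum
    }
  }
  # two samples: one in each half-range
  d2 <- lhs_design(rng, 2, seed = 9)
  mid <- (rng$lower + rng$upper) / 2
  for (j in 1:9) expect_equal(sum(d2[, j] < mid[j]), 1)

  # column marginals are uniform (KS statistic below the 5% critical value)
  n <- 1000
  for (seed in c(11, 12)) {
    d <- lhs_design(rng, n, seed = seed)
    for (j in c(1, 5, 9)) {
      u <- (d[, j] - rng$lower[j]) / (rng$upper[j] - rng$lower[j])
      ks <- suppressWarnings(stats::ks.test(u, "punif"))
      expect_lt(unname(ks$statistic), 1.358 / sqrt(n))
    }
  }
  expect_error(lhs_design(rng, 1), "n_samples")
})

test_that("output measures match closed forms and honor clipping", {
  inputs <- c("a1", "a2", "a3", "d1", "d2", "d3", "A0", "A1", "D1")
  zero_row <- matrix(0, 1, 9, dimnames = list(NULL, inputs))
  out <- evaluate_outputs(zero_row, horizon = 84)
  expect_equal(unlist(out), c(sumA = 0, sumD = 0, maxA = 0, maxD = 0))

  # geometric alcohol decay with no desire coupling: closed-form geometric sum
  g_row <- zero_row
  g_row[, "a2"] <- 0.9; g_row[, "A0"] <- 5; g_row[, "A1"] <- 5
  out <- evaluate_outputs(g_row, horizon = 50)
  expect_equal(out$sumA, 5 * (1 - 0.9^50) / (1 - 0.9), tolerance = 1e-10)
  expect_equal(out$maxA, 5)

  # constant-drinking regime: sumA = c * horizon
  c_row <- zero_row
  c_row[, "a2"] <- 1; c_row[, "A0"] <- 3; c_row[, "A1"] <- 3
  out <- evaluate_outputs(c_row, horizon = 84)
  expect_equal(out$sumA, 3 * 84)

  # a regime that would go negative is evaluated on the clipped path
  n_row <- zero_row
  n_row[, "a2"] <- 0.5; n_row[, "a3"] <- -3
  n_row[, "A0"] <- 1; n_row[, "A1"] <- 8; n_row[, "D1"] <- 2
  out <- evaluate_outputs(n_row, horizon = 30)
  p <- c(a1 = 0, a2 = 0.5, a3 = -3, d1 = 0, d2 = 0, d3 = 0)
  or <- oracle_traj(p, c(A0 = 1, A1 = 8, D1 = 2), 30, clip = TRUE)
  expect_equal(out$sumA, sum(or$A), tolerance = 1e-10)
  expect_true(all(unlist(out) >= 0))
})

test_that("PRCC attains its limits and is rank-invariant", {
  set.seed(101)
  rng <- default_ranges()
  d <- lhs_design(rng, 300, seed = 5)
  g <- prcc(d, d[, "a1"])
  expect_gt(g[["a1"]], 0.999)
  g <- prcc(d, -d[, "d2"])
  expect_lt(g[["d2"]], -0.999)

  # invariance under strictly monotone transforms of output and inputs
  y <- d[, "a1"] + 0.5 * d[, "d2"] + rnorm(300, 0, 0.1)
  g1 <- prcc(d, y)
  g2 <- prcc(d, exp(2 * y))
  expect_equal(g1, g2, tolerance = 1e-12)
  d3 <- d
  d3[, "a1"] <- log(d3[, "a1"])  # strictly monotone on its positive range
  expect_equal(prcc(d3, y), g1, tolerance = 1e-12)

  # constant column is flagged
  dc <- d
  dc[, "a3"] <- 1
  expect_warning(gc <- prcc(dc, y), "constant")
  expect_true(is.na(gc[["a3"]]))
  expect_error(prcc(d[1:5, ], y[1:5]), "n_samples")
})

test_that("PRCC significance is a two-sided monotone t reference", {
  g <- c(x = 0, y = 0.3, z = -0.6, w = 0.99)
  s <- prcc_significance(g, n_samples = 200, n_conditioned = 8)
  expect_equal(s$p_value[s$input == "x"], 1)
  expect_true(all(diff(s$p_value[match(c("x", "y", "z", "w"), s$input)]) < 0))
  sd1 <- prcc_significance(c(q = 1), 200, 8)
  expect_equal(sd1$p_value, 0)
  expect_true(sd1$degenerate)
  # closed-form check of the transform at one value
  tt <- 0.3 * sqrt((200 - 2 - 8) / (1 - 0.09))
  expect_equal(s$statistic[s$input == "y"], tt, tolerance = 1e-12)
  expect_equal(s$p_value[s$input == "y"], 2 * pt(-tt, df = 190),
               tolerance = 1e-12)
})

test_that("single-input sweeps detect monotone and flat responses", {
  inputs <- c("a1", "a2", "a3", "d1", "d2", "d3", "A0", "A1", "D1")
  base <- setNames(numeric(9), inputs)
  base["A0"] <- 5; base["A1"] <- 5

  sw <- monotonicity_sweep(base, "a2", range = c(0.1, 0.95), n_grid = 10,
                           horizon = 40)
  expect_true(sw$monotone[["sumA"]])
  expect_true(all(diff(sw$curve$sumA) > 0))
  # closed form at each grid point: geometric sum
  expect_equal(sw$curve$sumA,
               5 * (1 - sw$curve$a2^40) / (1 - sw$curve$a2), tolerance = 1e-8)

  # zero-leverage sweep is flat (constant-A regime, A0 = A1)
  base2 <- base; base2["a2"] <- 1
  sw2 <- monotonicity_sweep(base2, "a3", range = c(-1, 1), n_grid = 7,
                            horizon = 40)
  expect_true(all(abs(diff(sw2$curve$sumA)) < 1e-10))
  expect_true(all(sw2$monotone))

  # population baseline: the d2 response is concentrated in the upper range
  pop_base <- c(population_params(),
                c(A0 = 8.4, A1 = 4, D1 = 7))
  sw3 <- monotonicity_sweep(pop_base, "d2", n_grid = 25, horizon = 84)
  y <- sw3$curve$sumA
  x <- sw3$curve$d2
  base_val <- y[which.min(abs(x - 0.411))]
  expect_gt(max(y), 2 * base_val)              # drastic change overall
  low <- max(abs(diff(y[x < 0.45]))) / diff(x)[1]
  high <- max(abs(diff(y[x > 0.7]))) / diff(x)[1]
  expect_gt(high, 10 * low)                    # steepness lives up high
  expect_error(monotonicity_sweep(pop_base, "d2", n_grid = 2), "n_grid")
})

test_that("PRCC conclusions are stable across the two horizons", {
  rng <- default_ranges()
  d <- lhs_design(rng, 400, seed = 17)
  o84 <- evaluate_outputs(d, 84)
  o365 <- evaluate_outputs(d, 365)
  g84 <- prcc(d, o84$sumA)
  g365 <- prcc(d, o365$sumA)
  strong <- abs(g84) > 0.3
  expect_true(any(strong))
  expect_equal(sign(g84[strong]), sign(g365[strong]))
})
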