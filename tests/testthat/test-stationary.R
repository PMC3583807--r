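test_that("stationary frequency solves the equilibrium condition", {
  # full symmetry
  expect_equal(stationary_freq(rate_set(.1, .1, .03, .03, .01, .01))$x_hat, 0.5)
  # asymmetric character change, g = 0: closed form q10/(q01+q10)
  s <- stationary_freq(rate_set(.1, .1, .03, .03, .015, .005))
  expect_equal(s$x_hat, 0.25)
  expect_identical(s$tip_ratio, "3:1")
  # speciation asymmetry 1.25x: exact quadratic root; the displayed tip
  # ratio rounds to 3:1 even though the frequency is 0.2597
  s2 <- stationary_freq(rate_set(.1, .125, .03, .03, .01, .01))
  expect_equal(s2$x_hat, (0.045 - sqrt(0.001025)) / 0.05, tolerance = 1e-10)
  expect_identical(s2$tip_ratio, "3:1")
  # extinction asymmetry 2x: exact quadratic root (5 - sqrt(13)) / 6,
  # frozen from bisection of the equilibrium condition on [0, 1]
  s3 <- stationary_freq(rate_set(.1, .1, .06, .03, .01, .01))
  expect_equal(s3$x_hat, (5 - sqrt(13)) / 6, tolerance = 1e-12)
})

test_that("stationary frequency satisfies residual and symmetry invariants", {
  set.seed(42)
  for (i in 1:50) {
    r <- random_rates()
    s <- stationary_freq(r)
    expect_lt(abs(s$residual), 1e-10)
    expect_gte(s$x_hat, 0)
    expect_lte(s$x_hat, 1)
    # swapping state labels mirrors the frequency
    expect_equal(stationary_freq(swap_states(r))$x_hat, 1 - s$x_hat,
                 tolerance = 1e-9)
  }
})

test_that("stationary frequency rejects undefined and invalid input", {
  expect_error(stationary_freq(rate_set(.1, .1, .03, .03, 0, 0)),
               "undefined")
  expect_error(as_rate_set(c(lambda0 = -0.1, lambda1 = .1, mu0 = .03,
                             mu1 = .03, q01 = .01, q10 = .01)),
               "non-negative")
  expect_error(rate_set(0, 0, .03, .03, .01, .01), "speciation")
})

test_that("rate-ratio solver hits the target frequency and known ratios", {
  base <- rate_set(0.1, 0.1, 0.05, 0.05, 0.005, 0.005)
  # character change with everything else symmetric is analytic
  sol <- solve_rate_ratio("character_change", base, 0.25)
  expect_equal(sol$ratio, 3.0)
  expect_equal(sol$rates[["q01"]], 3 * sol$rates[["q10"]])
  # geometric placement around the base
  sp <- solve_rate_ratio("speciation", base, 0.25)
  expect_equal(sp$rates[["lambda0"]] * sp$rates[["lambda1"]], 0.1^2,
               tolerance = 1e-10)
  expect_equal(sp$rates[["lambda1"]] / sp$rates[["lambda0"]], sp$ratio,
               tolerance = 1e-8)
  # symmetric target is the identity
  expect_equal(solve_rate_ratio("extinction", base, 0.5)$ratio, 1.0)
  # direction convention: target > 0.5 favours state 0
  sol0 <- solve_rate_ratio("speciation", base, 0.75)
  expect_gt(sol0$rates[["lambda0"]], sol0$rates[["lambda1"]])
  expect_equal(stationary_freq(sol0$rates)$x_hat, 0.75, tolerance = 1e-8)
})

test_that("rate-ratio solver round-trips over random bases and targets", {
  set.seed(7)
  procs <- c("speciation", "extinction", "character_change")
  for (i in 1:100) {
    l <- stats::runif(1, 0.05, 0.3)
    m <- stats::runif(1, 0.01, 0.08)
    q <- stats::runif(1, 0.002, 0.05)
    base <- rate_set(l, l, m, m, q, q)
    target <- stats::runif(1, 0.05, 0.95)
    p <- sample(procs, 1)
    sol <- solve_rate_ratio(p, base, target)
    expect_equal(stationary_freq(sol$rates)$x_hat, target, tolerance = 1e-8)
    expect_gte(sol$ratio, 1 - 1e-12)
  }
})
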