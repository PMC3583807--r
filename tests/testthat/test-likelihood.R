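test_that("branch integration matches closed forms", {
  # pure extinction: E0(t) = 1 - exp(-mu t)
  r <- c(lambda0 = 0, lambda1 = 0, mu0 = 0.03, mu1 = 0.03, q01 = 0, q10 = 0)
  y <- branch_integrate(c(0, 0, 1, 1), r, 10)
  expect_equal(y[1], 1 - exp(-0.3), tolerance = 1e-9)
  expect_equal(y[2], 1 - exp(-0.3), tolerance = 1e-9)
  # pure speciation decay of the partial likelihood: D0(t) = exp(-lambda t)
  r2 <- c(lambda0 = 0.1, lambda1 = 0, mu0 = 0, mu1 = 0, q01 = 0, q10 = 0)
  y2 <- branch_integrate(c(0, 0, 1, 0), r2, 1)
  expect_equal(y2[3], exp(-0.1), tolerance = 1e-9)
  # constant-rate birth-death extinction probability
  lambda <- 0.1; mu <- 0.03
  E_bd <- function(t) mu * (exp((lambda - mu) * t) - 1) /
    (lambda * exp((lambda - mu) * t) - mu)
  r3 <- c(lambda0 = lambda, lambda1 = lambda, mu0 = mu, mu1 = mu,
          q01 = 0.01, q10 = 0.01)
  for (t in c(1, 5, 20)) {
    y3 <- branch_integrate(c(0, 0, 1, 0), r3, t)
    expect_equal(y3[1], E_bd(t), tolerance = 1e-6)
    expect_equal(y3[2], E_bd(t), tolerance = 1e-6)
  }
  # zero length is the identity
  expect_identical(branch_integrate(c(.1, .2, .3, .4), r3, 0),
                   c(.1, .2, .3, .4))
})

test_that("a two-tip cherry reproduces the closed-form likelihood", {
  phy <- ape::read.tree(text = "(t1:1,t2:1);")
  d <- bisse_data(phy, c(t1 = 0, t2 = 0))
  r <- as_rate_set(c(lambda0 = .1, lambda1 = .1, mu0 = 0, mu1 = 0,
                     q01 = 0, q10 = 0))
  ll <- bisse_loglik(d, r, root = root_mode("given", weights = c(1, 0)))
  expect_equal(ll, log(0.1) - 0.2, tolerance = 1e-8)
})

test_that("likelihood is invariant under a full state relabelling", {
  set.seed(9)
  r <- as_rate_set(c(lambda0 = .1, lambda1 = .15, mu0 = .02, mu1 = .05,
                     q01 = .02, q10 = .01))
  d <- random_tree_data(30, r)
  flipped <- bisse_data(d$phy, stats::setNames(1L - d$tip_state,
                                               names(d$tip_state)))
  ll <- bisse_loglik(d, r)
  ll_sw <- bisse_loglik(flipped, swap_states(r))
  expect_equal(ll, ll_sw, tolerance = 1e-8)
})

test_that("rate/time rescaling shifts the log-likelihood by (n-1) log c", {
  set.seed(10)
  r <- random_rates()
  d <- random_tree_data(12, r)
  ll <- bisse_loglik(d, r)
  n <- length(d$phy$tip.label)
  for (cc in c(0.5, 2)) {
    d2 <- d
    d2$phy$edge.length <- d$phy$edge.length / cc
    r2 <- as_rate_set(unclass(r) * cc)
    expect_equal(bisse_loglik(d2, r2), ll + (n - 1) * log(cc),
                 tolerance = 1e-6)
  }
})

test_that("adaptive integration agrees with the fine-step RK4 oracle", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(4:16, 1)
    d <- random_tree_data(n)
    r <- random_rates()
    x <- stationary_freq(r)$x_hat
    w <- c(x, 1 - x)
    mine <- bisse_loglik(d, r, root = root_mode("given", weights = w))
    orac <- oracle_loglik(d, r, w)
    expect_equal(mine, orac, tolerance = 1e-5)
  }
})

test_that("extinction probabilities stay in [0,1] along branches", {
  set.seed(12)
  for (i in 1:10) {
    r <- random_rates()
    y <- branch_integrate(c(0, 0, 1, 0), unclass(r), 50)
    expect_true(all(y[1:2] >= 0 & y[1:2] <= 1))
    expect_true(all(y[3:4] >= 0))
  }
})

test_that("root handling is validated", {
  d <- bisse_data(ape::read.tree(text = "((t1:1,t2:1):1,t3:2);"),
                  c(t1 = 0, t2 = 1, t3 = 0))
  r0 <- as_rate_set(c(lambda0 = .1, lambda1 = .1, mu0 = 0, mu1 = 0,
                      q01 = 0, q10 = 0))
  expect_error(bisse_loglik(d, r0), "explicit root mode")
  expect_silent(bisse_loglik(d, r0, root = root_mode("equal")))
  expect_error(root_mode("given", weights = c(0.7, 0.6)), "summing to 1")
  # fixed-root weighting bounds the mixture
  r <- rate_set(.1, .12, .02, .03, .02, .01)
  l0 <- bisse_loglik(d, r, root = root_mode("fixed0"))
  l1 <- bisse_loglik(d, r, root = root_mode("fixed1"))
  le <- bisse_loglik(d, r, root = root_mode("equal"))
  expect_gte(le, min(l0, l1) - 1e-9)
  expect_lte(le, max(l0, l1) + 1e-9)
})

test_that("extinction probability grows rootward when extinction operates", {
  set.seed(15)
  r <- unclass(random_rates())
  r[["mu0"]] <- max(r[["mu0"]], 0.02); r[["mu1"]] <- max(r[["mu1"]], 0.02)
  ts <- c(0.5, 1, 2, 5, 10, 20)
  E0 <- vapply(ts, function(t) branch_integrate(c(0, 0, 1, 0), r, t)[1],
               numeric(1))
  expect_true(all(diff(E0) > 0))
})
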