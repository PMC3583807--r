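test_that("Brent minimization solves smooth and non-smooth 1-D problems", {
  q <- brent_minimize(function(x) (x - 2)^2, 0, 5, tol = 1e-9)
  expect_equal(q$argmin, 2.0, tolerance = 1e-6)
  a <- brent_minimize(function(x) abs(x - 1), 0, 3, tol = 1e-9)
  expect_equal(a$argmin, 1.0, tolerance = 1e-6)
  expect_error(brent_minimize(function(x) NA_real_, 0, 1),
               "non-finite objective")
})

test_that("a Brent profile slice matches a dense grid scan", {
  set.seed(41)
  truth <- rate_set(.1, .1, .03, .03, .01, .01)
  d <- random_tree_data(100, truth)
  slice <- function(l0) {
    r <- unclass(truth); r[["lambda0"]] <- l0
    -bisse_loglik(d, as_rate_set(r))
  }
  grid <- exp(seq(log(0.01), log(1), length.out = 2000))
  vals <- vapply(grid, slice, numeric(1))
  g_best <- grid[which.min(vals)]
  b <- brent_minimize(function(x) slice(exp(x)), log(0.01), log(1),
                      tol = 1e-6)
  cell <- diff(log(grid[1:2]))
  expect_lt(abs(b$argmin - log(g_best)), 2 * cell)
})

test_that("three-parameter fit attains the exhaustive grid-search optimum", {
  set.seed(55)
  truth <- rate_set(.1, .1, .03, .03, .02, .02)
  d <- random_tree_data(8, truth)
  fit <- bisse_fit(d, pattern = "l=,m=,q=", warm_chain = FALSE, seed = 2)
  lg <- expand.grid(l = exp(seq(log(0.005), log(1), length.out = 30)),
                    m = exp(seq(log(1e-4), log(0.5), length.out = 30)),
                    q = exp(seq(log(1e-3), log(1), length.out = 30)))
  frame_ll <- function(l, m, q)
    tryCatch(bisse_loglik(d, as_rate_set(c(lambda0 = l, lambda1 = l,
                                           mu0 = m, mu1 = m,
                                           q01 = q, q10 = q))),
             error = function(e) -Inf)
  grid_best <- max(mapply(frame_ll, lg$l, lg$m, lg$q))
  expect_gte(fit$loglik, grid_best - 1e-3)
})

test_that("nested fits respect the likelihood ordering and warm starts", {
  set.seed(77)
  d <- random_tree_data(60, rate_set(.1, .15, .03, .03, .01, .01))
  ctl <- lean_control()
  f3 <- bisse_fit(d, "l=,m=,q=", control = ctl, warm_chain = FALSE, seed = 4)
  f5 <- bisse_fit(d, "l=,m0,m1,q0,q1", control = ctl, warm_start = f3,
                  seed = 4)
  f6 <- bisse_fit(d, "l0,l1,m0,m1,q0,q1", control = ctl, warm_start = f5,
                  seed = 4)
  expect_gte(f5$loglik, f3$loglik - 1e-6)
  expect_gte(f6$loglik, f5$loglik - 1e-6)
  # a warm-started fit never ends below its warm start
  expect_gte(f6$loglik, f5$loglik - 1e-9)
  # the stored log-likelihood re-evaluates to the same value
  expect_equal(f6$loglik, bisse_loglik(d, f6$rates, cfg = f6$cfg),
               tolerance = 1e-9)
})

test_that("fits are deterministic given the seed", {
  set.seed(88)
  d <- random_tree_data(25, rate_set(.1, .1, .03, .03, .02, .02))
  f1 <- bisse_fit(d, "l=,m=,q=", control = lean_control(), seed = 11,
                  warm_chain = FALSE)
  f2 <- bisse_fit(d, "l=,m=,q=", control = lean_control(), seed = 11,
                  warm_chain = FALSE)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$all_start_logliks, f2$all_start_logliks)
})

test_that("monomorphic tip states warn and flag boundary behaviour", {
  set.seed(66)
  r <- as_rate_set(c(lambda0 = .1, lambda1 = .1, mu0 = 0, mu1 = 0,
                     q01 = 1e-4, q10 = 1e-4))
  d <- prune_extinct(sim_bisse(r, 12, root_state = "fixed0"))
  d <- bisse_data(d$phy, stats::setNames(rep(0L, 12), names(d$tip_state)))
  expect_warning(fit <- bisse_fit(d, "l=,m=,q=", control = lean_control(),
                                  warm_chain = FALSE, seed = 3),
                 "monomorphic")
  expect_true(fit$monomorphic)
})

test_that("fit objects carry the standard modelling interface", {
  set.seed(14)
  d <- random_tree_data(20, rate_set(.1, .1, .03, .03, .02, .02))
  fit <- bisse_fit(d, "l=,m=,q=", control = lean_control(),
                   warm_chain = FALSE, seed = 5)
  expect_s3_class(fit, "bisse_fit")
  expect_named(coef(fit), c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10"))
  expect_length(coef(fit, expand = FALSE), 3L)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 3L)
  expect_output(print(fit), "3-parameter ML fit")
  expect_output(print(summary(fit)), "AIC")
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "bisse_data")
  expect_equal(length(sims[[1]]$tip_state), 20L)
})
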