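test_that("the LRT statistic is non-negative and zero for identical models", {
  set.seed(19)
  d <- random_tree_data(20, rate_set(.1, .1, .03, .03, .02, .02))
  lrt <- bisse_lrt(d, "l=,m=,q=", "l=,m=,q=", control = lean_control(),
                   seed = 2)
  expect_equal(lrt$stat, 0, tolerance = 1e-6)
  expect_gte(lrt$stat, 0)
  expect_error(bisse_lrt(d, "l=,m0,m1,q0,q1", "l0,l1,m=,q="),
               "does not nest")
})

test_that("the chi-square reference cutoff is exposed", {
  expect_equal(chisq_critical_value(0.05, 1), stats::qchisq(0.95, 1))
  expect_equal(round(chisq_critical_value(), 3), 3.841)
})

test_that("null distributions store the empirical quantile they advertise", {
  set.seed(23)
  sc <- scenario(rate_set(.1, .1, .03, .03, .02, .02), n_tips = 25,
                 n_reps = 8, label = "null", seed = 31)
  nd <- build_null_distribution(sc, "speciation", "6v5",
                                control = lean_control(), cfg = lean_cfg())
  expect_equal(nd$critical_value,
               unname(stats::quantile(nd$stats, 0.95, type = 7)))
  expect_equal(nd$n_reps, 8L)
  expect_false(is.unsorted(nd$stats))
  expect_true(all(nd$stats >= 0))
  # asymmetric rates are rejected as a null
  expect_error(
    build_null_distribution(scenario(rate_set(.1, .2, .03, .03, .01, .01),
                                     25, 4), "speciation"),
    "symmetric")
})

test_that("power estimation enforces matched tree sizes and reports a CI", {
  set.seed(29)
  sc_null <- scenario(rate_set(.1, .1, .03, .03, .02, .02), n_tips = 25,
                      n_reps = 6, seed = 41, label = "null")
  nd <- build_null_distribution(sc_null, "speciation", "6v5",
                                control = lean_control(), cfg = lean_cfg())
  sc_alt <- scenario(rate_set(.1, .2, .03, .03, .02, .02), n_tips = 30,
                     n_reps = 6, seed = 42, label = "alt")
  expect_error(estimate_power(sc_alt, nd), "mismatch")
  sc_alt$n_tips <- 25L
  pw <- estimate_power(sc_alt, nd, control = lean_control(),
                       cfg = lean_cfg())
  expect_gte(pw$power, 0)
  expect_lte(pw$power, 1)
  expect_equal(pw$ci_halfwidth,
               1.96 * sqrt(pw$power * (1 - pw$power) / pw$n_reps))
  expect_equal(pw$n_reps, 6L)
})

test_that("the power grid driver reduces to its parts", {
  empty <- run_power_grid(list(), character(0))
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("label", "power", "critical_value", "mean_frac_state0")
                  %in% names(empty)))
  set.seed(37)
  sc <- scenario(rate_set(.1, .2, .03, .03, .02, .02), n_tips = 25,
                 n_reps = 5, label = "spec 2x", seed = 51)
  grid <- run_power_grid(list(sc), "speciation", tree_sizes = 25,
                         pairs = "6v5", control = lean_control(),
                         cfg = lean_cfg())
  expect_equal(nrow(grid), 1L)
  expect_equal(grid$n_tips, 25)
  expect_equal(grid$n_reps, 5)
  expect_gte(grid$power, 0)
  expect_lte(grid$power, 1)
})

test_that("the power grid resumes from a checkpoint without recomputing", {
  sc <- scenario(rate_set(.1, .2, .03, .03, .02, .02), n_tips = 25,
                 n_reps = 5, label = "spec 2x", seed = 51)
  ck <- tempfile(fileext = ".csv")
  done <- data.frame(label = "spec 2x", process = "speciation", n_tips = 25,
                     pair = "6v5", n_reps = 5, critical_value = 2.5,
                     power = 0.4, ci_halfwidth = 0.1,
                     mean_frac_state0 = 0.2, redrawn = 0)
  utils::write.table(done, ck, sep = ",", quote = FALSE, row.names = FALSE)
  t0 <- Sys.time()
  grid <- run_power_grid(list(sc), "speciation", tree_sizes = 25,
                         pairs = "6v5", checkpoint = ck)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 2)
  expect_equal(grid$power, 0.4)
  expect_equal(grid$critical_value, 2.5)
})
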