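test_that("pure-birth simulation yields the expected degenerate tree", {
  set.seed(1)
  s <- sim_bisse(as_rate_set(c(lambda0 = 0.1, lambda1 = 0, mu0 = 0, mu1 = 0,
                               q01 = 0, q10 = 0)),
                 n_tips = 4, root_state = "fixed0")
  expect_equal(s$n_extant, 4L)
  expect_false(any(s$status == "extinct"))
  d <- prune_extinct(s)
  expect_equal(length(d$phy$tip.label), 4L)
  expect_true(all(d$tip_state == 0L))
  # no extinction: pruning only removes the stem, so node count is intact
  expect_equal(d$phy$Nnode, 3L)
})

test_that("pruned trees are ultrametric with exactly the target tip count", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(5:60, 1)
    d <- random_tree_data(n)
    expect_equal(length(d$phy$tip.label), n)
    depths <- ape::node.depth.edgelength(d$phy)
    tip_depths <- depths[seq_len(n)]
    expect_lt(diff(range(tip_depths)) / max(tip_depths), 1e-9)
    expect_true(all(d$tip_state %in% 0:1))
  }
})

test_that("hand-built simulation with one extinct tip prunes to the correct cherry", {
  # root lineage 1 speciates at t=1 into 2 and 3; 2 speciates at t=2 into
  # 4 and 5; 4 goes extinct at t=2.5; 3 and 5 survive to t=3
  sim <- structure(list(parent = c(0L, 1L, 1L, 2L, 2L),
                        birth = c(0, 1, 1, 2, 2),
                        end = c(1, 2, 3, 2.5, 3),
                        state = c(0L, 0L, 1L, 0L, 0L),
                        status = c("speciated", "speciated", "alive",
                                   "extinct", "alive"),
                        time = 3, n_extant = 2L),
                   class = "sim_bisse_tree")
  d <- prune_extinct(sim)
  expect_equal(length(d$phy$tip.label), 2L)
  # crown root sits at the first speciation (t=1): both tips at depth 2,
  # the suppressed degree-2 node's branches summed
  depths <- ape::node.depth.edgelength(d$phy)
  expect_equal(sort(depths), c(0, 2, 2))
  expect_setequal(as.integer(d$tip_state), c(0L, 1L))
  expect_true(ape::is.ultrametric(d$phy))
})

test_that("pruning requires at least two surviving tips", {
  sim <- structure(list(parent = 0L, birth = 0, end = 1, state = 0L,
                        status = "alive", time = 1, n_extant = 1L),
                   class = "sim_bisse_tree")
  expect_error(prune_extinct(sim), "at least 2 extant tips")
})

test_that("tip-state summaries count correctly", {
  phy <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  d <- bisse_data(phy, c(t1 = 0, t2 = 0, t3 = 1, t4 = 1))
  expect_equal(tip_state_summary(d),
               c(count0 = 2, count1 = 2, fraction0 = 0.5))
  d1 <- bisse_data(phy, c(t1 = 1, t2 = 1, t3 = 1, t4 = 1))
  expect_equal(tip_state_summary(d1)[["fraction0"]], 0)
})

test_that("batches are reproducible and symmetric rates give balanced tips", {
  r <- rate_set(.1, .1, .03, .03, .01, .01)
  b1 <- sim_bisse_batch(r, n_tips = 30, n_reps = 25, seed = 99)
  b2 <- sim_bisse_batch(r, n_tips = 30, n_reps = 25, seed = 99)
  nw1 <- vapply(b1$trees, function(d) ape::write.tree(d$phy), character(1))
  nw2 <- vapply(b2$trees, function(d) ape::write.tree(d$phy), character(1))
  expect_identical(nw1, nw2)
  expect_identical(b1$fraction0, b2$fraction0)
  # symmetric rates: mean fraction in state 0 near 1/2
  mc <- 3 * b1$summary[["sd_fraction0"]] / sqrt(25)
  expect_lt(abs(b1$summary[["mean_fraction0"]] - 0.5), mc + 0.05)
})

test_that("label-swap symmetry mirrors the tip-state distribution", {
  r <- as_rate_set(c(lambda0 = .1, lambda1 = .15, mu0 = .03, mu1 = .05,
                     q01 = .02, q10 = .01))
  b <- sim_bisse_batch(r, n_tips = 40, n_reps = 40, seed = 5)
  bs <- sim_bisse_batch(swap_states(r), n_tips = 40, n_reps = 40, seed = 6)
  mc <- 3 * sqrt(b1_sd <- b$summary[["sd_fraction0"]]^2 / 40 +
                   bs$summary[["sd_fraction0"]]^2 / 40)
  expect_lt(abs(b$summary[["mean_fraction0"]] -
                  (1 - bs$summary[["mean_fraction0"]])), mc + 0.05)
})

test_that("pure-birth waiting times follow the Yule law", {
  # with k lineages the wait to the next speciation is exponential with
  # rate k * lambda; pooled normalized waits are standard exponential
  set.seed(1234)
  lambda <- 0.1
  r <- as_rate_set(c(lambda0 = lambda, lambda1 = 0, mu0 = 0, mu1 = 0,
                     q01 = 0, q10 = 0))
  pooled <- c()
  for (i in 1:150) {
    s <- sim_bisse(r, 8, root_state = "fixed0")
    btimes <- sort(s$end[s$status == "speciated"])
    waits <- diff(c(0, btimes))
    k <- seq_along(waits) # lineage count during each wait
    pooled <- c(pooled, k * lambda * waits)
  }
  expect_gt(length(pooled), 1000)
  ks <- stats::ks.test(pooled, "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("total extinction triggers restart and eventually errors at the cap", {
  r <- as_rate_set(c(lambda0 = 0.01, lambda1 = 0.01, mu0 = 5, mu1 = 5,
                     q01 = 0.01, q10 = 0.01))
  set.seed(2)
  expect_error(sim_bisse(r, 50, max_retries = 5), "total extinction")
})

test_that("simulation inputs are validated", {
  expect_error(sim_bisse(rate_set(.1, .1, 0, 0, .01, .01), 2), "at least 3")
  expect_error(sim_bisse(rate_set(.1, .1, 0, 0, 0, 0), 10,
                         root_state = "stationary"), "undefined")
})
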