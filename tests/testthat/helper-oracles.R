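# Independent likelihood oracle: the same pruning recursion written in
# plain R, with branch ODEs integrated by deSolve's fixed-step classical
# RK4 at a fine step. Shares no code with the package's adaptive
# integrator.
oracle_loglik <- function(data, rates, root_w, step = 0.005) {
  phy <- ape::reorder.phylo(data$phy, "postorder")
  n_tip <- length(phy$tip.label)
  st <- data$tip_state[phy$tip.label]
  r <- unclass(rates)
  rhs <- function(t, y, p) {
    E0 <- y[1]; E1 <- y[2]; D0 <- y[3]; D1 <- y[4]
    s0 <- r[["lambda0"]] + r[["mu0"]] + r[["q01"]]
    s1 <- r[["lambda1"]] + r[["mu1"]] + r[["q10"]]
    list(c(r[["mu0"]] - s0 * E0 + r[["q01"]] * E1 + r[["lambda0"]] * E0^2,
           r[["mu1"]] - s1 * E1 + r[["q10"]] * E0 + r[["lambda1"]] * E1^2,
           -s0 * D0 + r[["q01"]] * D1 + 2 * r[["lambda0"]] * E0 * D0,
           -s1 * D1 + r[["q10"]] * D0 + 2 * r[["lambda1"]] * E1 * D1))
  }
  branch <- function(y, len) {
    if (len <= 0) return(y)
    times <- seq(0, len, length.out = max(81, ceiling(len / step) + 1))
    out <- deSolve::rk4(y, times, rhs, NULL)
    unname(out[nrow(out), 2:5])
  }
  vals <- matrix(NA_real_, 2 * n_tip - 1, 4)
  logsc <- 0
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]; pa <- phy$edge[e, 1]
    y <- if (ch <= n_tip)
      c(0, 0, as.numeric(st[ch] == 0), as.numeric(st[ch] == 1))
    else vals[ch, ]
    y <- branch(y, phy$edge.length[e])
    if (any(is.na(vals[pa, ]))) {
      vals[pa, ] <- y
    } else {
      D0 <- r[["lambda0"]] * vals[pa, 3] * y[3]
      D1 <- r[["lambda1"]] * vals[pa, 4] * y[4]
      s <- D0 + D1
      logsc <- logsc + log(s)
      vals[pa, ] <- c((vals[pa, 1] + y[1]) / 2, (vals[pa, 2] + y[2]) / 2,
                      D0 / s, D1 / s)
    }
  }
  log(root_w[1] * vals[n_tip + 1, 3] + root_w[2] * vals[n_tip + 1, 4]) + logsc
}

# random valid rate draw in the regime the study explores
random_rates <- function() {
  as_rate_set(c(lambda0 = stats::runif(1, 0.05, 0.3),
                lambda1 = stats::runif(1, 0.05, 0.3),
                mu0 = stats::runif(1, 0, 0.1),
                mu1 = stats::runif(1, 0, 0.1),
                q01 = stats::runif(1, 0.005, 0.1),
                q10 = stats::runif(1, 0.005, 0.1)))
}

# quick simulated data set
random_tree_data <- function(n_tips, rates = random_rates()) {
  prune_extinct(sim_bisse(rates, n_tips))
}

# desk-scale optimizer budget used by the heavier simulation tests
lean_control <- function(...) {
  optimizer_config(n_starts = 1L, polish_top = 1L, reltol = 1e-3,
                   screen_cycles = 1L, brent_tol = 2e-3, ...)
}
lean_cfg <- function() integrator_config(rel_tol = 1e-6, abs_tol = 1e-8)

# shared across acceptance blocks (populated in order by the test file)
acceptance_cache <- new.env(parent = emptyenv())
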