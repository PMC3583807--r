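#' Simulate a tree with a co-evolving binary character
#'
#' Exact forward-time, event-driven simulation of a birth-death process
#' whose speciation, extinction and character-transition rates depend on
#' a lineage's binary state. At any instant the total event rate is the
#' sum over living lineages of \eqn{\lambda_s + \mu_s + q_{s\to}}; the
#' waiting time to the next event is exponential with that rate, and the
#' event type and the lineage it strikes are drawn with probability
#' proportional to their rate contributions. After each event all living
#' terminal branches are extended to the event time, so extant tips are
#' contemporaneous. Simulation starts from a single stem lineage and
#' stops the first instant the number of living lineages reaches
#' `n_tips`; if the whole clade dies first the attempt is discarded and
#' the simulation restarts with fresh randomness, up to `max_retries`
#' attempts.
#'
#' @param rates A [rate_set()].
#' @param n_tips Target number of extant tips (>= 3).
#' @param root_state One of `"stationary"` (root state drawn with the
#'   stationary probability of state 0, the default and the convention
#'   used throughout the power experiments), `"fixed0"`, `"fixed1"`.
#' @param max_retries Restart cap on total extinction (default 1000).
#' @param keep_history Record per-lineage state-flip times (slower;
#'   default `FALSE`).
#' @return An object of class `"sim_bisse_tree"`: parallel vectors
#'   `parent`, `birth`, `end`, `state` (state at the lineage's final
#'   instant), `status` (`"alive"`, `"speciated"`, `"extinct"`), the stop
#'   `time`, `attempts` used, and `n_extant`. Use [prune_extinct()] to
#'   obtain the reconstructed extant-only tree.
#' @seealso [prune_extinct()], [sim_bisse_batch()]
#' @export
sim_bisse <- function(rates, n_tips,
                      root_state = c("stationary", "fixed0", "fixed1"),
                      max_retries = 1000, keep_history = FALSE) {
  r <- as_rate_set(rates)
  root_state <- match.arg(root_state)
  if (n_tips < 3) stop("n_tips must be at least 3")
  p_root0 <- switch(root_state,
                    stationary = stationary_freq(r)$x_hat,
                    fixed0 = 1, fixed1 = 0)
  for (attempt in seq_len(max_retries)) {
    sim <- sim_bisse_once(unclass(r), n_tips, p_root0, keep_history)
    if (!is.null(sim)) {
      sim$attempts <- attempt
      return(sim)
    }
  }
  stop("simulation failed: total extinction in each of ", max_retries,
       " attempts")
}

sim_bisse_once <- function(r, n_tips, p_root0, keep_history) {
  l0 <- r[["lambda0"]]; l1 <- r[["lambda1"]]
  m0 <- r[["mu0"]]; m1 <- r[["mu1"]]
  q01 <- r[["q01"]]; q10 <- r[["q10"]]
  per0 <- l0 + m0 + q01; per1 <- l1 + m1 + q10

  cap <- 4L * n_tips + 8L
  parent <- integer(cap); birth <- numeric(cap); endt <- rep(NA_real_, cap)
  state <- integer(cap); status <- integer(cap) # 0 alive, 1 speciated, 2 extinct
  # living-lineage registries per state, with O(1) removal by swap-with-last
  a0 <- integer(cap); a1 <- integer(cap); c0 <- 0L; c1 <- 0L
  pos <- integer(cap)
  hist <- if (keep_history) vector("list", cap) else NULL

  add_alive <- function(id) {
    if (state[id] == 0L) { c0 <<- c0 + 1L; a0[c0] <<- id; pos[id] <<- c0 }
    else { c1 <<- c1 + 1L; a1[c1] <<- id; pos[id] <<- c1 }
  }
  drop_alive <- function(id) {
    j <- pos[id]
    if (state[id] == 0L) {
      last <- a0[c0]; a0[j] <<- last; pos[last] <<- j; c0 <<- c0 - 1L
    } else {
      last <- a1[c1]; a1[j] <<- last; pos[last] <<- j; c1 <<- c1 - 1L
    }
  }

  n_lin <- 1L
  parent[1] <- 0L; birth[1] <- 0
  state[1] <- if (stats::runif(1) < p_root0) 0L else 1L
  add_alive(1L)
  t <- 0

  repeat {
    R <- c0 * per0 + c1 * per1
    if (R <= 0) { # all processes dead-ended (e.g. pure-birth state with rate 0)
      if (c0 + c1 >= n_tips) break
      return(NULL)
    }
    t <- t + stats::rexp(1, R)
    u <- stats::runif(1) * R
    if (u < c0 * per0) { # event strikes a state-0 lineage
      id <- a0[if (c0 == 1L) 1L else sample.int(c0, 1L)]
      w <- u %% per0
      type <- if (w < l0) 1L else if (w < l0 + m0) 2L else 3L
    } else {
      id <- a1[if (c1 == 1L) 1L else sample.int(c1, 1L)]
      w <- (u - c0 * per0) %% per1
      type <- if (w < l1) 1L else if (w < l1 + m1) 2L else 3L
    }
    if (type == 1L) { # speciation
      drop_alive(id); status[id] <- 1L; endt[id] <- t
      if (n_lin + 2L > cap) {
        cap2 <- cap * 2L
        parent <- c(parent, integer(cap2 - cap)); birth <- c(birth, numeric(cap2 - cap))
        endt <- c(endt, rep(NA_real_, cap2 - cap)); state <- c(state, integer(cap2 - cap))
        status <- c(status, integer(cap2 - cap)); pos <- c(pos, integer(cap2 - cap))
        a0 <- c(a0, integer(cap2 - cap)); a1 <- c(a1, integer(cap2 - cap))
        if (keep_history) hist <- c(hist, vector("list", cap2 - cap))
        cap <- cap2
      }
      for (k in 1:2) {
        n_lin <- n_lin + 1L
        parent[n_lin] <- id; birth[n_lin] <- t; state[n_lin] <- state[id]
        add_alive(n_lin)
      }
      if (c0 + c1 >= n_tips) break
    } else if (type == 2L) { # extinction
      drop_alive(id); status[id] <- 2L; endt[id] <- t
      if (c0 + c1 == 0L) return(NULL)
    } else { # state flip
      drop_alive(id)
      state[id] <- 1L - state[id]
      add_alive(id)
      if (keep_history) hist[[id]] <- c(hist[[id]], t)
    }
  }
  alive <- c(if (c0 > 0L) a0[seq_len(c0)], if (c1 > 0L) a1[seq_len(c1)])
  endt[alive] <- t
  structure(list(parent = parent[seq_len(n_lin)], birth = birth[seq_len(n_lin)],
                 end = endt[seq_len(n_lin)],
                 state = state[seq_len(n_lin)],
                 status = c("alive", "speciated", "extinct")[status[seq_len(n_lin)] + 1L],
                 time = t, n_extant = c0 + c1,
                 flip_times = if (keep_history) hist[seq_len(n_lin)] else NULL),
            class = "sim_bisse_tree")
}

#' @export
print.sim_bisse_tree <- function(x, ...) {
  cat(sprintf("simulated tree: %d lineages, %d extant, clock time %.4f (%d attempt%s)\n",
              length(x$parent), x$n_extant, x$time,
              x$attempts %||% 1L, if ((x$attempts %||% 1L) > 1L) "s" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prune extinct lineages from a simulated tree
#'
#' Removes every lineage without surviving descendants, suppresses the
#' degree-2 nodes this creates (summing branch lengths), and discards the
#' stem above the most recent common ancestor of the extant tips, giving
#' the reconstructed tree an empirical phylogeny of contemporaneous
#' species corresponds to. Tip states are the simulated states at the
#' final instant.
#'
#' @param sim A `"sim_bisse_tree"` from [sim_bisse()].
#' @return A list of class `"bisse_data"`: `phy` (an ultrametric
#'   [ape::phylo] with tips labelled `t1..tN`) and `tip_state` (named
#'   integer vector of 0/1).
#' @export
prune_extinct <- function(sim) {
  stopifnot(inherits(sim, "sim_bisse_tree"))
  n <- length(sim$parent)
  if (sim$n_extant < 2L) stop("need at least 2 extant tips to prune")
  surv <- sim$status == "alive"
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sim$parent[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  for (i in rev(seq_len(n))) { # children always have larger ids than parents
    if (!surv[i] && length(kids[[i]])) surv[i] <- any(surv[kids[[i]]])
  }
  if (!surv[1L]) stop("no surviving lineages")

  surviving_kids <- function(i) { k <- kids[[i]]; k[surv[k]] }
  # descend through degree-1 survivors to the crown root
  crown <- 1L
  repeat {
    if (sim$status[crown] == "alive") stop("fewer than 2 surviving tips")
    sk <- surviving_kids(crown)
    if (length(sk) == 2L) break
    crown <- sk[1L]
  }

  n_tip <- sum(sim$status == "alive")
  edge <- matrix(0L, 2L * n_tip - 2L, 2L)
  elen <- numeric(2L * n_tip - 2L)
  tip_state <- integer(n_tip)
  n_edge <- 0L; next_tip <- 0L; next_node <- n_tip + 1L

  # stack of (lineage id, assigned parent node, time of parent node)
  root_node <- next_node; next_node <- next_node + 1L
  stack <- list(list(id = surviving_kids(crown)[1L], pn = root_node, pt = sim$end[crown]),
                list(id = surviving_kids(crown)[2L], pn = root_node, pt = sim$end[crown]))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    id <- fr$id
    # follow the chain of single-survivor speciations
    repeat {
      if (sim$status[id] == "alive") {
        next_tip <- next_tip + 1L
        n_edge <- n_edge + 1L
        edge[n_edge, ] <- c(fr$pn, next_tip)
        elen[n_edge] <- sim$end[id] - fr$pt
        tip_state[next_tip] <- sim$state[id]
        break
      }
      sk <- surviving_kids(id)
      if (length(sk) == 1L) { id <- sk; next }
      node <- next_node; next_node <- next_node + 1L
      n_edge <- n_edge + 1L
      edge[n_edge, ] <- c(fr$pn, node)
      elen[n_edge] <- sim$end[id] - fr$pt
      stack[[length(stack) + 1L]] <- list(id = sk[1L], pn = node, pt = sim$end[id])
      stack[[length(stack) + 1L]] <- list(id = sk[2L], pn = node, pt = sim$end[id])
      break
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("t", seq_len(n_tip)),
                        Nnode = n_tip - 1L),
                   class = "phylo", order = "cladewise")
  names(tip_state) <- phy$tip.label
  bisse_data(phy, tip_state)
}

#' Bundle a tree and its tip states
#'
#' @param phy An [ape::phylo] tree (rooted, bifurcating, branch lengths).
#' @param tip_state Named 0/1 vector covering exactly the tip labels.
#' @return A list of class `"bisse_data"`.
#' @export
bisse_data <- function(phy, tip_state) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' tree")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree must be strictly bifurcating")
  if (is.null(names(tip_state)))
    stop("tip_state must be named by tip label")
  miss <- setdiff(phy$tip.label, names(tip_state))
  if (length(miss)) stop("missing tip state: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(tip_state), phy$tip.label)
  if (length(extra)) stop("unknown tip in state table: ",
                          paste(extra, collapse = ", "))
  st <- as.integer(tip_state[phy$tip.label])
  if (any(is.na(st)) || !all(st %in% 0:1))
    stop("tip states must be 0 or 1")
  names(st) <- phy$tip.label
  structure(list(phy = phy, tip_state = st), class = "bisse_data")
}

#' @export
print.bisse_data <- function(x, ...) {
  s <- tip_state_summary(x)
  cat(sprintf("tree with %d tips: %d in state 0, %d in state 1 (fraction0 = %.4f)\n",
              length(x$tip_state), s[["count0"]], s[["count1"]],
              s[["fraction0"]]))
  invisible(x)
}

#' Tip-state counts of a tree
#'
#' @param x A `"bisse_data"` object or a named 0/1 state vector.
#' @return Named numeric vector `count0`, `count1`, `fraction0`.
#' @export
tip_state_summary <- function(x) {
  st <- if (inherits(x, "bisse_data")) x$tip_state else x
  n1 <- sum(st == 1L); n0 <- sum(st == 0L)
  c(count0 = n0, count1 = n1, fraction0 = n0 / (n0 + n1))
}

#' Simulate a batch of reconstructed trees
#'
#' Runs [sim_bisse()] + [prune_extinct()] `n_reps` times. Replicate
#' streams are derived from the base seed by drawing one sub-seed per
#' replicate up front, so any replicate can be reproduced independently.
#'
#' @param rates A [rate_set()] (ignored if `scenario` given).
#' @param n_tips,n_reps Tree size and replicate count.
#' @param seed Base RNG seed (integer).
#' @param root_state Root-state rule passed to [sim_bisse()].
#' @param scenario Optionally a [scenario()] supplying rates, `n_tips`,
#'   `n_reps` and `seed` in one object.
#' @param max_retries Per-replicate restart cap.
#' @return A list of class `"bisse_batch"`: `trees` (list of
#'   `"bisse_data"`), `fraction0` per replicate, `summary` (mean/sd of
#'   `fraction0`, total restart count), and the seeds used.
#' @export
sim_bisse_batch <- function(rates = NULL, n_tips = NULL, n_reps = NULL,
                            seed = 1L,
                            root_state = "stationary", scenario = NULL,
                            max_retries = 1000) {
  if (!is.null(scenario)) {
    rates <- scenario$rates; n_tips <- scenario$n_tips
    n_reps <- n_reps %||% scenario$n_reps
    seed <- scenario$seed %||% seed
  }
  stopifnot(n_reps >= 1)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  trees <- vector("list", n_reps)
  frac0 <- numeric(n_reps)
  retries <- 0L
  for (i in seq_len(n_reps)) {
    set.seed(sub_seeds[i])
    s <- sim_bisse(rates, n_tips, root_state = root_state,
                   max_retries = max_retries)
    retries <- retries + (s$attempts - 1L)
    trees[[i]] <- prune_extinct(s)
    frac0[i] <- tip_state_summary(trees[[i]])[["fraction0"]]
  }
  structure(list(trees = trees, fraction0 = frac0,
                 summary = c(mean_fraction0 = mean(frac0),
                             sd_fraction0 = stats::sd(frac0),
                             restarts = retries),
                 seed = seed, sub_seeds = sub_seeds),
            class = "bisse_batch")
}

#' @export
print.bisse_batch <- function(x, ...) {
  cat(sprintf("batch of %d trees: mean fraction0 = %.4f (sd %.4f, %d restarts)\n",
              length(x$trees), x$summary[["mean_fraction0"]],
              x$summary[["sd_fraction0"]], x$summary[["restarts"]]))
  invisible(x)
}
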