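#' Optimizer settings for maximum-likelihood fitting
#'
#' Fitting maximizes the log-likelihood over the log-transformed free
#' parameters of a [constraint_pattern()] by cyclic coordinate descent,
#' one Brent line search per free parameter per cycle, repeated from
#' several random log-uniform starting points plus an optional warm
#' start taken from a more-constrained fit.
#'
#' @param n_starts Number of random starting points (default 2, on top
#'   of any warm start).
#' @param start_bounds Log-uniform sampling range for starting rates
#'   (default `c(1e-4, 10)` per time unit).
#' @param rate_bounds Hard search bounds on every rate
#'   (default `c(1e-8, 100)`).
#' @param max_cycles Cap on coordinate-descent cycles per start.
#' @param reltol Minimum log-likelihood improvement per full cycle to
#'   continue (natural-log units).
#' @param brent_tol Brent tolerance on each log-rate coordinate.
#' @param screen_cycles Cycles every start runs before screening.
#' @param polish_top How many of the screened leaders are run to full
#'   convergence (the rest stop at the screen). A warm start is always
#'   polished, on top of this count.
#' @return A list of class `"optimizer_config"`.
#' @export
optimizer_config <- function(n_starts = 2L, start_bounds = c(1e-4, 10),
                             rate_bounds = c(1e-8, 100),
                             max_cycles = 200L, reltol = 1e-6,
                             brent_tol = 1e-3, screen_cycles = 2L,
                             polish_top = 1L) {
  stopifnot(n_starts >= 1, length(start_bounds) == 2L,
            all(start_bounds > 0), start_bounds[1] < start_bounds[2],
            length(rate_bounds) == 2L, all(rate_bounds > 0),
            rate_bounds[1] < rate_bounds[2], max_cycles >= 1, reltol > 0,
            brent_tol > 0, screen_cycles >= 1, polish_top >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 start_bounds = start_bounds, rate_bounds = rate_bounds,
                 max_cycles = as.integer(max_cycles), reltol = reltol,
                 brent_tol = brent_tol,
                 screen_cycles = as.integer(screen_cycles),
                 polish_top = as.integer(polish_top)),
            class = "optimizer_config")
}

#' One-dimensional Brent minimization
#'
#' Thin wrapper around [stats::optimize()] (Brent's derivative-free
#' golden-section/parabolic-interpolation method) that checks for
#' non-finite objective values and returns both the minimizer and the
#' minimum.
#'
#' @param f Scalar objective.
#' @param lower,upper Bracket endpoints.
#' @param tol Convergence tolerance on the argument.
#' @return List with `argmin` and `min`.
#' @export
brent_minimize <- function(f, lower, upper, tol = 1e-8) {
  wrapped <- function(x) {
    v <- f(x)
    if (is.na(v)) stop("non-finite objective at x = ", format(x))
    v
  }
  res <- stats::optimize(wrapped, lower = lower, upper = upper, tol = tol)
  list(argmin = res$minimum, min = res$objective)
}

#' Fit a BiSSE model by maximum likelihood
#'
#' Estimates the six state-dependent diversification rates (or the free
#' equality classes of a constrained model) from a reconstructed tree
#' with binary tip states. The search runs in log-parameter space by
#' cyclic coordinate descent with Brent line searches (rates span orders
#' of magnitude and must stay positive), from `n_starts` random
#' log-uniform starting points plus, when `warm_chain = TRUE` (the
#' default for models with more than three parameters), a warm start at
#' the optimum of the fully constrained three-parameter model. The best
#' final log-likelihood across starts wins; ties break to the lowest
#' start index. Results are deterministic given `seed`.
#'
#' @param data A [bisse_data()] object, or an `ape::phylo` tree (then
#'   supply `tip_state`).
#' @param pattern A [constraint_pattern()] or compact pattern string
#'   (default the full six-parameter model).
#' @param tip_state Named 0/1 vector when `data` is a bare tree.
#' @param root A [root_mode()].
#' @param control An [optimizer_config()].
#' @param cfg An [integrator_config()].
#' @param warm_start Optional `"bisse_fit"` from a nested (more
#'   constrained) pattern whose rates seed an extra start.
#' @param warm_chain If `TRUE` and no `warm_start` is supplied, first fit
#'   the three-parameter symmetric model and use it as warm start.
#' @param seed Integer seed for the random starts.
#' @return An object of class `"bisse_fit"` with components `rates`
#'   (the full `"rate_set"` at the optimum), `par` (free values),
#'   `loglik`, `pattern`, `converged`, `n_cycles`, `start_index`,
#'   `all_start_logliks`, `n_eval`, `boundary` (any estimate within 1e-6
#'   of a rate bound), `monomorphic` flag, and the inputs needed to
#'   re-evaluate the likelihood.
#' @seealso [bisse_loglik()], [anova.bisse_fit()] for likelihood-ratio
#'   comparison of nested fits.
#' @examples
#' set.seed(7)
#' d <- prune_extinct(sim_bisse(rate_set(.1, .1, .03, .03, .01, .01), 40))
#' fit <- bisse_fit(d, pattern = "l=,m=,q=", seed = 1)
#' coef(fit)
#' @export
bisse_fit <- function(data, pattern = "l0,l1,m0,m1,q0,q1", tip_state = NULL,
                      root = root_mode("stationary"),
                      control = optimizer_config(),
                      cfg = integrator_config(),
                      warm_start = NULL, warm_chain = TRUE, seed = 1L) {
  if (inherits(data, "phylo")) data <- bisse_data(data, tip_state)
  stopifnot(inherits(data, "bisse_data"))
  pattern <- constraint_pattern(pattern)
  if (length(data$tip_state) < 4L)
    stop("need at least 4 tips to fit")
  monomorphic <- length(unique(data$tip_state)) == 1L
  if (monomorphic)
    warning("tip states are monomorphic; expect boundary estimates")

  frame <- likelihood_frame(data, cfg)
  lb <- log(control$rate_bounds[1]); ub <- log(control$rate_bounds[2])
  n_eval <- 0L
  cls_idx <- lapply(pattern$classes, function(cl) match(cl, RATE_NAMES))
  static_w <- if (root$mode != "stationary") root_weights_for(root, NULL)
  objective <- function(theta) { # negative log-likelihood on log rates
    n_eval <<- n_eval + 1L
    rv <- numeric(6)
    v <- exp(theta)
    for (i in seq_along(cls_idx)) rv[cls_idx[[i]]] <- v[i]
    w <- if (is.null(static_w)) {
      x <- stationary_x_fast(rv)
      c(x, 1 - x)
    } else static_w
    res <- .bisse_loglik_cpp(frame$edge_parent, frame$edge_child,
                             frame$edge_length, frame$n_tip, frame$tip_state,
                             rv, w, frame$initial_step, frame$rel_tol,
                             frame$abs_tol, frame$clamp[1], frame$clamp[2])
    if (!res$ok || !is.finite(res$loglik) || res$e_mismatch > 1e-4)
      return(1e10)
    -res$loglik
  }

  if (is.null(warm_start) && warm_chain && pattern$free_count > 3L) {
    warm_start <- bisse_fit(data, pattern = "l=,m=,q=", root = root,
                            control = control, cfg = cfg,
                            warm_chain = FALSE, seed = seed)
  }
  starts <- list()
  if (!is.null(warm_start)) {
    stopifnot(inherits(warm_start, "bisse_fit"))
    th <- log(pmin(pmax(project_params(warm_start$rates, pattern),
                        control$rate_bounds[1]), control$rate_bounds[2]))
    starts <- list(th)
  }
  set.seed(as.integer(seed))
  for (i in seq_len(control$n_starts)) {
    starts[[length(starts) + 1L]] <-
      stats::runif(pattern$free_count, log(control$start_bounds[1]),
                   log(control$start_bounds[2]))
  }

  # Rates far above ~1 per unit of tree height put the clamped integrator
  # past its resolvable range (and the likelihood there is vanishingly
  # small); pull any start stranded in that infeasible region toward a
  # moderate anchor rate until the objective is finite.
  anchor <- log(1 / max(1, diff(range(ape::node.depth.edgelength(data$phy)))))
  rescue <- function(theta) {
    for (i in 1:8) {
      if (objective(theta) < 1e9) return(theta)
      theta <- 0.5 * theta + 0.5 * anchor
    }
    rep(anchor, length(theta))
  }
  # screen: every start runs a couple of cycles; only the leaders are
  # polished to convergence (cheap protection against local optima
  # without paying full convergence cost on every start)
  screen_ctl <- control
  screen_ctl$max_cycles <- min(control$screen_cycles, control$max_cycles)
  runs <- lapply(starts, function(theta0)
    coordinate_descent(objective, rescue(theta0), lb, ub, screen_ctl))
  screened <- vapply(runs, function(r) r$value, numeric(1))
  keep <- utils::head(order(screened), control$polish_top)
  # the warm start is always polished: a warm-started fit must never end
  # below the fit that seeded it
  if (!is.null(warm_start)) keep <- union(1L, keep)
  for (j in keep) {
    polished <- coordinate_descent(objective, runs[[j]]$par, lb, ub, control)
    polished$cycles <- polished$cycles + runs[[j]]$cycles
    runs[[j]] <- polished
  }
  finals <- vapply(runs, function(r) r$value, numeric(1))
  best <- which.min(finals) # which.min takes the first (lowest index) on ties
  run <- runs[[best]]
  if (!is.finite(run$value) || run$value >= 1e10)
    stop("all optimizer starts failed to find a finite likelihood")

  rates <- expand_params(exp(run$par), pattern)
  boundary <- any(abs(run$par - lb) < 1e-6) || any(abs(run$par - ub) < 1e-6)
  structure(list(rates = rates, par = exp(run$par), loglik = -run$value,
                 pattern = pattern, converged = run$converged,
                 n_cycles = run$cycles, start_index = best,
                 all_start_logliks = -finals, n_eval = n_eval,
                 boundary = boundary, monomorphic = monomorphic,
                 data = data, root = root, control = control, cfg = cfg,
                 seed = seed, n_tips = length(data$tip_state)),
            class = "bisse_fit")
}

coordinate_descent <- function(objective, theta0, lb, ub, control) {
  theta <- pmin(pmax(theta0, lb), ub)
  value <- objective(theta)
  converged <- FALSE
  cycles <- 0L
  half <- rep(2, length(theta)) # per-coordinate bracket half-width
  for (cyc in seq_len(control$max_cycles)) {
    cycles <- cyc
    prev <- value
    for (k in seq_along(theta)) {
      f1 <- function(x) { th <- theta; th[k] <- x; objective(th) }
      # Brent on a local bracket around the current coordinate; the
      # coordinate only moves on strict improvement, and the bracket is
      # re-expanded when an improving minimizer lands on an interior
      # bracket edge (never on penalty plateaus, where the minimizer's
      # position is meaningless)
      old <- theta[k]
      half_k <- half[k]
      edge_tol <- 10 * control$brent_tol
      repeat {
        lo <- max(lb, theta[k] - half_k); hi <- min(ub, theta[k] + half_k)
        opt <- stats::optimize(f1, lower = lo, upper = hi,
                               tol = control$brent_tol)
        moved <- opt$objective < value
        if (moved) {
          theta[k] <- opt$minimum
          value <- opt$objective
        }
        at_edge <- (opt$minimum - lo < edge_tol && lo > lb) ||
          (hi - opt$minimum < edge_tol && hi < ub)
        if (!moved || !at_edge || half_k >= (ub - lb)) break
        half_k <- half_k * 4
      }
      half[k] <- min(2, max(0.25, 4 * abs(theta[k] - old)))
    }
    if (value >= 1e9 && cyc >= 2L) break # start stuck in an infeasible region
    if (prev - value < control$reltol) { converged <- TRUE; break }
  }
  list(par = theta, value = value, converged = converged, cycles = cycles)
}

#' @export
print.bisse_fit <- function(x, digits = 5, ...) {
  cat(sprintf("BiSSE %d-parameter ML fit (%d tips)\n",
              x$pattern$free_count, x$n_tips))
  cat("pattern: ", pattern_string(x$pattern), "\n", sep = "")
  print(signif(unclass(x$rates), digits))
  cat(sprintf("ln L = %.4f%s%s\n", x$loglik,
              if (x$converged) "" else " (not converged)",
              if (x$boundary) " (estimate at a rate bound)" else ""))
  invisible(x)
}

#' @export
summary.bisse_fit <- function(object, ...) {
  out <- list(rates = object$rates, loglik = object$loglik,
              df = object$pattern$free_count,
              aic = 2 * object$pattern$free_count - 2 * object$loglik,
              pattern = pattern_string(object$pattern),
              converged = object$converged, n_cycles = object$n_cycles,
              start_index = object$start_index,
              all_start_logliks = object$all_start_logliks,
              boundary = object$boundary, n_tips = object$n_tips)
  class(out) <- "summary.bisse_fit"
  out
}

#' @export
print.summary.bisse_fit <- function(x, ...) {
  cat(sprintf("BiSSE fit: %s (%d free parameters, %d tips)\n",
              x$pattern, x$df, x$n_tips))
  print(signif(unclass(x$rates), 5))
  cat(sprintf("ln L = %.4f   AIC = %.2f\n", x$loglik, x$aic))
  cat(sprintf("winning start %d of %d; per-start ln L: %s\n",
              x$start_index, length(x$all_start_logliks),
              paste(sprintf("%.3f", x$all_start_logliks), collapse = ", ")))
  if (!x$converged) cat("warning: cycle cap reached before convergence\n")
  if (x$boundary) cat("warning: estimate at a rate bound\n")
  invisible(x)
}

#' @export
coef.bisse_fit <- function(object, expand = TRUE, ...) {
  if (expand) unclass(object$rates)
  else stats::setNames(object$par, names(object$pattern$classes))
}

#' @export
logLik.bisse_fit <- function(object, ...) {
  structure(object$loglik, df = object$pattern$free_count,
            nobs = object$n_tips, class = "logLik")
}

#' Simulate trees from a fitted model
#'
#' Draws new reconstructed trees (with tip states) of the same size as
#' the fitted data under the maximum-likelihood rates.
#'
#' @param object A `"bisse_fit"`.
#' @param nsim Number of trees.
#' @param seed Base seed.
#' @param ... Unused.
#' @return A list of [bisse_data()] objects (length `nsim`).
#' @export
simulate.bisse_fit <- function(object, nsim = 1, seed = 1L, ...) {
  batch <- sim_bisse_batch(object$rates, n_tips = object$n_tips,
                           n_reps = nsim, seed = seed)
  batch$trees
}

#' Likelihood-ratio comparison of nested BiSSE fits
#'
#' @param object A constrained `"bisse_fit"`.
#' @param ... Exactly one less-constrained `"bisse_fit"` on the same data.
#' @return A data frame with log-likelihoods, the statistic
#'   `2 * (lnL_full - lnL_constrained)` and the chi-square p-value at
#'   `df = ` difference in free parameters (offered for reference; the
#'   power experiments use simulated critical values instead).
#' @export
anova.bisse_fit <- function(object, ...) {
  others <- list(...)
  if (length(others) != 1L || !inherits(others[[1]], "bisse_fit"))
    stop("anova() needs exactly two nested bisse_fit objects")
  small <- object; big <- others[[1]]
  if (small$pattern$free_count > big$pattern$free_count) {
    tmp <- small; small <- big; big <- tmp
  }
  if (!pattern_nests(small$pattern, big$pattern))
    stop("models are not nested")
  stat <- max(0, 2 * (big$loglik - small$loglik))
  df <- big$pattern$free_count - small$pattern$free_count
  data.frame(model = c(pattern_string(small$pattern),
                       pattern_string(big$pattern)),
             df = c(small$pattern$free_count, big$pattern$free_count),
             logLik = c(small$loglik, big$loglik),
             stat = c(NA, stat),
             p_chisq = c(NA, stats::pchisq(stat, df, lower.tail = FALSE)))
}
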