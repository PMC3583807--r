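#' Parameter-recovery experiment for one scenario
#'
#' Simulates replicate trees under a scenario's rates and refits the
#' unconstrained six-parameter model on each, summarizing how well the
#' generating rates are recovered. This reproduces the accuracy/precision
#' side of the power study: estimate clouds tighten with tree size and
#' low tip bias, and strong tip bias lets an asymmetry in one process
#' masquerade as asymmetry in another (confounding).
#'
#' @param scenario A [scenario()].
#' @param root,control,cfg Shared configurations (see [bisse_fit()]).
#' @param pattern Fitted model (default the full six-parameter model).
#' @return A list of class `"bisse_recovery"`: `fits` (successful
#'   `"bisse_fit"`s), `estimates` (replicate-by-rate matrix), `summary`
#'   (an `"estimate_summary"`), `n_failed`, `n_boundary`, the scenario.
#' @export
run_recovery <- function(scenario, root = root_mode("stationary"),
                         control = optimizer_config(),
                         cfg = integrator_config(),
                         pattern = "l0,l1,m0,m1,q0,q1") {
  stopifnot(inherits(scenario, "scenario"))
  batch <- sim_bisse_batch(scenario = scenario)
  fits <- vector("list", length(batch$trees))
  failed <- logical(length(batch$trees))
  for (i in seq_along(batch$trees)) {
    fits[[i]] <- tryCatch(
      bisse_fit(batch$trees[[i]], pattern = pattern, root = root,
                control = control, cfg = cfg, seed = scenario$seed + i),
      error = function(e) NULL)
    failed[i] <- is.null(fits[[i]])
  }
  fits <- fits[!failed]
  if (!length(fits)) stop("every replicate fit failed")
  summ <- summarize_estimates(fits, scenario$rates)
  if (mean(failed) > 0.10) summ$flagged <- TRUE
  structure(list(fits = fits, estimates = summ$estimates, summary = summ,
                 n_failed = sum(failed),
                 n_boundary = sum(vapply(fits, `[[`, logical(1), "boundary")),
                 scenario = scenario),
            class = "bisse_recovery")
}

#' Summarize replicate rate estimates against the truth
#'
#' @param fits List of `"bisse_fit"`s (at least 2) sharing a pattern.
#' @param truth The generating [rate_set()].
#' @return An object of class `"estimate_summary"`: `table` (data frame
#'   with true value, mean, sd -- the sample standard deviation across
#'   replicates -- bias and 2.5/50/97.5% quantiles per rate), the raw
#'   `estimates` matrix (rows sorted for order-independence), `n_reps`.
#' @export
summarize_estimates <- function(fits, truth) {
  if (length(fits) < 2L) stop("need at least 2 fits to summarize")
  truth <- as_rate_set(truth)
  est <- t(vapply(fits, function(f) unclass(f$rates), numeric(6)))
  colnames(est) <- RATE_NAMES
  est <- est[do.call(order, as.data.frame(est)), , drop = FALSE]
  qs <- apply(est, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), type = 7)
  tab <- data.frame(rate = RATE_NAMES,
                    true = as.numeric(unclass(truth)),
                    mean = colMeans(est),
                    sd = apply(est, 2, stats::sd),
                    bias = colMeans(est) - as.numeric(unclass(truth)),
                    q025 = qs[1, ], q50 = qs[2, ], q975 = qs[3, ],
                    row.names = NULL)
  structure(list(table = tab, estimates = est, n_reps = nrow(est),
                 flagged = FALSE),
            class = "estimate_summary")
}

#' @export
print.estimate_summary <- function(x, digits = 4, ...) {
  cat(sprintf("parameter recovery over %d replicate fits%s:\n", x$n_reps,
              if (x$flagged) " (more than 10% of fits failed)" else ""))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.bisse_recovery <- function(x, ...) {
  cat(sprintf("recovery experiment '%s' (%d tips, %d fits, %d failed, %d at bounds)\n",
              x$scenario$label, x$scenario$n_tips, length(x$fits),
              x$n_failed, x$n_boundary))
  print(x$summary)
  invisible(x)
}

#' Scatter plot of replicate estimates per process
#'
#' Base-graphics scatter of the paired estimates for each process
#' (lambda0 vs lambda1, mu0 vs mu1, q01 vs q10) with the generating
#' values marked, in the style of recovery clouds.
#'
#' @param x A `"bisse_recovery"`.
#' @param ... Passed to [plot()].
#' @export
plot.bisse_recovery <- function(x, ...) {
  est <- x$estimates
  truth <- unclass(x$scenario$rates)
  pairs <- list(c("lambda0", "lambda1"), c("mu0", "mu1"), c("q01", "q10"))
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (p in pairs) {
    graphics::plot(est[, p[1]], est[, p[2]], xlab = p[1], ylab = p[2],
                   pch = 16, col = "#00000088", ...)
    graphics::points(truth[[p[1]]], truth[[p[2]]], pch = 3, col = "red",
                     cex = 2, lwd = 2)
  }
  invisible(x)
}
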