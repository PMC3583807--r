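#' Stationary frequency of state 0
#'
#' Solves the equilibrium condition for the proportion of lineages in
#' state 0 under state-dependent diversification,
#' \deqn{g \hat{x} (1-\hat{x}) - \hat{x} q_{01} + (1-\hat{x}) q_{10} = 0,}
#' where \eqn{g = \lambda_0 - \mu_0 - \lambda_1 + \mu_1}. The expected
#' tip-state ratio of a clade evolved to stationarity is
#' \eqn{(1-\hat{x}) : \hat{x}} (state 1 : state 0).
#'
#' When \eqn{g = 0} the closed form \eqn{\hat{x} = q_{10}/(q_{01}+q_{10})}
#' applies; otherwise the condition is a quadratic in \eqn{\hat{x}} with
#' exactly one root in \eqn{[0,1]}, found in closed form and refined by
#' bisection if floating-point cancellation leaves the closed-form root
#' outside tolerance.
#'
#' @param rates A [rate_set()] (or coercible named vector). Requires
#'   `q01 + q10 > 0`.
#' @return A list of class `"stationary_solution"`: `x_hat` (frequency of
#'   state 0), `g` (the composite rate), `tip_ratio` (display string,
#'   nearest-integer "N1:1" style ratio), `residual`.
#' @examples
#' stationary_freq(rate_set(0.1, 0.125, 0.03, 0.03, 0.01, 0.01))
#' @export
stationary_freq <- function(rates) {
  r <- as_rate_set(rates)
  q01 <- r[["q01"]]; q10 <- r[["q10"]]
  if (q01 + q10 <= 0)
    stop("stationary frequency undefined: q01 = q10 = 0")
  g <- r[["lambda0"]] - r[["mu0"]] - r[["lambda1"]] + r[["mu1"]]
  f <- function(x) g * x * (1 - x) - x * q01 + (1 - x) * q10
  if (g == 0) {
    x <- q10 / (q01 + q10)
  } else {
    # g x^2 - (g - q01 - q10) x - q10 = 0
    a <- g; b <- -(g - q01 - q10); cc <- -q10
    disc <- sqrt(max(b * b - 4 * a * cc, 0))
    roots <- c((-b + disc) / (2 * a), (-b - disc) / (2 * a))
    roots <- pmin(pmax(roots, 0), 1)
    x <- roots[which.min(abs(f(roots)))] # the root inside [0,1]
  }
  if (!is.finite(x) || abs(f(x)) >= 1e-10) {
    # bisection fallback: f(0) = q10 >= 0, f(1) = -q01 <= 0
    x <- stats::uniroot(f, c(0, 1), tol = 1e-15)$root
  }
  structure(list(x_hat = x, g = g, tip_ratio = tip_ratio_string(x),
                 residual = f(x)),
            class = "stationary_solution")
}

# allocation-light stationary frequency for the optimizer hot path;
# rv ordered as RATE_NAMES
stationary_x_fast <- function(rv) {
  q01 <- rv[5]; q10 <- rv[6]
  g <- rv[1] - rv[3] - rv[2] + rv[4]
  if (g == 0) return(q10 / (q01 + q10))
  b <- -(g - q01 - q10)
  disc <- sqrt(max(b * b + 4 * g * q10, 0))
  r1 <- (-b + disc) / (2 * g)
  if (r1 >= 0 && r1 <= 1) return(r1)
  min(max((-b - disc) / (2 * g), 0), 1)
}

tip_ratio_string <- function(x_hat) {
  if (x_hat <= 0) return("all-1")
  if (x_hat >= 1) return("all-0")
  r <- (1 - x_hat) / x_hat
  if (r >= 1) sprintf("%d:1", as.integer(round(r)))
  else sprintf("1:%d", as.integer(round(1 / r)))
}

#' @export
print.stationary_solution <- function(x, ...) {
  cat(sprintf("stationary freq of state 0: x_hat = %.6f (tip ratio %s, g = %.6g)\n",
              x$x_hat, x$tip_ratio, x$g))
  invisible(x)
}

#' Rate ratio producing a target stationary state frequency
#'
#' Finds the asymmetry in one process (speciation, extinction or
#' character change) that drives the stationary frequency of state 0 to a
#' target value, with the two rates of that process placed geometrically
#' around their base value: `base/sqrt(r)` and `base*sqrt(r)`. The sign of
#' the asymmetry is arranged so that state 1 is favoured when
#' `target_x_hat < 0.5` (higher speciation in state 1, higher extinction
#' in state 0, or net transition flow into state 1) and state 0 is
#' favoured otherwise. All other rates keep their base values.
#'
#' For character change with the other processes symmetric the answer is
#' analytic: the ratio equals `(1 - target_x_hat) / target_x_hat`. The
#' other processes are solved by root-finding on the log-ratio.
#'
#' @param process One of `"speciation"`, `"extinction"`,
#'   `"character_change"`.
#' @param base_rates A [rate_set()] in which the chosen process is
#'   symmetric; its common value is the base the asymmetric rates are
#'   placed around.
#' @param target_x_hat Target stationary frequency of state 0, in (0,1).
#' @param tol Convergence tolerance on `x_hat` (default `1e-10`, well
#'   inside the `1e-8` contract).
#' @return List with `ratio` (>= 1) and `rates` (the asymmetric
#'   `"rate_set"`).
#' @examples
#' base <- rate_set(0.1, 0.1, 0.05, 0.05, 0.005, 0.005)
#' solve_rate_ratio("speciation", base, 0.25) # ratio 1.1425
#' @export
solve_rate_ratio <- function(process = c("speciation", "extinction", "character_change"),
                             base_rates, target_x_hat, tol = 1e-10) {
  process <- match.arg(process)
  r <- as_rate_set(base_rates)
  if (!(target_x_hat > 0 && target_x_hat < 1))
    stop("target_x_hat must lie strictly in (0, 1)")
  nm <- switch(process,
               speciation = c("lambda0", "lambda1"),
               extinction = c("mu0", "mu1"),
               character_change = c("q01", "q10"))
  if (abs(r[[nm[1]]] - r[[nm[2]]]) > 1e-12 * max(r[[nm[1]]], 1))
    stop("base rates for the chosen process must be symmetric")
  base <- r[[nm[1]]]
  if (base <= 0) stop("base rate for the chosen process must be positive")

  favor1 <- target_x_hat < 0.5
  # which of the process's two rates is raised when state 1 is favoured:
  # speciation: lambda1 up; extinction: mu0 up; character change: q01 up
  up_first <- switch(process, speciation = FALSE, extinction = TRUE,
                     character_change = TRUE)
  place <- function(ratio) {
    s <- sqrt(ratio)
    hi <- base * s; lo <- base / s
    out <- unclass(r)
    raised_is_first <- xor(up_first, !favor1)
    out[nm] <- if (raised_is_first) c(hi, lo) else c(lo, hi)
    as_rate_set(out)
  }
  xfun <- function(log_ratio) stationary_freq(place(exp(log_ratio)))$x_hat

  if (process == "character_change" &&
      r[["lambda0"]] == r[["lambda1"]] && r[["mu0"]] == r[["mu1"]]) {
    # g = 0: x_hat = q10/(q01+q10) = 1/(1+ratio) when state 1 favoured
    ratio <- if (favor1) (1 - target_x_hat) / target_x_hat else
      target_x_hat / (1 - target_x_hat)
    return(list(ratio = ratio, rates = place(ratio)))
  }

  obj <- function(lr) xfun(lr) - target_x_hat
  # monotone bracket on log-ratio >= 0; expand until sign change
  lo <- 0; hi <- 1e-3
  f_lo <- obj(lo)
  if (abs(f_lo) < tol) return(list(ratio = 1, rates = place(1)))
  repeat {
    f_hi <- obj(hi)
    if (is.finite(f_hi) && sign(f_hi) != sign(f_lo)) break
    hi <- hi * 2
    if (hi > log(1e8)) stop("target unreachable: no rate ratio attains the ",
                            "requested stationary frequency")
  }
  root <- stats::uniroot(obj, c(lo, hi), tol = 1e-14)$root
  ratio <- exp(root)
  out <- place(ratio)
  if (abs(stationary_freq(out)$x_hat - target_x_hat) > 1e-8)
    stop("rate-ratio solver failed to converge")
  list(ratio = ratio, rates = out)
}
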