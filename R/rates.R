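#' The six BiSSE rates
#'
#' Construct and validate the rate set of the binary-state speciation and
#' extinction model: state-specific speciation rates (`lambda0`, `lambda1`),
#' extinction rates (`mu0`, `mu1`) and character transition rates (`q01`,
#' `q10`), all in events per lineage per unit time.
#'
#' @param lambda0,lambda1 Speciation rate while in state 0 / state 1.
#' @param mu0,mu1 Extinction rate while in state 0 / state 1.
#' @param q01 Transition rate from state 0 to state 1.
#' @param q10 Transition rate from state 1 to state 0.
#' @return A named numeric vector of class `"rate_set"` with elements
#'   `lambda0, lambda1, mu0, mu1, q01, q10`.
#' @examples
#' rate_set(0.1, 0.125, 0.03, 0.03, 0.01, 0.01)
#' @export
rate_set <- function(lambda0, lambda1, mu0, mu1, q01, q10) {
  x <- c(lambda0 = lambda0, lambda1 = lambda1, mu0 = mu0, mu1 = mu1,
         q01 = q01, q10 = q10)
  validate_rates(x)
  class(x) <- "rate_set"
  x
}

RATE_NAMES <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")

#' Coerce a named vector to a rate set
#'
#' @param x Named numeric vector containing all six rate names.
#' @return A `"rate_set"`.
#' @export
as_rate_set <- function(x) {
  if (inherits(x, "rate_set")) return(x)
  if (is.null(names(x)) || !all(RATE_NAMES %in% names(x)))
    stop("rates must be named with: ", paste(RATE_NAMES, collapse = ", "))
  y <- as.numeric(x[RATE_NAMES])
  names(y) <- RATE_NAMES
  validate_rates(y)
  class(y) <- "rate_set"
  y
}

validate_rates <- function(x) {
  v <- unclass(x)
  if (length(v) != 6L || !is.numeric(v))
    stop("a rate set has exactly six numeric rates")
  if (any(!is.finite(v)) || any(v < 0))
    stop("all rates must be finite and non-negative")
  if (v[["lambda0"]] <= 0 && v[["lambda1"]] <= 0)
    stop("at least one speciation rate must be positive")
  invisible(x)
}

#' @export
print.rate_set <- function(x, digits = 6, ...) {
  cat("BiSSE rates (events/lineage/time):\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

#' Swap the roles of states 0 and 1 in a rate set
#'
#' Exchanges `lambda0` with `lambda1`, `mu0` with `mu1` and `q01` with
#' `q10`. Useful for label-swap symmetry checks: the model is invariant
#' under simultaneously relabelling tip states and swapping rates.
#'
#' @param rates A `"rate_set"`.
#' @return The relabelled `"rate_set"`.
#' @export
swap_states <- function(rates) {
  r <- as_rate_set(rates)
  rate_set(r[["lambda1"]], r[["lambda0"]], r[["mu1"]], r[["mu0"]],
           r[["q10"]], r[["q01"]])
}
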