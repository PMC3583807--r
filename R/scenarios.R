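#' Canonical simulation scenarios of the power study
#'
#' `asymmetry_scenarios()` builds the single-process rate-asymmetry
#' conditions used for the six-vs-five-parameter power analysis: one
#' process gets an asymmetric pair while the other two stay at their
#' symmetric bases (speciation rows use `mu = 0.03`, `q = 0.01`;
#' character-change rows use `lambda = 0.1`, `mu = 0.03`; extinction rows
#' use `lambda = 0.1`, `q = 0.01`).
#'
#' `bias_target_scenarios()` builds the reduced-model (four-vs-three)
#' conditions: for each process, the two rates are placed geometrically
#' around bases `lambda = 0.1`, `mu = 0.05`, `q = 0.005` at the ratio
#' that drives the stationary minority-state frequency to a 3:1 (low
#' bias) or 7:1 (high bias) tip ratio, via [solve_rate_ratio()].
#'
#' @param n_tips,n_reps,seed Scenario sizing applied to every row.
#' @return A named list of [scenario()]s.
#' @export
asymmetry_scenarios <- function(n_tips = 500L, n_reps = 500L, seed = 1L) {
  mk <- function(label, l0, l1, m0, m1, q01, q10)
    scenario(rate_set(l0, l1, m0, m1, q01, q10), n_tips, n_reps, label, seed)
  spec_mult <- c(1.25, 1.5, 2, 3, 4, 5, 10, 20)
  char_mult <- c(2, 3, 4, 5, 10, 20, 40)
  ext_mult <- c(2, 3, 4, 5, 10)
  out <- list()
  for (m in spec_mult)
    out[[sprintf("speciation %gx", m)]] <-
      mk(sprintf("speciation %gx", m), 0.1, 0.1 * m, 0.03, 0.03, 0.01, 0.01)
  for (m in char_mult)
    out[[sprintf("character %gx", m)]] <-
      mk(sprintf("character %gx", m), 0.1, 0.1, 0.03, 0.03, 0.005 * m, 0.005)
  for (m in ext_mult)
    out[[sprintf("extinction %gx", m)]] <-
      mk(sprintf("extinction %gx", m), 0.1, 0.1, 0.03 * m, 0.03, 0.01, 0.01)
  out
}

#' @rdname asymmetry_scenarios
#' @param bias `"low"` (3:1 target, stationary frequency 0.25) and/or
#'   `"high"` (7:1 target, 0.125).
#' @export
bias_target_scenarios <- function(bias = c("low", "high"), n_tips = 500L,
                                  n_reps = 500L, seed = 1L) {
  bias <- match.arg(bias, several.ok = TRUE)
  base <- rate_set(0.1, 0.1, 0.05, 0.05, 0.005, 0.005)
  targets <- c(low = 0.25, high = 0.125)
  out <- list()
  for (b in bias) {
    for (pr in c("speciation", "extinction", "character_change")) {
      sol <- solve_rate_ratio(pr, base, targets[[b]])
      lab <- sprintf("%s %s bias", sub("_change", "", pr), b)
      out[[lab]] <- scenario(sol$rates, n_tips, n_reps, lab, seed)
    }
  }
  out
}

#' List and load the shipped scenario fixture files
#'
#' One plain-text file per simulation condition ships under
#' `extdata/scenarios`; [read_scenario()] parses them.
#'
#' @return `scenario_fixture_files()`: character vector of paths.
#' @export
scenario_fixture_files <- function() {
  dir <- system.file("extdata", "scenarios", package = "bissepower")
  list.files(dir, pattern = "\\.txt$", full.names = TRUE)
}
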