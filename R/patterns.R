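#' Model constraint patterns
#'
#' A constraint pattern partitions the six BiSSE rates into equality
#' classes, defining the 3- to 6-parameter models compared in
#' likelihood-ratio tests. Only rates of the same process may be merged
#' (speciation with speciation, extinction with extinction, transition
#' with transition).
#'
#' The compact string notation lists one token per process pair:
#' `"l0,l1"` leaves the two speciation rates free, `"l="` constrains
#' `lambda0 = lambda1`, and likewise `m0,m1`/`m=` for extinction and
#' `q0,q1`/`q=` for the transition rates (where `q0` stands for `q01` and
#' `q1` for `q10`). Examples:
#' \describe{
#'   \item{`"l0,l1,m0,m1,q0,q1"`}{the full six-parameter model}
#'   \item{`"l=,m0,m1,q0,q1"`}{five parameters, speciation constrained}
#'   \item{`"l0,l1,m=,q="`}{four parameters, speciation free}
#'   \item{`"l=,m=,q="`}{the three-parameter symmetric model}
#' }
#'
#' @param spec Compact pattern string, or a list of character vectors of
#'   rate names giving the equality classes explicitly.
#' @return An object of class `"constraint_pattern"`: a list with
#'   `classes` (named list of rate-name vectors) and `free_count`.
#' @examples
#' constraint_pattern("l0,l1,m=,q=")
#' @export
constraint_pattern <- function(spec) {
  if (inherits(spec, "constraint_pattern")) return(spec)
  classes <- if (is.character(spec) && length(spec) == 1L) {
    parse_pattern_string(spec)
  } else if (is.list(spec)) {
    spec
  } else stop("pattern must be a compact string or a list of rate-name classes")
  validate_pattern_classes(classes)
  names(classes) <- vapply(classes, function(cl) cl[1L], character(1))
  structure(list(classes = classes, free_count = length(classes)),
            class = "constraint_pattern")
}

parse_pattern_string <- function(s) {
  tok <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  map <- list(
    "l0" = "lambda0", "l1" = "lambda1",
    "m0" = "mu0", "m1" = "mu1",
    "q0" = "q01", "q1" = "q10")
  merged <- list("l=" = c("lambda0", "lambda1"),
                 "m=" = c("mu0", "mu1"),
                 "q=" = c("q01", "q10"))
  classes <- list()
  for (t in tok) {
    if (!is.null(map[[t]])) classes <- c(classes, list(map[[t]]))
    else if (!is.null(merged[[t]])) classes <- c(classes, list(merged[[t]]))
    else stop("unknown pattern token: '", t, "'")
  }
  classes
}

validate_pattern_classes <- function(classes) {
  all_names <- unlist(classes)
  if (!setequal(all_names, RATE_NAMES) || anyDuplicated(all_names))
    stop("pattern classes must partition the six rate names exactly once each")
  proc <- function(nm) substr(nm, 1, 1) # l/m/q by leading letter of rate name
  for (cl in classes) {
    if (length(unique(vapply(cl, proc, character(1)))) != 1L)
      stop("only rates of the same process may share an equality class")
  }
  invisible(classes)
}

#' @export
print.constraint_pattern <- function(x, ...) {
  cl <- vapply(x$classes, paste, character(1), collapse = "=")
  cat(sprintf("%d-parameter model: (%s)\n", x$free_count,
              paste(cl, collapse = ") (")))
  invisible(x)
}

#' Expand free parameter values into a full rate set
#'
#' Maps optimizer coordinates (one value per equality class, in the order
#' the classes appear in the pattern) onto the six rates.
#'
#' @param free_values Numeric vector, one value per class.
#' @param pattern A [constraint_pattern()].
#' @return A `"rate_set"`.
#' @export
expand_params <- function(free_values, pattern) {
  pattern <- constraint_pattern(pattern)
  if (length(free_values) != pattern$free_count)
    stop("expected ", pattern$free_count, " free values, got ",
         length(free_values))
  if (any(!is.finite(free_values)) || any(free_values < 0))
    stop("free values must be finite and non-negative")
  out <- numeric(6)
  names(out) <- RATE_NAMES
  for (i in seq_along(pattern$classes)) out[pattern$classes[[i]]] <- free_values[i]
  as_rate_set(out)
}

#' Project a rate set onto a pattern's free coordinates
#'
#' Inverse of [expand_params()]: each class takes the mean of its member
#' rates (exact when the rates already satisfy the constraints).
#'
#' @param rates A `"rate_set"`.
#' @param pattern A [constraint_pattern()].
#' @return Numeric vector of length `free_count`.
#' @export
project_params <- function(rates, pattern) {
  rates <- as_rate_set(rates)
  pattern <- constraint_pattern(pattern)
  vapply(pattern$classes, function(cl) mean(unclass(rates)[cl]), numeric(1))
}

#' Does one pattern nest within another?
#'
#' `constrained` nests in `full` when every equality class of `constrained`
#' is a union of classes of `full` (so the constrained model is a
#' restriction of the full one).
#'
#' @param constrained,full [constraint_pattern()]s.
#' @return Logical.
#' @export
pattern_nests <- function(constrained, full) {
  constrained <- constraint_pattern(constrained)
  full <- constraint_pattern(full)
  for (cl in full$classes) {
    holders <- vapply(constrained$classes,
                      function(cc) all(cl %in% cc), logical(1))
    if (sum(holders) != 1L) return(FALSE)
  }
  TRUE
}

# standard model pairs used by the power experiments
pair_patterns <- function(process = c("speciation", "extinction", "character"),
                          pair = c("6v5", "4v3")) {
  process <- match.arg(process)
  pair <- match.arg(pair)
  tok <- switch(process, speciation = "l", extinction = "m", character = "q")
  others <- setdiff(c("l", "m", "q"), tok)
  if (pair == "6v5") {
    full <- "l0,l1,m0,m1,q0,q1"
    constrained <- paste(c(paste0(tok, "="),
                           paste0(rep(others, each = 2), 0:1)), collapse = ",")
  } else {
    full <- paste(c(paste0(tok, 0:1), paste0(others, "=")), collapse = ",")
    constrained <- "l=,m=,q="
  }
  list(full = constraint_pattern(full), constrained = constraint_pattern(constrained))
}
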