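#' Simulation scenario
#'
#' A scenario bundles the generating rates with the experiment size: the
#' number of extant tips per tree, the number of replicate trees, a text
#' label and the base RNG seed.
#'
#' @param rates A [rate_set()].
#' @param n_tips Extant tips per tree (>= 3).
#' @param n_reps Replicates (>= 1).
#' @param label Free-text tag, e.g. `"speciation 1.25x"`.
#' @param seed Base seed.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(rates, n_tips, n_reps = 500L, label = "", seed = 1L) {
  r <- as_rate_set(rates)
  if (n_tips < 3) stop("n_tips must be at least 3")
  if (n_reps < 1) stop("n_reps must be at least 1")
  structure(list(rates = r, n_tips = as.integer(n_tips),
                 n_reps = as.integer(n_reps), label = label,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %d trees of %d tips (seed %d)\n",
              x$label, x$n_reps, x$n_tips, x$seed))
  print(x$rates)
  invisible(x)
}

#' Read / write scenario files
#'
#' Scenario files are plain `key = value` text with keys `lambda0`,
#' `lambda1`, `mu0`, `mu1`, `q01`, `q10`, `n_tips`, `n_reps`, `seed`,
#' `label`; lines starting with `#` are comments. The package ships one
#' file per simulation condition of the power study under
#' `system.file("extdata", "scenarios", package = "bissepower")`.
#'
#' @param path File path.
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed scenario line: '", lines[bad][1L], "'")
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = "="), character(1)))
  names(vals) <- keys
  need <- c(RATE_NAMES, "n_tips", "n_reps", "seed")
  miss <- setdiff(need, keys)
  if (length(miss)) stop("scenario file missing keys: ",
                         paste(miss, collapse = ", "))
  num <- stats::setNames(as.numeric(vals[need]), need)
  scenario(rates = as_rate_set(stats::setNames(num[1:6], RATE_NAMES)),
           n_tips = num[["n_tips"]], n_reps = num[["n_reps"]],
           label = if ("label" %in% keys) vals[["label"]] else "",
           seed = num[["seed"]])
}

#' @rdname read_scenario
#' @param x A [scenario()] to write.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "scenario"))
  lines <- c(sprintf("label = %s", x$label),
             sprintf("%s = %.12g", RATE_NAMES, unclass(x$rates)[RATE_NAMES]),
             sprintf("n_tips = %d", x$n_tips),
             sprintf("n_reps = %d", x$n_reps),
             sprintf("seed = %d", x$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tree and its tip states from files
#'
#' The tree is Newick (branch lengths required, no polytomies); states
#' are a two-column tab-separated table (`tip_id`, `state` in 0/1, with
#' or without a header line).
#'
#' @param tree_path Newick file.
#' @param states_path Tab-separated state table.
#' @return A [bisse_data()].
#' @export
read_bisse_data <- function(tree_path, states_path) {
  phy <- ape::read.tree(tree_path)
  if (is.null(phy)) stop("could not parse Newick file: ", tree_path)
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths: ", tree_path)
  if (!ape::is.binary(phy))
    stop("tree contains polytomies: ", tree_path)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  tab <- utils::read.table(states_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("tip_id", "state"))
  if (identical(tolower(tab$tip_id[1L]), "tip_id")) tab <- tab[-1L, ]
  st <- suppressWarnings(as.integer(tab$state))
  names(st) <- tab$tip_id
  bisse_data(phy, st)
}

#' Write a tree and its tip states to files
#'
#' @param x A [bisse_data()].
#' @param tree_path,states_path Output paths (Newick; TSV with a
#'   `tip_id`/`state` header).
#' @export
write_bisse_data <- function(x, tree_path, states_path) {
  stopifnot(inherits(x, "bisse_data"))
  ape::write.tree(x$phy, file = tree_path, digits = 15)
  utils::write.table(
    data.frame(tip_id = names(x$tip_state), state = x$tip_state),
    states_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Write a results object to JSON or CSV
#'
#' Serializes fit results, power estimates and grids with stable field
#' order and a metadata header (package version and seed) so identical
#' runs give byte-identical files.
#'
#' @param object A `"bisse_fit"`, `"bisse_power"` or data frame.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @param seed Optional seed recorded in the metadata.
#' @export
write_results <- function(object, path, format = c("json", "csv"),
                          seed = NULL) {
  format <- match.arg(format)
  meta <- sprintf("bissepower %s seed=%s",
                  as.character(utils::packageVersion("bissepower")),
                  if (is.null(seed)) "NA" else format(seed))
  if (format == "csv") {
    df <- as.data.frame(object)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", meta), con)
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    payload <- results_payload(object)
    payload <- c(list(meta = meta), payload)
    writeLines(to_json(payload), path)
  }
  invisible(path)
}

results_payload <- function(object) {
  if (inherits(object, "bisse_fit")) {
    list(rates = as.list(signif(unclass(object$rates), 12)),
         loglik = signif(object$loglik, 12),
         pattern = pattern_string(object$pattern),
         converged = object$converged,
         n_cycles = object$n_cycles,
         start_index = object$start_index)
  } else if (inherits(object, "bisse_power")) {
    list(label = object$label, process = object$process, pair = object$pair,
         n_tips = object$n_tips, n_reps = object$n_reps,
         critical_value = signif(object$critical_value, 12),
         power = signif(object$power, 12),
         ci_halfwidth = signif(object$ci_halfwidth, 12))
  } else if (is.list(object)) {
    object
  } else stop("cannot serialize object of class ", class(object)[1L])
}

pattern_string <- function(pattern) {
  paste(vapply(pattern$classes, paste, character(1), collapse = "="),
        collapse = ",")
}

# minimal JSON writer for (possibly nested) named lists of scalars
to_json <- function(x) {
  enc <- function(v) {
    if (is.list(v)) {
      parts <- vapply(seq_along(v), function(i)
        sprintf("\"%s\": %s", names(v)[i], enc(v[[i]])), character(1))
      return(paste0("{", paste(parts, collapse = ", "), "}"))
    }
    if (length(v) > 1L) {
      return(paste0("[", paste(vapply(v, enc, character(1)), collapse = ", "), "]"))
    }
    if (is.character(v)) sprintf("\"%s\"", v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 12, scientific = FALSE, trim = TRUE)
  }
  enc(x)
}
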