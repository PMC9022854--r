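# Flat key=value text serialization of a fitted model so a run can be
# audited and re-scored without R object files.

#' Write a fitted index model to a flat text file
#'
#' One `key = value` pair per line (vectors comma-separated, full precision),
#' covering means, scales, loadings, orientation, score range, explained
#' variance, and the config flags. [read_qci_model()] inverts it.
#'
#' @param model A [fit_qci()] model.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_qci_model <- function(model, path) {
  stopifnot(inherits(model, "qci_model"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = ",")
  lines <- c(
    sprintf("ratio_names = %s", paste(RATIO_COLS, collapse = ",")),
    sprintf("means = %s", num(model$means)),
    sprintf("scales = %s", num(model$scales)),
    sprintf("loadings = %s", num(model$loadings)),
    sprintf("orientation = %d", model$orientation),
    sprintf("explained_fraction = %s", num(model$explained_fraction)),
    sprintf("score_min = %s", num(model$score_min)),
    sprintf("score_max = %s", num(model$score_max)),
    sprintf("standardize = %s", model$standardize),
    sprintf("log_transform = %s", model$log_transform),
    sprintf("n_strata = %d", model$n_strata)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a fitted index model from a flat text file
#'
#' @param path Path written by [write_qci_model()].
#' @return A `qci_model` object.
#' @export
read_qci_model <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("File not found: %s", path))
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(
    vapply(kv, function(p) p[2], character(1)),
    vapply(kv, function(p) p[1], character(1))
  )
  nums <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1]])
  structure(
    list(
      means = stats::setNames(nums("means"), RATIO_COLS),
      scales = stats::setNames(nums("scales"), RATIO_COLS),
      loadings = stats::setNames(nums("loadings"), RATIO_COLS),
      orientation = as.integer(vals[["orientation"]]),
      explained_fraction = nums("explained_fraction"),
      score_min = nums("score_min"),
      score_max = nums("score_max"),
      standardize = as.logical(vals[["standardize"]]),
      log_transform = as.logical(vals[["log_transform"]]),
      n_strata = as.integer(vals[["n_strata"]])
    ),
    class = "qci_model"
  )
}
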