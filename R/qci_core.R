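#' Fit the quality of care index on a ratio table
#'
#' The four secondary ratios (mir, prev_inc, daly_prev, yll_yld) are
#' optionally log-transformed, centered, and (by default) scaled to unit
#' variance; the index direction is the leading eigenvector of their
#' correlation (default) or covariance matrix. The component is oriented so
#' that higher scores mean better care (the mir loading is made non-positive;
#' see [orient_component()]), and the min/max of the oriented raw scores over
#' the fitting frame are stored so scores can be rescaled to \[0, 100\].
#'
#' Correlation-matrix PCA is the default because the four ratios live on very
#' different scales (mir below 1, yll_yld often above 10); covariance-mode
#' PCA would let the widest-ranging ratio dominate the component.
#'
#' @param ratios Ratio table as returned by [compute_ratios()]; must contain
#'   the four ratio columns and at least 3 rows.
#' @param standardize Scale each ratio to unit variance (correlation PCA,
#'   default TRUE). FALSE gives covariance-matrix PCA (still centered).
#' @param log_transform Natural-log transform the ratios before PCA (default
#'   FALSE); useful for heavy-tailed yll_yld. Requires strictly positive
#'   ratios. Recorded in the model so scoring matches fitting.
#' @return An object of class `qci_model`: centering means, scales, unit-norm
#'   loadings, orientation sign, explained variance fraction, raw-score min
#'   and max over the fitting frame, and the config flags.
#' @export
fit_qci <- function(ratios, standardize = TRUE, log_transform = FALSE) {
  missing_cols <- setdiff(RATIO_COLS, names(ratios))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "Ratio table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as.matrix(ratios[RATIO_COLS])
  if (nrow(x) < 3) {
    abort_data(sprintf(
      "At least 3 strata are required to fit the index (got %d).", nrow(x)
    ))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    abort_validation("Ratios must be finite and non-negative.")
  }
  if (log_transform) {
    if (any(x <= 0)) {
      abort_validation("log_transform requires strictly positive ratios.")
    }
    x <- log(x)
  }

  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero_var <- sds < .Machine$double.eps^0.5
  if (any(zero_var)) {
    abort_degenerate(sprintf(
      "Zero-variance ratio column(s): %s",
      paste(RATIO_COLS[zero_var], collapse = ", ")
    ))
  }
  scales <- if (standardize) sds else rep(1, 4)
  z <- sweep(sweep(x, 2, means, "-"), 2, scales, "/")

  s <- stats::cov(z)
  eig <- eigen(s, symmetric = TRUE)
  # Tie on the leading eigenvalue: take the eigenvector with the larger
  # |mir| loading so the fit is deterministic.
  lead <- which(abs(eig$values - eig$values[1]) < 1e-12 * max(1, abs(eig$values[1])))
  if (length(lead) > 1) {
    pick <- lead[which.max(abs(eig$vectors[1, lead]))]
  } else {
    pick <- 1L
  }
  loadings <- eig$vectors[, pick]
  loadings <- loadings / sqrt(sum(loadings^2))
  names(loadings) <- RATIO_COLS

  orientation <- orient_component(loadings)
  explained_fraction <- eig$values[pick] / sum(eig$values)

  raw <- as.numeric(z %*% loadings) * orientation
  score_min <- min(raw)
  score_max <- max(raw)
  if (score_max - score_min < .Machine$double.eps^0.5) {
    abort_degenerate("Raw component scores are constant; cannot rescale.")
  }

  structure(
    list(
      means = means,
      scales = stats::setNames(scales, RATIO_COLS),
      loadings = loadings,
      orientation = orientation,
      explained_fraction = explained_fraction,
      score_min = score_min,
      score_max = score_max,
      standardize = standardize,
      log_transform = log_transform,
      n_strata = nrow(x)
    ),
    class = "qci_model"
  )
}

#' Orientation sign for an index component
#'
#' PCA determines loadings only up to sign; the index requires higher = better
#' care. Since a higher mortality-to-incidence ratio always means worse care,
#' the sign is chosen so the oriented mir loading is non-positive. If the mir
#' loading is exactly zero, the decision falls through the other
#' "higher = worse" ratios (yll_yld, then daly_prev), and finally to making
#' the prev_inc loading ("higher = better") non-negative.
#'
#' @param loadings Unit-norm numeric 4-vector in order
#'   (mir, prev_inc, daly_prev, yll_yld).
#' @return `+1` or `-1`.
#' @export
orient_component <- function(loadings) {
  if (all(loadings == 0)) {
    abort_degenerate("All loadings are zero; cannot orient.")
  }
  for (val in c(loadings[1], loadings[4], loadings[3], -loadings[2])) {
    if (val > 0) return(-1)
    if (val < 0) return(1)
  }
  1
}

#' @export
print.qci_model <- function(x, ...) {
  cat("Quality of care index model\n")
  cat(sprintf("  fitted on %d strata (%s PCA%s)\n", x$n_strata,
              if (x$standardize) "correlation" else "covariance",
              if (x$log_transform) ", log-transformed ratios" else ""))
  cat("  loadings (oriented):\n")
  l <- x$loadings * x$orientation
  for (nm in names(l)) cat(sprintf("    %-9s % .4f\n", nm, l[[nm]]))
  cat(sprintf("  explained variance fraction: %.3f\n", x$explained_fraction))
  cat(sprintf("  raw score range: [%.4f, %.4f]\n", x$score_min, x$score_max))
  invisible(x)
}

#' Score strata with a fitted index model
#'
#' The raw score of a stratum is the oriented dot product of its standardized
#' ratio vector with the loadings; the index is the affine rescale
#' `100 * (raw - score_min) / (score_max - score_min)`, so strata from the
#' fitting frame land in \[0, 100\] with the extremes attaining exactly 0 and
#' 100. Strata outside the fitting frame may fall outside the range; they are
#' flagged in an `out_of_range` column and clamped only if `clamp = TRUE`.
#'
#' @param model A fitted [fit_qci()] model.
#' @param ratios Ratio table to score (frame keys + the four ratio columns).
#' @param clamp Clamp out-of-range scores into \[0, 100\] (default FALSE).
#' @return The input's key columns plus `qci` (full precision) and
#'   `out_of_range`. Use [round()] to 1 decimal for reporting.
#' @export
score_qci <- function(model, ratios, clamp = FALSE) {
  stopifnot(inherits(model, "qci_model"))
  if (model$score_max - model$score_min < .Machine$double.eps^0.5) {
    abort_degenerate("Model has score_max == score_min; cannot rescale.")
  }
  x <- as.matrix(ratios[RATIO_COLS])
  if (model$log_transform) {
    if (any(x <= 0)) {
      abort_validation("Model was fit on log ratios; scoring needs positive ratios.")
    }
    x <- log(x)
  }
  z <- sweep(sweep(x, 2, model$means, "-"), 2, model$scales, "/")
  raw <- as.numeric(z %*% model$loadings) * model$orientation
  qci <- 100 * (raw - model$score_min) / (model$score_max - model$score_min)
  out_of_range <- qci < 0 | qci > 100
  if (clamp) qci <- pmin(pmax(qci, 0), 100)
  out <- ratios[setdiff(names(ratios), RATIO_COLS)]
  out$qci <- qci
  out$out_of_range <- out_of_range
  tibble::as_tibble(out)
}

#' Share of total variance on the index component
#'
#' @param model A fitted [fit_qci()] model.
#' @return The leading eigenvalue divided by the trace (in (0, 1\]). Under
#'   correlation PCA this equals the leading eigenvalue / 4.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "qci_model"))
  model$explained_fraction
}

#' Correlate index scores with a reference quality measure
#'
#' Matches strata between a scored index table and a reference series on the
#' shared key columns and reports the Pearson product-moment correlation plus
#' a Spearman companion (monotone association).
#'
#' @param qci Scored table with a `qci` column.
#' @param reference Table with the same key columns and a `reference` column
#'   (any per-stratum quality measure, e.g. an external coverage index or the
#'   latent truth of a synthetic run).
#' @param by Key columns to match on; default: all shared non-value columns.
#' @return List with `pearson`, `spearman`, and `n_matched`.
#' @export
correlate_with_reference <- function(qci, reference, by = NULL) {
  if (is.null(by)) {
    by <- setdiff(intersect(names(qci), names(reference)),
                  c("qci", "reference", "out_of_range"))
  }
  if (length(by) == 0) abort_config("No shared key columns to match on.")
  matched <- dplyr::inner_join(qci, reference, by = by)
  if (nrow(matched) < 3) {
    abort_data(sprintf(
      "Need at least 3 matched strata to correlate (got %d).", nrow(matched)
    ))
  }
  if (stats::sd(matched$qci) == 0 || stats::sd(matched$reference) == 0) {
    abort_degenerate("Correlation undefined: a series has zero variance.")
  }
  list(
    pearson = stats::cor(matched$qci, matched$reference, method = "pearson"),
    spearman = stats::cor(matched$qci, matched$reference, method = "spearman"),
    n_matched = nrow(matched)
  )
}
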