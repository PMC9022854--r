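#' Simulate a synthetic measure table and write it to disk
#'
#' Writes two CSVs: the GBD-shaped measure table and the latent truth table
#' (location, year, sex, q, sdi) used to generate it, plus a settings
#' manifest recording every generator parameter and the seed so the run can
#' be reproduced bit-identically.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [synthetic_config()]; `seed` (if given) overrides its seed.
#' @param seed Optional integer seed override.
#' @return Invisibly, a named list of the written file paths.
#' @export
cmd_simulate <- function(out_dir, config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  latent <- simulate_latent(config)
  measures <- simulate_measures(latent, config)

  paths <- list(
    measures = file.path(out_dir, "measures.csv"),
    truth = file.path(out_dir, "latent_truth.csv"),
    manifest = file.path(out_dir, "simulate_manifest.txt")
  )
  write_measure_table(measures, paths$measures)
  readr::write_csv(latent, paths$truth, progress = FALSE)
  write_manifest(config[setdiff(names(config), "age_bins")],
                 extra = list(age_bins = paste(config$age_bins, collapse = ",")),
                 path = paths$manifest)
  invisible(paths)
}

write_manifest <- function(settings, extra = list(), path) {
  all <- c(settings, extra)
  fmt <- vapply(all, function(v) paste(format(v, digits = 17), collapse = ","),
                character(1))
  writeLines(sprintf("%s = %s", names(all), fmt), path)
  invisible(path)
}

#' Run the full index pipeline on a measure table
#'
#' Stages: secondary ratios (with exclusion log) -> index fit -> scoring ->
#' gender disparity ratio -> SDI quintile assignment (when an `sdi` column is
#' present) -> summary tables. All outputs are CSV; the fitted model is a
#' flat key=value text file; a manifest records every setting.
#'
#' `fit_scope` controls the fitting frame:
#' \describe{
#'   \item{pooled}{one fit on all location-year-sex strata at the
#'     age-standardized level (default) — female and male scores share one
#'     scale, as the gender disparity ratio requires;}
#'   \item{per_sex}{separate fit and 0-100 rescale within each sex;}
#'   \item{per_age}{fit within each age group, on location-year-sex strata.}
#' }
#'
#' @param input Path to a measure CSV, or a measure table.
#' @param out_dir Output directory (created if missing).
#' @param fit_scope `"pooled"`, `"per_sex"`, or `"per_age"`.
#' @param standardize,log_transform Passed to [fit_qci()].
#' @param clamp Passed to [score_qci()].
#' @param quintile_method,cutpoints Passed to [assign_sdi_quintiles()].
#' @param rounding Decimals for reported scores in CSV outputs (default 1;
#'   full precision is kept in the returned objects).
#' @return Invisibly, a list with `ratios`, `exclusions`, `model` (or models
#'   per scope group), `qci`, `gdr`, `gdr_skipped`, `summaries`, and the
#'   output `paths`.
#' @export
cmd_run <- function(input, out_dir,
                    fit_scope = c("pooled", "per_sex", "per_age"),
                    standardize = TRUE, log_transform = FALSE,
                    clamp = FALSE,
                    quintile_method = "rank", cutpoints = NULL,
                    rounding = 1) {
  fit_scope <- match.arg(fit_scope)
  table <- if (is.character(input)) read_measure_table(input) else input
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, qcindex_error = function(e) {
      rlang::abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
                   class = class(e)[1], parent = e)
    })
  }

  frame <- if (fit_scope == "per_age") {
    c("location", "year", "sex", "age_group")
  } else {
    c("location", "year", "sex")
  }
  rat <- stage("ratios", compute_ratios(table, frame = frame))
  ratios <- rat$ratios

  group_col <- switch(fit_scope, pooled = NULL, per_sex = "sex",
                      per_age = "age_group")
  fit_score <- function(df) {
    model <- fit_qci(df, standardize = standardize,
                     log_transform = log_transform)
    list(model = model, qci = score_qci(model, df, clamp = clamp))
  }
  if (is.null(group_col)) {
    fs <- stage("fit", fit_score(ratios))
    models <- list(pooled = fs$model)
    qci <- fs$qci
  } else {
    groups <- split(ratios, ratios[[group_col]])
    fss <- stage("fit", lapply(groups, fit_score))
    models <- lapply(fss, `[[`, "model")
    qci <- dplyr::bind_rows(lapply(fss, `[[`, "qci"))
  }

  gdr_res <- if ("sex" %in% names(qci) &&
                 any(qci$sex %in% c("female", "male"))) {
    stage("gdr", compute_gdr(qci))
  } else {
    list(gdr = NULL, skipped = NULL)
  }

  quintiles <- NULL
  if ("sdi" %in% names(qci) && length(unique(qci$location)) >= 5) {
    quintiles <- stage("quintiles", assign_sdi_quintiles(
      qci[c("location", "year", "sdi")],
      method = quintile_method, cutpoints = cutpoints
    ))
  }

  summaries <- list()
  if (!is.null(quintiles)) {
    qq <- dplyr::left_join(qci, quintiles[c("location", "year", "quintile")],
                           by = c("location", "year"))
    summaries$qci_by_quintile <- summarize_by(
      qq, grouping = c("quintile", "year", if ("sex" %in% names(qq)) "sex")
    )
    if (!is.null(gdr_res$gdr)) {
      gq <- dplyr::left_join(gdr_res$gdr,
                             quintiles[c("location", "year", "quintile")],
                             by = c("location", "year"))
      summaries$gdr_by_quintile <- summarize_by(
        gq, grouping = c("quintile", "year"), value = "gdr"
      )
    }
  }

  paths <- list(
    ratios = file.path(out_dir, "ratios.csv"),
    exclusions = file.path(out_dir, "exclusions.csv"),
    qci = file.path(out_dir, "qci.csv"),
    manifest = file.path(out_dir, "run_manifest.txt")
  )
  readr::write_csv(ratios, paths$ratios, progress = FALSE)
  readr::write_csv(rat$exclusions, paths$exclusions, progress = FALSE)
  qci_out <- qci
  qci_out$qci <- round(qci_out$qci, rounding)
  readr::write_csv(qci_out, paths$qci, progress = FALSE)
  for (nm in names(models)) {
    p <- file.path(out_dir, sprintf("model_%s.txt", nm))
    write_qci_model(models[[nm]], p)
    paths[[paste0("model_", nm)]] <- p
  }
  if (!is.null(gdr_res$gdr)) {
    paths$gdr <- file.path(out_dir, "gdr.csv")
    gdr_out <- gdr_res$gdr
    gdr_out$gdr <- round(gdr_out$gdr, rounding)
    readr::write_csv(gdr_out, paths$gdr, progress = FALSE)
    paths$gdr_skipped <- file.path(out_dir, "gdr_skipped.csv")
    readr::write_csv(gdr_res$skipped, paths$gdr_skipped, progress = FALSE)
  }
  if (!is.null(quintiles)) {
    paths$quintiles <- file.path(out_dir, "sdi_quintiles.csv")
    readr::write_csv(quintiles, paths$quintiles, progress = FALSE)
  }
  for (nm in names(summaries)) {
    p <- file.path(out_dir, sprintf("summary_%s.csv", nm))
    readr::write_csv(summaries[[nm]], p, progress = FALSE)
    paths[[paste0("summary_", nm)]] <- p
  }
  write_manifest(
    list(fit_scope = fit_scope, standardize = standardize,
         log_transform = log_transform, clamp = clamp,
         quintile_method = quintile_method,
         cutpoints = if (is.null(cutpoints)) "none" else cutpoints,
         rounding = rounding),
    path = paths$manifest
  )

  invisible(list(ratios = ratios, exclusions = rat$exclusions,
                 models = models, qci = qci, gdr = gdr_res$gdr,
                 gdr_skipped = gdr_res$skipped, quintiles = quintiles,
                 summaries = summaries, paths = paths))
}

#' Validate index scores against a reference series
#'
#' Matches a scored index CSV with a reference CSV on their shared key
#' columns and reports Pearson and Spearman correlations with the matched
#' stratum count.
#'
#' @param qci Path to a scored index CSV (column `qci`) or such a table.
#' @param reference Path to a reference CSV or table; its value column
#'   (anything not a key, e.g. `q`, `uhc`, `reference`) is used.
#' @param value Name of the reference value column; default: auto-detect.
#' @return List with `pearson`, `spearman`, `n_matched`.
#' @export
cmd_validate <- function(qci, reference, value = NULL) {
  qtbl <- if (is.character(qci)) {
    readr::read_csv(qci, show_col_types = FALSE, progress = FALSE)
  } else qci
  rtbl <- if (is.character(reference)) {
    readr::read_csv(reference, show_col_types = FALSE, progress = FALSE)
  } else reference
  if (is.null(value)) {
    candidates <- setdiff(names(rtbl),
                          c("location", "year", "sex", "age_group", "sdi"))
    if (length(candidates) == 0) {
      abort_schema("Reference table has no value column.")
    }
    value <- candidates[1]
  }
  rtbl$reference <- rtbl[[value]]
  keep <- unique(c(setdiff(names(rtbl), value), "reference"))
  correlate_with_reference(qtbl, rtbl[keep])
}
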