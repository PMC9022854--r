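SDI_QUINTILES <- c("low", "low-middle", "middle", "high-middle", "high")

#' Gender disparity ratio: female index score divided by male
#'
#' For every stratum (all key columns except `sex`) that has both a female
#' and a male score, computes `gdr = female qci / male qci` on the
#' full-precision scores — dividing scores already rounded for reporting
#' would inject spurious disparity. Values above 1 indicate better quality of
#' care for females, below 1 better for males, 1 parity. Strata missing
#' either sex, or with male score 0 (ratio undefined), are omitted and
#' logged.
#'
#' @param qci Scored table from [score_qci()] with a `sex` column containing
#'   `"female"` and/or `"male"` rows (`"both"` rows are ignored).
#' @return List with `gdr` (stratum keys + `qci_female`, `qci_male`, `gdr`)
#'   and `skipped` (stratum keys + `reason` in
#'   `{missing_female, missing_male, zero_male}`). Round `gdr` to 1 decimal
#'   for reporting.
#' @export
compute_gdr <- function(qci) {
  if (!"sex" %in% names(qci)) abort_schema("QCI table has no `sex` column.")
  if (!"qci" %in% names(qci)) abort_schema("Table has no `qci` column.")
  keys <- setdiff(names(qci), c("sex", "qci", "out_of_range", "sdi"))
  sexed <- dplyr::filter(qci, .data$sex %in% c("female", "male"))
  if (nrow(sexed) == 0) abort_data("No female/male rows in the QCI table.")
  wide <- tidyr::pivot_wider(
    sexed[c(keys, "sex", "qci")],
    names_from = "sex", values_from = "qci", names_prefix = "qci_"
  )
  if (!"qci_female" %in% names(wide)) wide$qci_female <- NA_real_
  if (!"qci_male" %in% names(wide)) wide$qci_male <- NA_real_

  reason <- rep(NA_character_, nrow(wide))
  reason[is.na(wide$qci_female)] <- "missing_female"
  reason[is.na(wide$qci_male)] <- "missing_male"
  reason[!is.na(wide$qci_male) & !is.na(wide$qci_female) &
           wide$qci_male == 0] <- "zero_male"

  skipped <- wide[!is.na(reason), keys, drop = FALSE]
  skipped$reason <- reason[!is.na(reason)]

  kept <- wide[is.na(reason), , drop = FALSE]
  kept$gdr <- kept$qci_female / kept$qci_male
  list(gdr = tibble::as_tibble(kept), skipped = tibble::as_tibble(skipped))
}

#' Assign SDI quintiles to locations
#'
#' Partitions locations into the five socio-demographic index bands (low,
#' low-middle, middle, high-middle, high). In `rank` mode the 20/40/60/80th
#' percentiles of SDI over locations in a reference year (default: the latest
#' year present) define the boundaries; `fixed_cutpoints` mode takes
#' user-supplied boundaries, e.g. published cut-offs, so results can be
#' replicated against an external quintile table. A location keeps its
#' reference-year quintile in every year. Percentile ties are broken by
#' ranking on (sdi, location) so assignment is stable and row-order
#' independent.
#'
#' @param sdi Table with columns `location`, `year`, `sdi` (in \[0, 1\]).
#' @param method `"rank"` (default) or `"fixed_cutpoints"`.
#' @param cutpoints Increasing numeric 4-vector of boundaries for
#'   `fixed_cutpoints` mode.
#' @param reference_year Year whose SDI values define rank-mode boundaries.
#' @return The distinct location-year table with a `quintile` factor column
#'   (levels low < low-middle < middle < high-middle < high).
#' @export
assign_sdi_quintiles <- function(sdi,
                                 method = c("rank", "fixed_cutpoints"),
                                 cutpoints = NULL,
                                 reference_year = NULL) {
  method <- match.arg(method)
  need <- c("location", "year", "sdi")
  if (!all(need %in% names(sdi))) {
    abort_schema(sprintf(
      "SDI table is missing column(s): %s",
      paste(setdiff(need, names(sdi)), collapse = ", ")
    ))
  }
  if (any(!is.finite(sdi$sdi) | sdi$sdi < 0 | sdi$sdi > 1)) {
    abort_validation("sdi values must be finite and in [0, 1].")
  }
  tbl <- dplyr::distinct(tibble::as_tibble(sdi[need]))
  if (is.null(reference_year)) reference_year <- max(tbl$year)
  ref <- tbl[tbl$year == reference_year, ]
  ref <- ref[!duplicated(ref$location), ]
  if (nrow(ref) == 0) {
    abort_data(sprintf("No SDI rows in reference year %s.", reference_year))
  }

  if (method == "rank") {
    if (nrow(ref) < 5) {
      abort_data(sprintf(
        "Rank mode needs at least 5 locations (got %d).", nrow(ref)
      ))
    }
    if (anyDuplicated(ref$sdi)) {
      warning("Tied SDI values; quintiles assigned by stable (sdi, location) order.")
    }
    ord <- order(ref$sdi, ref$location)
    idx <- integer(nrow(ref))
    idx[ord] <- seq_len(nrow(ref))
    q <- ceiling(5 * idx / nrow(ref))
    ref$quintile <- factor(SDI_QUINTILES[q], levels = SDI_QUINTILES)
  } else {
    if (is.null(cutpoints) || length(cutpoints) != 4 ||
        is.unsorted(cutpoints, strictly = TRUE)) {
      abort_config("`cutpoints` must be a strictly increasing numeric 4-vector.")
    }
    band <- findInterval(ref$sdi, cutpoints) + 1L
    ref$quintile <- factor(SDI_QUINTILES[band], levels = SDI_QUINTILES)
  }
  dplyr::left_join(tbl, ref[c("location", "quintile")], by = "location")
}

#' Group-wise summaries of index or disparity tables
#'
#' Aggregates a value column over grouping keys with either a plain mean or a
#' population-weighted mean (sum(w*x)/sum(w)); supports age/SDI/region
#' profile tables.
#'
#' @param tbl Input table.
#' @param grouping Character vector of grouping columns.
#' @param value Name of the value column (default `"qci"`).
#' @param aggregator `"mean"` or `"population_weighted_mean"`.
#' @param weight Name of the weight column (required for the weighted mean).
#' @return One row per group with the aggregate in `value`'s name plus `n`
#'   (rows aggregated) and `n_missing` (NA values skipped).
#' @export
summarize_by <- function(tbl, grouping, value = "qci",
                         aggregator = c("mean", "population_weighted_mean"),
                         weight = NULL) {
  aggregator <- match.arg(aggregator)
  bad <- setdiff(c(grouping, value, weight), names(tbl))
  if (length(bad) > 0) {
    abort_config(sprintf("Unknown column(s): %s", paste(bad, collapse = ", ")))
  }
  if (aggregator == "population_weighted_mean" && is.null(weight)) {
    abort_config("population_weighted_mean requires a `weight` column.")
  }
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_missing = sum(is.na(.data[[value]])),
      "{value}" := if (aggregator == "mean") {
        mean(.data[[value]], na.rm = TRUE)
      } else {
        ok <- !is.na(.data[[value]]) & !is.na(.data[[weight]])
        sum(.data[[value]][ok] * .data[[weight]][ok]) /
          sum(.data[[weight]][ok])
      },
      .groups = "drop"
    )
}
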