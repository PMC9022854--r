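#' @importFrom rlang .data
NULL

MEASURE_LEVELS <- c("incidence", "deaths", "prevalence", "yll", "yld", "daly")
SEX_LEVELS <- c("female", "male", "both")
SCHEMA_COLS <- c("location", "year", "sex", "age_group", "measure", "value")
KEY_COLS <- c("location", "year", "sex", "age_group", "measure")

AGE_STANDARDIZED <- "age-standardized"
ALL_AGES <- "all-ages"

#' GBD-convention 5-year age bin labels
#'
#' Labels run from "0-4" in 5-year steps up to an open-ended top bin
#' (default "95+").
#'
#' @param top Lower bound of the open-ended top bin (multiple of 5).
#' @return Character vector of age-bin labels.
#' @export
#' @examples
#' gbd_age_bins()
gbd_age_bins <- function(top = 95) {
  if (top < 5 || top %% 5 != 0) {
    abort_config("`top` must be a positive multiple of 5.")
  }
  lower <- seq(0, top - 5, by = 5)
  c(paste0(lower, "-", lower + 4), paste0(top, "+"))
}

#' Midpoints of 5-year age bins
#'
#' The open-ended top bin "x+" is given midpoint x + 2.5.
#'
#' @param age_bins Character vector of bin labels as from [gbd_age_bins()].
#' @return Numeric vector of midpoints in years.
#' @export
age_bin_midpoints <- function(age_bins) {
  lower <- as.numeric(sub("[-+].*$|\\+$", "", age_bins))
  lower + 2.5
}

#' Construct a reference age standard
#'
#' A standard population expressed as weights over age groups; weights must
#' sum to 1. The default is equal weight on every bin, which keeps the
#' standard explicit rather than hiding a particular reference population.
#'
#' @param age_groups Character vector of age-bin labels.
#' @param weights Numeric weights, one per group, summing to 1 (tolerance
#'   1e-9). Default: equal weights.
#' @return A tibble of class `age_standard` with columns `age_group`, `weight`.
#' @export
age_standard <- function(age_groups = gbd_age_bins(),
                         weights = rep(1 / length(age_groups), length(age_groups))) {
  if (length(age_groups) != length(weights)) {
    abort_config("`age_groups` and `weights` must have the same length.")
  }
  if (anyDuplicated(age_groups)) {
    abort_config("Age groups in a standard must be unique.")
  }
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1)) {
    abort_config("Standard weights must be finite and in [0, 1].")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort_config(sprintf(
      "Standard weights must sum to 1 (got %.12f).", sum(weights)
    ))
  }
  out <- tibble::tibble(age_group = as.character(age_groups), weight = weights)
  class(out) <- c("age_standard", class(out))
  out
}

#' Direct age standardization
#'
#' Computes the weighted sum of age-specific rates under a reference age
#' standard: sum over age groups of weight * rate. Units are preserved
#' (rates per 100,000 in, per 100,000 out).
#'
#' @param rates Named numeric vector of age-specific rates (names are age-bin
#'   labels), or a data frame with columns `age_group` and `value`.
#' @param standard An [age_standard()].
#' @return The age-standardized rate (scalar).
#' @export
#' @examples
#' std <- age_standard(c("0-49", "50+"), c(0.5, 0.5))
#' age_standardize(c("0-49" = 10, "50+" = 30), std) # 20
age_standardize <- function(rates, standard) {
  if (!inherits(standard, "age_standard")) {
    standard <- age_standard(standard$age_group, standard$weight)
  }
  if (is.data.frame(rates)) {
    rates <- stats::setNames(rates$value, rates$age_group)
  }
  missing_groups <- setdiff(standard$age_group, names(rates))
  if (length(missing_groups) > 0) {
    abort_data(sprintf(
      "Age groups missing from rates: %s",
      paste(missing_groups, collapse = ", ")
    ))
  }
  sum(standard$weight * rates[standard$age_group])
}

validate_measure_table <- function(tbl, strict = TRUE, origin = "measure table") {
  missing_cols <- setdiff(SCHEMA_COLS, names(tbl))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "%s is missing required column(s): %s",
      origin, paste(missing_cols, collapse = ", ")
    ))
  }
  bad_sex <- !tbl$sex %in% SEX_LEVELS
  if (any(bad_sex)) {
    abort_validation(sprintf(
      "Invalid sex value(s) at row(s) %s (allowed: %s).",
      paste(utils::head(which(bad_sex), 5), collapse = ", "),
      paste(SEX_LEVELS, collapse = ", ")
    ))
  }
  bad_measure <- !tbl$measure %in% MEASURE_LEVELS
  if (any(bad_measure)) {
    abort_validation(sprintf(
      "Invalid measure value(s) at row(s) %s (allowed: %s).",
      paste(utils::head(which(bad_measure), 5), collapse = ", "),
      paste(MEASURE_LEVELS, collapse = ", ")
    ))
  }
  bad_value <- !is.finite(tbl$value) | tbl$value < 0
  if (any(bad_value)) {
    abort_validation(sprintf(
      "Values must be finite and non-negative; offending row(s): %s",
      paste(utils::head(which(bad_value), 5), collapse = ", ")
    ))
  }
  if (strict) {
    key <- do.call(paste, c(tbl[KEY_COLS], sep = "\r"))
    if (anyDuplicated(key)) {
      abort_validation(sprintf(
        "Duplicate (location, year, sex, age_group, measure) key(s) at row(s): %s",
        paste(utils::head(which(duplicated(key)), 5), collapse = ", ")
      ))
    }
  }
  invisible(tbl)
}

#' Read a long-format measure table from CSV
#'
#' Expects the six schema columns `location`, `year`, `sex`, `age_group`,
#' `measure`, `value`; an optional `sdi` column (real in \[0, 1\]) is carried
#' through; other extra columns are ignored. Measures are the six burden
#' measures `incidence`, `deaths`, `prevalence`, `yll`, `yld`, `daly`, as
#' rates per 100,000. Case of `sex`/`measure` labels is normalized to lower.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, "." decimal,
#'   header required).
#' @param strict Reject duplicated (location, year, sex, age_group, measure)
#'   keys (default TRUE).
#' @return A validated tibble in input row order.
#' @export
read_measure_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort_data(sprintf("File not found: %s", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(SCHEMA_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "CSV %s is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  keep <- intersect(c(SCHEMA_COLS, "sdi"), names(raw))
  tbl <- raw[keep]
  tbl$location <- as.character(tbl$location)
  tbl$year <- as.integer(tbl$year)
  tbl$sex <- tolower(as.character(tbl$sex))
  tbl$age_group <- as.character(tbl$age_group)
  tbl$measure <- tolower(as.character(tbl$measure))
  tbl$value <- as.numeric(tbl$value)
  if ("sdi" %in% names(tbl)) {
    bad_sdi <- !is.na(tbl$sdi) & (tbl$sdi < 0 | tbl$sdi > 1)
    if (any(bad_sdi)) {
      abort_validation(sprintf(
        "sdi must lie in [0, 1]; offending row(s): %s",
        paste(utils::head(which(bad_sdi), 5), collapse = ", ")
      ))
    }
  }
  validate_measure_table(tbl, strict = strict, origin = path)
  tbl
}

#' Write a measure table to CSV
#'
#' Inverse of [read_measure_table()]: reading the written file reproduces the
#' table field-for-field.
#'
#' @param table A validated measure table.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_measure_table <- function(table, path) {
  validate_measure_table(table, strict = FALSE)
  keep <- intersect(c(SCHEMA_COLS, "sdi"), names(table))
  readr::write_csv(table[keep], path, progress = FALSE)
  invisible(path)
}

#' Append age-standardized rows to an age-specific measure table
#'
#' For every (location, year, sex, measure) stratum, computes the
#' age-standardized rate over the standard's age groups and appends it as a
#' row with `age_group = "age-standardized"`. An `sdi` column, if present, is
#' carried through (taken as constant within a location-year-sex stratum).
#'
#' @param table Measure table with age-specific rows.
#' @param standard An [age_standard()]; every standard age group must be
#'   present in each stratum.
#' @return The table with age-standardized rows appended.
#' @export
add_age_standardized <- function(table, standard = age_standard()) {
  validate_measure_table(table, strict = FALSE)
  age_rows <- dplyr::filter(
    table, !.data$age_group %in% c(AGE_STANDARDIZED, ALL_AGES)
  )
  asr <- age_rows |>
    dplyr::group_by(.data$location, .data$year, .data$sex, .data$measure) |>
    dplyr::group_modify(function(df, key) {
      val <- age_standardize(
        stats::setNames(df$value, df$age_group), standard
      )
      out <- tibble::tibble(age_group = AGE_STANDARDIZED, value = val)
      if ("sdi" %in% names(df)) out$sdi <- df$sdi[1]
      out
    }) |>
    dplyr::ungroup()
  dplyr::bind_rows(table, asr[names(table)[names(table) %in% names(asr)]])
}
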