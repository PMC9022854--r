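RATIO_COLS <- c("mir", "prev_inc", "daly_prev", "yll_yld")
EXCLUSION_REASONS <- c("zero_incidence", "zero_prevalence", "zero_yld",
                       "missing_measure")

#' Transform the six primary measures into the four secondary ratios
#'
#' For each stratum, computes the four ratios the index is built from:
#' \describe{
#'   \item{mir}{deaths / incidence (mortality-to-incidence). Higher is worse:
#'     at stable incidence, more deaths mean worse care.}
#'   \item{prev_inc}{prevalence / incidence. Higher is better: at similar
#'     incidence, higher prevalence reflects management that keeps patients
#'     alive.}
#'   \item{daly_prev}{DALY / prevalence. Higher is worse: more healthy life
#'     lost per prevalent case.}
#'   \item{yll_yld}{YLL / YLD. Higher is worse: the health system is failing
#'     to postpone deaths relative to disability.}
#' }
#'
#' A stratum yields a ratio record only when all six measures are present and
#' the three denominators (incidence, prevalence, YLD) are strictly positive;
#' otherwise it is excluded and logged with a reason. This mirrors the manual
#' inspection of measures for zero estimates that precedes index fitting. An
#' epsilon-imputation mode (`zero_policy = "epsilon"`) replaces zero
#' denominators by `epsilon` instead of dropping; it is off by default because
#' imputation silently distorts the PCA loadings.
#'
#' Ratios are computed from rates, not counts; the stratum population cancels,
#' so both give the same value.
#'
#' @param table Measure table (see [read_measure_table()]).
#' @param frame Character vector of grouping keys defining a stratum.
#'   Default: `c("location", "year", "sex")` at the age-standardized level.
#' @param age_level Which `age_group` level to use when `"age_group"` is not
#'   itself in `frame` (default `"age-standardized"`). Ignored when the frame
#'   includes `age_group`.
#' @param zero_policy `"exclude"` (default) or `"epsilon"`.
#' @param epsilon Replacement for non-positive denominators under the epsilon
#'   policy.
#' @return A list with `ratios` (one row per retained stratum: frame keys,
#'   the four ratio columns, and `sdi` if present) and `exclusions` (frame
#'   keys + `reason`).
#' @export
compute_ratios <- function(table,
                           frame = c("location", "year", "sex"),
                           age_level = AGE_STANDARDIZED,
                           zero_policy = c("exclude", "epsilon"),
                           epsilon = 1e-6) {
  zero_policy <- match.arg(zero_policy)
  validate_measure_table(table, strict = FALSE)
  if (!all(frame %in% names(table))) {
    abort_config(sprintf(
      "Frame key(s) not in table: %s",
      paste(setdiff(frame, names(table)), collapse = ", ")
    ))
  }
  if (!"age_group" %in% frame) {
    table <- dplyr::filter(table, .data$age_group == age_level)
    if (nrow(table) == 0) {
      abort_data(sprintf("No rows at age_group level '%s'.", age_level))
    }
  }

  has_sdi <- "sdi" %in% names(table)
  id_cols <- if (has_sdi) c(frame, "sdi") else frame
  wide <- tidyr::pivot_wider(
    table[c(id_cols, "measure", "value")],
    id_cols = dplyr::all_of(id_cols),
    names_from = "measure", values_from = "value",
    values_fn = function(v) v[1]
  )
  for (m in setdiff(MEASURE_LEVELS, names(wide))) wide[[m]] <- NA_real_

  missing_any <- !stats::complete.cases(wide[MEASURE_LEVELS])
  reason <- rep(NA_character_, nrow(wide))
  reason[missing_any] <- "missing_measure"
  zero_den <- !missing_any & wide$incidence <= 0
  reason[zero_den] <- "zero_incidence"
  zero_prev <- !missing_any & !zero_den & wide$prevalence <= 0
  reason[zero_prev] <- "zero_prevalence"
  zero_yld <- !missing_any & !zero_den & !zero_prev & wide$yld <= 0
  reason[zero_yld] <- "zero_yld"

  if (zero_policy == "epsilon") {
    keep <- !missing_any
    wide$incidence <- pmax(wide$incidence, epsilon)
    wide$prevalence <- pmax(wide$prevalence, epsilon)
    wide$yld <- pmax(wide$yld, epsilon)
  } else {
    keep <- is.na(reason)
  }
  excluded <- if (zero_policy == "epsilon") missing_any else !is.na(reason)

  exclusions <- wide[excluded, frame, drop = FALSE]
  exclusions$reason <- reason[excluded]

  kept <- wide[keep, , drop = FALSE]
  ratios <- kept[c(frame, if (has_sdi) "sdi")]
  ratios$mir <- kept$deaths / kept$incidence
  ratios$prev_inc <- kept$prevalence / kept$incidence
  ratios$daly_prev <- kept$daly / kept$prevalence
  ratios$yll_yld <- kept$yll / kept$yld

  if (nrow(ratios) == 0) {
    abort_data("No stratum survived ratio computation; nothing to index.")
  }
  list(ratios = tibble::as_tibble(ratios),
       exclusions = tibble::as_tibble(exclusions))
}

#' Tally an exclusion log by reason
#'
#' @param log Exclusion log as returned by [compute_ratios()].
#' @return Named integer vector over all exclusion reasons; sums to
#'   `nrow(log)`.
#' @export
summarize_exclusions <- function(log) {
  counts <- table(factor(log$reason, levels = EXCLUSION_REASONS))
  stats::setNames(as.integer(counts), EXCLUSION_REASONS)
}
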