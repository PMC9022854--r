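#' Configuration for the synthetic burden-data generator
#'
#' Defines a latent quality-of-care model from which GBD-shaped measure
#' tables are simulated. Each location draws a latent quality `q` in (0, 1);
#' all four secondary ratios are monotone in `q` by construction, so fitted
#' index scores can be checked against known ground truth:
#' \itemize{
#'   \item deaths = incidence * mir(q), with
#'     `mir(q) = mir_floor + (mir_ceil - mir_floor) * (1 - q)` — higher
#'     quality lowers the mortality-to-incidence ratio;
#'   \item prevalence = incidence * duration(q), with mean prevalent duration
#'     `duration(q) = duration_floor + (duration_ceil - duration_floor) * q`
#'     years — higher quality keeps patients alive longer, raising
#'     prevalence-to-incidence;
#'   \item yld = prevalence * disability_weight;
#'   \item yll = deaths * residual life expectancy at the age-bin midpoint;
#'   \item daly = yll + yld, exactly (the GBD identity), so DALY-to-prevalence
#'     and YLL-to-YLD fall with quality too.
#' }
#' Age-specific incidence follows a logistic curve in age (rare in the young,
#' plateauing in old age, as for colorectal cancer). Noise is multiplicative
#' log-normal per measure and age bin — rates stay positive and burden
#' estimation error is heavier on the multiplicative scale. SDI is a monotone
#' (identity-slope) function of `q` plus truncated noise, so quality and
#' development are positively associated as observed in real burden data.
#'
#' @param n_locations Number of locations (default 100).
#' @param years Integer vector of calendar years (default 2019).
#' @param age_bins Age-bin labels (default [gbd_age_bins()]).
#' @param latent_shape1,latent_shape2 Beta parameters of the latent quality
#'   distribution (default Beta(2, 2)).
#' @param year_trend Additive quality drift per year after the first
#'   (default 0).
#' @param sex_effect Multiplier on female latent quality (default 1:
#'   no sex effect).
#' @param sdi_intercept,sdi_slope Monotone link `sdi = intercept + slope * q`
#'   (defaults 0.1, 0.8, keeping noise-free sdi inside \[0, 1\]).
#' @param sdi_noise_sd SD of truncated Gaussian noise added to sdi
#'   (default 0.05).
#' @param incidence_scale Peak of the age-incidence curve per 100,000
#'   (default 150).
#' @param incidence_midpoint,incidence_width Age (years) of the logistic
#'   curve's half-maximum and its width (defaults 60, 12).
#' @param mir_floor,mir_ceil Mortality-to-incidence ratio at perfect and at
#'   absent quality (defaults 0.1, 0.9; must satisfy
#'   0 <= floor < ceil <= 1).
#' @param duration_floor,duration_ceil Mean prevalent duration in years at
#'   q = 0 and q = 1 (defaults 2, 10).
#' @param disability_weight Disability weight in (0, 1) (default 0.2).
#' @param le_at_birth,le_at_top Residual life expectancy (years) at age 0 and
#'   at the top bin's lower bound; linear in between (defaults 85, 2).
#' @param noise_sd SD of log-normal measure noise on the log scale
#'   (default 0.1).
#' @param shared_sex_noise Draw one noise value per location-year-age-measure
#'   and apply it to both sexes (default TRUE), so sex contrasts reflect only
#'   the latent sex effect rather than independent measurement noise.
#' @param seed Integer RNG seed (default 42).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_locations = 100,
                             years = 2019L,
                             age_bins = gbd_age_bins(),
                             latent_shape1 = 2,
                             latent_shape2 = 2,
                             year_trend = 0,
                             sex_effect = 1,
                             sdi_intercept = 0.1,
                             sdi_slope = 0.8,
                             sdi_noise_sd = 0.05,
                             incidence_scale = 150,
                             incidence_midpoint = 60,
                             incidence_width = 12,
                             mir_floor = 0.1,
                             mir_ceil = 0.9,
                             duration_floor = 2,
                             duration_ceil = 10,
                             disability_weight = 0.2,
                             le_at_birth = 85,
                             le_at_top = 2,
                             noise_sd = 0.1,
                             shared_sex_noise = TRUE,
                             seed = 42L) {
  cfg <- as.list(environment())
  if (cfg$n_locations < 1) abort_config("n_locations must be >= 1.")
  if (cfg$latent_shape1 <= 0 || cfg$latent_shape2 <= 0) {
    abort_config("Beta shape parameters must be positive.")
  }
  if (!(cfg$mir_floor >= 0 && cfg$mir_floor < cfg$mir_ceil && cfg$mir_ceil <= 1)) {
    abort_config("Need 0 <= mir_floor < mir_ceil <= 1.")
  }
  if (cfg$duration_floor <= 0 || cfg$duration_ceil <= cfg$duration_floor) {
    abort_config("Need 0 < duration_floor < duration_ceil.")
  }
  if (cfg$disability_weight <= 0 || cfg$disability_weight >= 1) {
    abort_config("disability_weight must be in (0, 1).")
  }
  if (cfg$noise_sd < 0 || cfg$sdi_noise_sd < 0) {
    abort_config("Noise SDs must be non-negative.")
  }
  if (cfg$sex_effect <= 0) abort_config("sex_effect must be positive.")
  cfg$years <- as.integer(cfg$years)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

clamp_unit <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# Deterministic sub-seeds: one RNG stream per purpose, derived from the
# master seed, so adding a measure or toggling a knob doesn't shift the
# draws of the others. Kept below 2^31.
sub_seed <- function(seed, stream) {
  offsets <- c(latent = 1L, sdi = 2L, incidence = 11L, deaths = 12L,
               prevalence = 13L, yll = 14L, yld = 15L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}

#' Simulate the latent quality table
#'
#' Draws one latent quality value per location from the configured Beta
#' distribution, applies the per-year trend and the female sex-effect
#' multiplier, and links SDI to quality monotonically plus truncated noise.
#' Fixed seed gives bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with one row per location-year-sex: `location`, `year`,
#'   `sex`, `q` (latent quality in (0, 1)), `sdi` (in \[0, 1\]).
#' @export
simulate_latent <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  loc <- sprintf("loc_%03d", seq_len(config$n_locations))

  set.seed(sub_seed(config$seed, "latent"))
  q0 <- stats::rbeta(config$n_locations, config$latent_shape1,
                     config$latent_shape2)
  q0 <- clamp_unit(q0)

  grid <- tidyr::expand_grid(
    location = loc,
    year = config$years,
    sex = c("female", "male")
  )
  grid$q <- q0[match(grid$location, loc)] +
    config$year_trend * (grid$year - min(config$years))
  grid$q <- ifelse(grid$sex == "female", grid$q * config$sex_effect, grid$q)
  grid$q <- clamp_unit(grid$q)

  set.seed(sub_seed(config$seed, "sdi"))
  sdi_base <- config$sdi_intercept + config$sdi_slope * q0
  sdi_noise <- stats::rnorm(config$n_locations * length(config$years),
                            0, config$sdi_noise_sd)
  loc_year <- tidyr::expand_grid(location = loc, year = config$years)
  loc_year$sdi <- pmin(pmax(
    sdi_base[match(loc_year$location, loc)] + sdi_noise, 0), 1)

  dplyr::left_join(grid, loc_year, by = c("location", "year"))
}

#' Residual life expectancy at age-bin midpoints
#'
#' Linear decline from `le_at_birth` at age 0 to `le_at_top` at the top
#' bin's lower bound, floored at `le_at_top`.
#' @noRd
residual_le <- function(age_mid, config) {
  top_age <- max(age_mid) - 2.5
  le <- config$le_at_birth -
    (config$le_at_birth - config$le_at_top) * age_mid / top_age
  pmax(le, config$le_at_top)
}

#' Simulate a measure table from a latent quality table
#'
#' For every location-year-sex stratum and age bin, generates age-specific
#' rates of the six measures from the latent quality (see
#' [synthetic_config()] for the generative links), applies multiplicative
#' log-normal noise per measure, sets `daly = yll + yld` exactly, and appends
#' age-standardized rows (equal-weight standard over the configured bins).
#' The latent SDI is carried through in an `sdi` column.
#'
#' @param latent Latent table from [simulate_latent()].
#' @param config The same [synthetic_config()].
#' @return A validated measure table (long format) with age-specific and
#'   age-standardized rows.
#' @export
simulate_measures <- function(latent, config) {
  stopifnot(inherits(config, "synthetic_config"))
  age_mid <- age_bin_midpoints(config$age_bins)
  inc_curve <- config$incidence_scale *
    stats::plogis((age_mid - config$incidence_midpoint) / config$incidence_width)
  rle_mid <- residual_le(age_mid, config)

  grid <- tidyr::expand_grid(
    latent[c("location", "year", "sex", "q", "sdi")],
    tibble::tibble(age_group = config$age_bins,
                   .inc0 = inc_curve, .rle = rle_mid)
  )

  mir <- config$mir_floor + (config$mir_ceil - config$mir_floor) * (1 - grid$q)
  duration <- config$duration_floor +
    (config$duration_ceil - config$duration_floor) * grid$q

  # Noise indexed by location-year-age-measure; when shared_sex_noise the
  # same draw applies to both sexes so GDR reflects only the sex effect.
  noise_key <- if (config$shared_sex_noise) {
    grid[c("location", "year", "age_group")]
  } else {
    grid[c("location", "year", "sex", "age_group")]
  }
  key_id <- do.call(paste, c(noise_key, sep = "\r"))
  uniq <- unique(key_id)
  idx <- match(key_id, uniq)
  draw_noise <- function(stream) {
    set.seed(sub_seed(config$seed, stream))
    exp(stats::rnorm(length(uniq), 0, config$noise_sd))[idx]
  }

  incidence <- grid$.inc0 * draw_noise("incidence")
  deaths <- grid$.inc0 * mir * draw_noise("deaths")
  prevalence <- grid$.inc0 * duration * draw_noise("prevalence")
  yld <- prevalence * config$disability_weight * draw_noise("yld")
  yll <- deaths * grid$.rle * draw_noise("yll")
  daly <- yll + yld

  long <- tidyr::pivot_longer(
    dplyr::bind_cols(
      grid[c("location", "year", "sex", "age_group", "sdi")],
      tibble::tibble(incidence = incidence, deaths = deaths,
                     prevalence = prevalence, yll = yll, yld = yld,
                     daly = daly)
    ),
    cols = dplyr::all_of(MEASURE_LEVELS),
    names_to = "measure", values_to = "value"
  )
  long <- long[c("location", "year", "sex", "age_group", "measure",
                 "value", "sdi")]
  out <- add_age_standardized(long, age_standard(config$age_bins))
  validate_measure_table(out, strict = TRUE)
  tibble::as_tibble(out)
}

#' Join fitted scores to the latent truth
#'
#' Inner join of a latent table and a scored index table on their shared
#' stratum keys (location, year, sex), for parameter-recovery checks.
#'
#' @param latent Latent table from [simulate_latent()].
#' @param qci Scored table from [score_qci()].
#' @return Tibble of matched strata with `q`, `sdi`, and `qci`; attribute
#'   `n_unmatched` counts latent strata without a score.
#' @export
truth_join <- function(latent, qci) {
  by <- intersect(c("location", "year", "sex"), intersect(names(latent), names(qci)))
  if (length(by) == 0) abort_config("No shared key columns between tables.")
  qcols <- qci[c(by, "qci")]
  joined <- dplyr::inner_join(latent, qcols, by = by)
  if (nrow(joined) == 0) abort_data("Truth join is empty: no shared strata.")
  attr(joined, "n_unmatched") <- nrow(latent) - nrow(joined)
  joined
}
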