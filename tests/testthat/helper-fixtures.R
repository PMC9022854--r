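# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A minimal valid measure table: n strata at the age-standardized level with
# all six measures, consistent by construction (daly = yll + yld).
make_measure_table <- function(n = 4, seed = 1, sdi = FALSE) {
  set.seed(seed)
  strata <- tidyr::expand_grid(
    location = sprintf("L%02d", seq_len(n)),
    year = 2019L,
    sex = "both"
  )
  inc <- stats::runif(n, 10, 50)
  mir <- stats::runif(n, 0.2, 0.8)
  dur <- stats::runif(n, 2, 10)
  deaths <- inc * mir
  prev <- inc * dur
  yld <- prev * 0.2
  yll <- deaths * stats::runif(n, 5, 20)
  vals <- tibble::tibble(
    incidence = inc, deaths = deaths, prevalence = prev,
    yll = yll, yld = yld, daly = yll + yld
  )
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(strata, vals),
    cols = dplyr::all_of(c("incidence", "deaths", "prevalence",
                           "yll", "yld", "daly")),
    names_to = "measure", values_to = "value"
  )
  out$age_group <- "age-standardized"
  out <- out[c("location", "year", "sex", "age_group", "measure", "value")]
  if (sdi) out$sdi <- rep(stats::runif(n), each = 6)
  out
}

# Random ratio table for PCA tests: four positive, partially correlated
# ratio columns.
make_ratio_table <- function(n = 50, seed = 1) {
  set.seed(seed)
  q <- stats::runif(n)
  tibble::tibble(
    location = sprintf("L%03d", seq_len(n)),
    year = 2019L,
    sex = "both",
    mir = 0.1 + 0.8 * (1 - q) * exp(stats::rnorm(n, 0, 0.2)),
    prev_inc = (2 + 8 * q) * exp(stats::rnorm(n, 0, 0.2)),
    daly_prev = (0.5 + 2 * (1 - q)) * exp(stats::rnorm(n, 0, 0.2)),
    yll_yld = (1 + 15 * (1 - q)) * exp(stats::rnorm(n, 0, 0.2))
  )
}

# Independent PCA oracle: prcomp (SVD of the data matrix), a different route
# from the package's eigendecomposition of the correlation matrix.
oracle_pca <- function(ratio_table, standardize = TRUE) {
  x <- as.matrix(ratio_table[c("mir", "prev_inc", "daly_prev", "yll_yld")])
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  list(
    loadings = p$rotation[, 1],
    explained = p$sdev[1]^2 / sum(p$sdev^2),
    scores = p$x[, 1]
  )
}
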