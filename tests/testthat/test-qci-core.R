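ratio_cols <- c("mir", "prev_inc", "daly_prev", "yll_yld")

test_that("fit matches the SVD-based PCA oracle on random tables", {
  for (s in 1:10) {
    n <- sample(10:200, 1)
    rt <- make_ratio_table(n = n, seed = s)
    model <- fit_qci(rt)
    oracle <- oracle_pca(rt)
    # align signs before comparing
    sgn <- sign(sum(model$loadings * oracle$loadings))
    expect_equal(unname(model$loadings * sgn), unname(oracle$loadings),
                 tolerance = 1e-8)
    expect_equal(model$explained_fraction, oracle$explained,
                 tolerance = 1e-8)
    raw <- (as.matrix(scale(rt[ratio_cols])) %*% model$loadings)[, 1]
    expect_equal(raw * sgn, unname(oracle$scores), tolerance = 1e-8)
    expect_equal(sum(model$loadings^2), 1, tolerance = 1e-9)
  }
})

test_that("covariance-mode fit matches the unscaled oracle", {
  rt <- make_ratio_table(n = 80, seed = 2)
  model <- fit_qci(rt, standardize = FALSE)
  oracle <- oracle_pca(rt, standardize = FALSE)
  sgn <- sign(sum(model$loadings * oracle$loadings))
  expect_equal(unname(model$loadings * sgn), unname(oracle$loadings),
               tolerance = 1e-8)
  expect_equal(model$explained_fraction, oracle$explained, tolerance = 1e-8)
})

test_that("collinear and duplicated-pair structures give closed-form explained fractions", {
  # four perfectly collinear columns -> rank-1 correlation -> fraction 1
  set.seed(1)
  base <- runif(30, 1, 2)
  col <- tibble::tibble(mir = base, prev_inc = 2 * base,
                        daly_prev = 0.5 * base, yll_yld = 3 * base)
  expect_equal(fit_qci(col)$explained_fraction, 1.0, tolerance = 1e-9)

  # duplicated pair (a, b, a, b): correlation eigenvalues 2(1+r), 2(1-r), 0, 0
  # -> explained fraction (1 + |r|) / 2
  set.seed(2)
  a <- runif(100, 1, 3)
  b <- 0.5 * a + runif(100, 0, 1)
  dup <- tibble::tibble(mir = a, prev_inc = b, daly_prev = a, yll_yld = b)
  r <- cor(a, b)
  expect_equal(fit_qci(dup)$explained_fraction, (1 + abs(r)) / 2,
               tolerance = 1e-9)
})

test_that("explained fraction of independent columns approaches 1/4", {
  set.seed(3)
  n <- 20000
  x <- abs(matrix(rnorm(4 * n), n, 4)) + 0.1
  rt <- tibble::as_tibble(setNames(as.data.frame(x), ratio_cols))
  expect_equal(fit_qci(rt)$explained_fraction, 0.25, tolerance = 0.02)
})

test_that("orientation makes the mir loading non-positive, with tie-breaks", {
  expect_equal(orient_component(c(0.5, -0.5, 0.5, 0.5)), -1)
  expect_equal(orient_component(c(-0.5, 0.5, -0.5, -0.5)), 1)
  expect_equal(orient_component(c(0, 0.5, 0.5, 0.7)), -1)   # yll_yld decides
  expect_equal(orient_component(c(0, 0.5, -0.7, 0)), 1)     # daly_prev decides
  expect_equal(orient_component(c(0, 0.9, 0, 0)), 1)        # prev_inc decides
  expect_error(orient_component(c(0, 0, 0, 0)),
               class = "qcindex_degenerate_error")
  for (s in 1:20) {
    set.seed(s)
    model <- fit_qci(make_ratio_table(n = 40, seed = s))
    expect_lte((model$loadings * model$orientation)[["mir"]], 0)
  }
})

test_that("scores span exactly [0, 100] on the fitting frame", {
  rt <- make_ratio_table(n = 60, seed = 4)
  model <- fit_qci(rt)
  scored <- score_qci(model, rt)
  expect_equal(min(scored$qci), 0, tolerance = 1e-9)
  expect_equal(max(scored$qci), 100, tolerance = 1e-9)
  expect_false(any(scored$out_of_range))

  # the midpoint of the extreme strata in standardized space maps to qci 50
  z <- scale(as.matrix(rt[ratio_cols]))
  raw <- as.numeric(z %*% model$loadings) * model$orientation
  i_min <- which.min(raw); i_max <- which.max(raw)
  z_mid <- (z[i_min, ] + z[i_max, ]) / 2
  raw_mid <- sum(z_mid * model$loadings) * model$orientation
  qci_mid <- 100 * (raw_mid - model$score_min) /
    (model$score_max - model$score_min)
  expect_equal(qci_mid, 50, tolerance = 1e-9)
})

test_that("out-of-frame strata are flagged, and clamped only on request", {
  rt <- make_ratio_table(n = 30, seed = 5)
  model <- fit_qci(rt)
  extreme <- rt[1, ]
  extreme$mir <- max(rt$mir) * 10
  extreme$yll_yld <- max(rt$yll_yld) * 10
  s <- score_qci(model, extreme)
  expect_true(s$out_of_range)
  expect_lt(s$qci, 0)
  sc <- score_qci(model, extreme, clamp = TRUE)
  expect_equal(sc$qci, 0)
  expect_true(sc$out_of_range)
})

test_that("qci is invariant to affine transforms of ratio columns (correlation mode)", {
  rt <- make_ratio_table(n = 40, seed = 6)
  base <- score_qci(fit_qci(rt), rt)$qci
  shifted <- rt
  shifted$yll_yld <- shifted$yll_yld * 3.7 + 11
  shifted$mir <- shifted$mir * 0.2 + 0.05
  expect_equal(score_qci(fit_qci(shifted), shifted)$qci, base,
               tolerance = 1e-8)
})

test_that("model quantities are invariant to row permutation", {
  rt <- make_ratio_table(n = 35, seed = 7)
  m1 <- fit_qci(rt)
  set.seed(8)
  m2 <- fit_qci(rt[sample(nrow(rt)), ])
  expect_equal(m1$loadings, m2$loadings)
  expect_equal(m1$score_min, m2$score_min)
  expect_equal(m1$score_max, m2$score_max)
  expect_equal(m1$explained_fraction, m2$explained_fraction)
})

test_that("raising a stratum's mir never raises its score", {
  rt <- make_ratio_table(n = 50, seed = 9)
  model <- fit_qci(rt)
  bumped <- rt
  bumped$mir <- bumped$mir * 1.25
  before <- score_qci(model, rt)$qci
  after <- score_qci(model, bumped)$qci
  expect_true(all(after <= before + 1e-12))
})

test_that("degenerate inputs raise classed errors", {
  rt <- make_ratio_table(n = 2)
  expect_error(fit_qci(rt), class = "qcindex_data_error")
  flat <- make_ratio_table(n = 10)
  flat$mir <- 0.5
  expect_error(fit_qci(flat), class = "qcindex_degenerate_error")
  expect_error(fit_qci(flat), "mir")
})

test_that("log-transform mode is recorded and applied consistently at scoring", {
  rt <- make_ratio_table(n = 40, seed = 10)
  model <- fit_qci(rt, log_transform = TRUE)
  expect_true(model$log_transform)
  scored <- score_qci(model, rt)
  expect_equal(min(scored$qci), 0, tolerance = 1e-9)
  expect_equal(max(scored$qci), 100, tolerance = 1e-9)
})

test_that("correlation against a reference behaves at the fixed points", {
  rt <- make_ratio_table(n = 20, seed = 11)
  scored <- score_qci(fit_qci(rt), rt)
  ref <- scored[c("location", "year", "sex")]
  ref$reference <- scored$qci
  expect_equal(correlate_with_reference(scored, ref)$pearson, 1.0)
  ref$reference <- -scored$qci
  res <- correlate_with_reference(scored, ref)
  expect_equal(res$pearson, -1.0)
  expect_equal(res$n_matched, 20)
  expect_error(correlate_with_reference(scored[1:2, ], ref[1:2, ]),
               class = "qcindex_data_error")
  ref$reference <- 1
  expect_error(correlate_with_reference(scored, ref),
               class = "qcindex_degenerate_error")
})

test_that("model serialization round-trips and re-scores identically", {
  rt <- make_ratio_table(n = 30, seed = 12)
  model <- fit_qci(rt)
  path <- withr::local_tempfile(fileext = ".txt")
  write_qci_model(model, path)
  back <- read_qci_model(path)
  expect_equal(back$loadings, model$loadings)
  expect_equal(back$score_min, model$score_min)
  expect_equal(score_qci(back, rt)$qci, score_qci(model, rt)$qci)
})
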