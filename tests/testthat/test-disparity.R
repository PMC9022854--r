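make_qci_table <- function(female, male, locations = NULL) {
  n <- length(female)
  if (is.null(locations)) locations <- sprintf("L%03d", seq_len(n))
  tibble::tibble(
    location = rep(locations, 2),
    year = 2019L,
    age_group = "age-standardized",
    sex = rep(c("female", "male"), each = n),
    qci = c(female, male)
  )
}

test_that("GDR reproduces the printed global values at 1-decimal rounding", {
  # global QCI female/male: 76.2/78.6 in 2019, 63.5/63.9 in 1990
  tbl <- tibble::tibble(
    location = "Global",
    year = c(2019L, 2019L, 1990L, 1990L),
    age_group = "age-standardized",
    sex = c("female", "male", "female", "male"),
    qci = c(76.2, 78.6, 63.5, 63.9)
  )
  res <- compute_gdr(tbl)
  expect_equal(round(res$gdr$gdr, 1), c(1.0, 1.0))
})

test_that("GDR divides female by male and handles missing/zero males", {
  res <- compute_gdr(make_qci_table(c(50, 40, 30), c(25, 40, 0)))
  expect_equal(res$gdr$gdr, c(2, 1))
  expect_equal(res$skipped$reason, "zero_male")

  one_sex <- make_qci_table(c(10), c(20))
  one_sex <- one_sex[one_sex$sex == "female" | one_sex$location != "L001", ]
  res2 <- compute_gdr(one_sex[one_sex$sex == "female", ])
  expect_equal(nrow(res2$gdr), 0)
  expect_equal(res2$skipped$reason, "missing_male")
})

test_that("swapping the sexes inverts GDR", {
  set.seed(5)
  f <- runif(20, 10, 90); m <- runif(20, 10, 90)
  g1 <- compute_gdr(make_qci_table(f, m))$gdr
  g2 <- compute_gdr(make_qci_table(m, f))$gdr
  expect_equal(g1$gdr, 1 / g2$gdr, tolerance = 1e-12)
  expect_equal(g1$gdr[f == m], rep(1, sum(f == m)))
})

test_that("rank-mode quintiles split locations evenly with stable ties", {
  sdi <- tibble::tibble(location = sprintf("L%02d", 1:10), year = 2019L,
                        sdi = seq(0.05, 0.95, length.out = 10))
  q <- assign_sdi_quintiles(sdi)
  expect_equal(as.vector(table(q$quintile)), rep(2L, 5))
  expect_equal(as.character(q$quintile[q$sdi == min(q$sdi)]), "low")
  expect_equal(as.character(q$quintile[q$sdi == max(q$sdi)]), "high")

  five <- sdi[1:5, ]
  q5 <- assign_sdi_quintiles(five)
  expect_equal(sort(as.character(q5$quintile)),
               sort(c("low", "low-middle", "middle", "high-middle", "high")))

  # ties: stable (sdi, location) order, with a warning; row order irrelevant
  tied <- tibble::tibble(location = sprintf("L%02d", 1:10), year = 2019L,
                         sdi = 0.5)
  expect_warning(qt <- assign_sdi_quintiles(tied), "Tied")
  expect_warning(qt2 <- assign_sdi_quintiles(tied[10:1, ]), "Tied")
  both <- dplyr::inner_join(qt, qt2, by = c("location", "year"))
  expect_equal(both$quintile.x, both$quintile.y)
})

test_that("rank-mode quintiles are invariant to monotone transforms of sdi", {
  set.seed(6)
  sdi <- tibble::tibble(location = sprintf("L%02d", 1:15), year = 2019L,
                        sdi = runif(15))
  q1 <- assign_sdi_quintiles(sdi)
  sdi2 <- sdi
  sdi2$sdi <- sdi$sdi^3 # strictly monotone on [0,1]
  q2 <- assign_sdi_quintiles(sdi2)
  expect_equal(q1$quintile, q2$quintile)
})

test_that("fixed cutpoints assign bands and validate monotonicity", {
  sdi <- tibble::tibble(location = c("A", "B", "C"), year = 2019L,
                        sdi = c(0.1, 0.5, 0.9))
  q <- assign_sdi_quintiles(sdi, method = "fixed_cutpoints",
                            cutpoints = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(as.character(q$quintile), c("low", "middle", "high"))
  tied <- tibble::tibble(location = c("A", "B"), year = 2019L, sdi = 0.5)
  qt <- assign_sdi_quintiles(tied, method = "fixed_cutpoints",
                             cutpoints = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(unique(as.character(qt$quintile)), "middle")
  expect_error(
    assign_sdi_quintiles(sdi, method = "fixed_cutpoints",
                         cutpoints = c(0.4, 0.2, 0.6, 0.8)),
    class = "qcindex_config_error"
  )
  expect_error(assign_sdi_quintiles(sdi), # only 3 locations in rank mode
               class = "qcindex_data_error")
})

test_that("summaries aggregate by group, plain and weighted", {
  tbl <- tibble::tibble(
    g = c("a", "a", "b"), qci = c(10, 30, 50), w = c(1, 3, 2)
  )
  s <- summarize_by(tbl, "g")
  expect_equal(s$qci, c(20, 50))
  expect_equal(s$n, c(2L, 1L))
  sw <- summarize_by(tbl, "g", aggregator = "population_weighted_mean",
                     weight = "w")
  expect_equal(sw$qci, c((10 + 3 * 30) / 4, 50))
  # brute-force weighted oracle on random data
  set.seed(9)
  big <- tibble::tibble(g = sample(letters[1:3], 50, TRUE),
                        qci = runif(50), w = rexp(50))
  sb <- summarize_by(big, "g", aggregator = "population_weighted_mean",
                     weight = "w")
  for (gg in unique(big$g)) {
    sub <- big[big$g == gg, ]
    expect_equal(sb$qci[sb$g == gg], sum(sub$qci * sub$w) / sum(sub$w))
  }
  expect_error(summarize_by(tbl, "nope"), class = "qcindex_config_error")
})
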