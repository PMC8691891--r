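test_that("co-coverage distribution matches brute-force weighted tabulation", {
  set.seed(101)
  for (rep in 1:30) {
    dat <- random_indicator_data()
    counts <- sample(0:5, nrow(dat), replace = TRUE)
    d <- survey_design(dat$stratum, dat$psu, dat$weight)
    cc <- cocoverage_distribution(counts, d)
    expect_equal(unname(cc$shares),
                 bf_cocoverage_shares(counts, dat$weight))
    # mean/sd identities at 1e-9
    expect_equal(cc$mean, sum((0:5) * cc$shares), tolerance = 1e-9)
    expect_equal(cc$sd, sqrt(sum((0:5)^2 * cc$shares) - cc$mean^2),
                 tolerance = 1e-9)
    expect_equal(sum(cc$shares), 1, tolerance = 1e-9)
  }
})

test_that("share-based construction handles published percentage rows", {
  cc <- cocoverage_from_shares(c(39.2, 6.7, 10.5, 8.1, 9.3, 26.3))
  expect_equal(round(cc$mean, 1), 2.2)
  expect_equal(round(cc$sd, 2), 2.10)

  degenerate <- cocoverage_from_shares(c(0, 0, 0, 0, 0, 100))
  expect_equal(degenerate$mean, 5)
  expect_equal(degenerate$sd, 0)
})

test_that("the coverage cascade is monotone with exact tail sums", {
  set.seed(202)
  for (rep in 1:10) {
    dat <- random_indicator_data()
    dat$co_coverage <- as.integer(dat$B1 + dat$B2 + dat$B3 + dat$B4 + dat$B5)
    dat$any_contact <- dat$A | dat$co_coverage > 0
    d <- survey_design(dat$stratum, dat$psu, dat$weight)
    casc <- coverage_cascade(dat, d)
    est <- casc$estimate[match(paste0("co_ge_", 1:5), casc$level)]
    expect_true(all(diff(est) <= 1e-12))
    # tail sums of the weighted distribution
    shares <- bf_cocoverage_shares(dat$co_coverage, dat$weight)
    expect_equal(est, rev(cumsum(rev(shares)))[2:6])
    # a record with a check but no intervention widens contact beyond co>=1
    expect_gte(casc$estimate[casc$level == "any_contact"], est[1] - 1e-12)
  }
})

test_that("cascade on check-only records: full contact, empty co-coverage", {
  dat <- tibble::tibble(
    stratum = 1, psu = rep(1:3, each = 2), weight = 1,
    A = TRUE, B1 = FALSE, B2 = FALSE, B3 = FALSE, B4 = FALSE, B5 = FALSE,
    co_coverage = 0L, any_contact = TRUE
  )
  d <- survey_design(dat$stratum, dat$psu, dat$weight)
  casc <- coverage_cascade(dat, d)
  expect_equal(casc$estimate, c(1, rep(0, 5)))
})

test_that("quality-coverage gaps are 100 minus coverage among contacts", {
  # every contact record has all five interventions: all gaps are zero
  dat <- tibble::tibble(
    stratum = 1, psu = rep(1:4, each = 2), weight = 1,
    A = rep(c(TRUE, FALSE), 4),
    B1 = rep(c(TRUE, FALSE), 4), B2 = rep(c(TRUE, FALSE), 4),
    B3 = rep(c(TRUE, FALSE), 4), B4 = rep(c(TRUE, FALSE), 4),
    B5 = rep(c(TRUE, FALSE), 4)
  )
  dat$co_coverage <- as.integer(dat$B1 + dat$B2 + dat$B3 + dat$B4 + dat$B5)
  dat$any_contact <- dat$A | dat$co_coverage > 0
  d <- survey_design(dat$stratum, dat$psu, dat$weight)
  gaps <- quality_coverage_gaps(dat, d)
  expect_equal(gaps$gap_pct, rep(0, 6))

  # half the contacts got a temperature check: B2 gap is 50%
  dat$B2 <- rep(c(TRUE, FALSE, FALSE, FALSE), 2)
  dat$co_coverage <- as.integer(dat$B1 + dat$B2 + dat$B3 + dat$B4 + dat$B5)
  gaps <- quality_coverage_gaps(dat, d)
  expect_equal(gaps$gap_pct[gaps$indicator == "B2"], 50)
  # full-content row reflects co-coverage = 5 among contacts
  expect_equal(gaps$gap_pct[gaps$indicator == "all_five"], 50)
  expect_equal(gaps$n, rep(4L, 6))  # domain is the 4 contact records
})

test_that("inconsistency cells partition the sample; no cord checks, no inconsistency", {
  set.seed(303)
  for (rep in 1:10) {
    dat <- random_indicator_data()
    dat$consistency <- classify_consistency(dat$A, dat$B1)
    d <- survey_design(dat$stratum, dat$psu, dat$weight)
    res <- inconsistency_rate(dat, d)
    expect_equal(sum(res$cells$estimate), 1, tolerance = 1e-12)
    expect_equal(res$rate$estimate,
                 bf_proportion(!dat$A & dat$B1, dat$weight))
  }

  dat <- random_indicator_data()
  dat$B1 <- FALSE
  dat$consistency <- classify_consistency(dat$A, dat$B1)
  d <- survey_design(dat$stratum, dat$psu, dat$weight)
  expect_equal(inconsistency_rate(dat, d)$rate$estimate, 0)
})

test_that("agreement matrix matches brute force and its invariants", {
  set.seed(404)
  for (rep in 1:20) {
    dat <- random_indicator_data()
    d <- survey_design(dat$stratum, dat$psu, dat$weight)
    M <- as.matrix(dat[, c("A", "B1", "B2", "B3", "B4", "B5")])
    ag <- agreement_matrix(dat, d)
    expect_equal(ag, bf_agreement(M, dat$weight))
    expect_equal(diag(ag), setNames(rep(1, 6), colnames(M)))
    expect_equal(ag, t(ag))
    expect_true(all(ag >= 0 & ag <= 1))
    # unweighted mode is the same computation with unit weights
    expect_equal(agreement_matrix(dat, d, weighted = FALSE),
                 bf_agreement(M, rep(1, nrow(dat))))
  }

  # identical vectors agree everywhere; complementary vectors never
  dat <- random_indicator_data()
  dat$B1 <- dat$A; dat$B2 <- !dat$A
  d <- survey_design(dat$stratum, dat$psu, dat$weight)
  ag <- agreement_matrix(dat, d)
  expect_equal(ag["A", "B1"], 1)
  expect_equal(ag["A", "B2"], 0)
})
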