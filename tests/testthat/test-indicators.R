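test_that("postnatal check combines the routed questions within the 2-day window", {
  rec <- rbind(
    # facility birth, checked in facility on day 0
    make_records(1, q438 = "yes", q438_timing_days = 0),
    # facility birth, checked only after discharge on day 2
    make_records(1, q445 = "yes", q445_timing_days = 2),
    # facility birth, post-discharge check too late
    make_records(1, q445 = "yes", q445_timing_days = 3),
    # non-facility birth checked on day 5: outside the window
    make_records(1, place_delivery = "non_facility",
                 q438 = "missing", q445 = "missing",
                 q453 = "yes", q453_timing_days = 5),
    # non-facility birth checked on day 1
    make_records(1, place_delivery = "non_facility",
                 q438 = "missing", q445 = "missing",
                 q453 = "yes", q453_timing_days = 1),
    # all responses don't know
    make_records(1, q438 = "dont_know", q445 = "dont_know")
  )
  expect_equal(derive_postnatal_check(rec),
               c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("a reported check with unknown timing follows the timing_unknown mode", {
  rec <- make_records(1, q438 = "yes", q438_timing_days = NA_real_)
  expect_true(derive_postnatal_check(rec, timing_unknown = "count"))
  expect_false(derive_postnatal_check(rec, timing_unknown = "strict"))
})

test_that("intervention indicators reproduce all 32 response patterns", {
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), 5))
  resp <- function(x) ifelse(x, "yes", "no")
  rec <- make_records(
    nrow(grid),
    q457a = resp(grid[[1]]), q457b = resp(grid[[2]]),
    q457c = resp(grid[[3]]), q457d = resp(grid[[4]]),
    q457e = resp(grid[[5]])
  )
  B <- derive_interventions(rec)
  expect_equal(unname(B), unname(as.matrix(grid)))

  # dont_know and missing count as not received
  rec2 <- make_records(2, q457a = c("dont_know", "missing"))
  expect_false(any(derive_interventions(rec2)))
})

test_that("composites: any-contact is broad, co-coverage counts B only", {
  B0 <- matrix(FALSE, 1, 5)
  # a postnatal check alone qualifies as contact but scores zero
  expect_equal(derive_composites(TRUE, B0),
               list(any_contact = TRUE, co_coverage = 0L))
  # a single intervention without a check also qualifies as contact
  B1 <- matrix(c(TRUE, rep(FALSE, 4)), 1)
  expect_equal(derive_composites(FALSE, B1),
               list(any_contact = TRUE, co_coverage = 1L))
  expect_equal(derive_composites(FALSE, B0),
               list(any_contact = FALSE, co_coverage = 0L))
})

test_that("consistency classification matches the two-way table", {
  expect_equal(
    as.character(classify_consistency(c(TRUE, TRUE, FALSE, FALSE),
                                      c(TRUE, FALSE, FALSE, TRUE))),
    c("coverage", "quality_coverage_gap", "coverage_gap",
      "internal_inconsistency")
  )
})

test_that("indicator invariants hold on fuzzed records", {
  set.seed(404)
  for (rep in 1:25) {
    g <- generate_births(generator_config(
      seed = rep, n_strata = 2, clusters_per_stratum = 3,
      births_per_cluster = 15,
      p_dont_know = runif(1, 0, 0.3),
      tau_inconsistency = runif(1),
      p_contact = runif(1),
      p_intervention_given_contact = runif(5),
      p_intervention_no_contact = runif(5, 0, 0.3),
      p_check_given_contact = runif(1)
    ))
    ind <- derive_indicators(filter_analysis_sample(g$records)$included)
    B <- as.matrix(ind[, c("B1", "B2", "B3", "B4", "B5")])
    expect_equal(ind$co_coverage, as.integer(rowSums(B)))
    expect_equal(ind$any_contact, ind$A | rowSums(B) > 0)
    # full co-coverage implies contact; inconsistent records count as contact
    expect_true(all(ind$any_contact[ind$co_coverage == 5]))
    expect_true(all(ind$any_contact[ind$consistency == "internal_inconsistency"]))
    # the four categories partition all records
    expect_false(anyNA(ind$consistency))
    expect_equal(sum(table(ind$consistency)), nrow(ind))
  }
})

test_that("the missing-response sensitivity mode drops flagged records", {
  rec <- rbind(
    make_records(1, record_id = "ok", q438 = "yes", q438_timing_days = 1),
    make_records(1, record_id = "dk_b", q457c = "dont_know"),
    make_records(1, record_id = "miss_a", q445 = "missing")
  )
  ind <- derive_indicators(rec, missing = "drop")
  expect_equal(ind$record_id, "ok")
  expect_setequal(attr(ind, "dropped"), c("dk_b", "miss_a"))
  # default mode keeps everything, scoring non-substantive responses as no
  expect_equal(nrow(derive_indicators(rec)), 3)
})
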