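#' Configuration for the synthetic DHS-shaped microdata generator
#'
#' Describes a stratified two-stage sample of most-recent live births with
#' the response structure of a DHS child-recode extract. Defaults emulate a
#' mid-sized country survey from the DHS 2015–2018 round: about 4,000
#' most-recent births in the last two years, spread over clusters within
#' strata, a majority of facility deliveries, and intervention receipt
#' driven by a latent provider-contact event (which induces the positive
#' correlation between interventions observed in real data).
#'
#' The reporting model is: a newborn has provider contact with probability
#' `p_contact` (possibly facility-dependent); given contact status each
#' intervention B1–B5 is received independently with
#' `p_intervention_given_contact` (resp. `p_intervention_no_contact`); the
#' postnatal check A would be reported with `p_check_given_contact` (resp.
#' `p_check_no_contact`); an internally inconsistent response is injected
#' by flipping a would-be "yes" on A to "no" with probability
#' `tau_inconsistency` when the cord check (B1) was received; finally each
#' applicable response is replaced by "don't know" with probability
#' `p_dont_know`. Ineligible records (not most recent, older than two
#' years, died in the first two days, born within two days of interview)
#' are planted at the configured rates, mutually exclusively, so the
#' eligibility filter's exclusion log can be checked against planted
#' counts exactly.
#'
#' @param seed integer seed making the output bit-reproducible.
#' @param n_strata,clusters_per_stratum,births_per_cluster sample sizes
#'   (defaults 8 × 25 × 20 = 4,000 births).
#' @param weight_dispersion sdlog of the lognormal cluster-level relative
#'   weights (0 gives a self-weighting sample).
#' @param p_facility probability of a facility delivery.
#' @param p_contact scalar, or named vector `c(facility=, non_facility=)`,
#'   probability of provider contact in the first two days.
#' @param p_intervention_given_contact,p_intervention_no_contact length-5
#'   vectors of per-intervention receipt probabilities given contact
#'   status.
#' @param p_check_given_contact,p_check_no_contact probability the
#'   postnatal check would be reported, by contact status.
#' @param p_check_in_facility_share for facility births with a reported
#'   check, probability it is reported as the in-facility question (q438)
#'   rather than post-discharge (q445).
#' @param tau_inconsistency P(A flipped to "no" | A would be yes, B1
#'   received) — the injected misreporting rate.
#' @param p_dont_know per-question probability of a "don't know" response.
#' @param p_not_most_recent,p_over_two_years,p_died_first_two_days,p_born_within_two_days
#'   planting rates of the four ineligibility reasons (mutually exclusive).
#' @param p_died_later probability an eligible child died after day 1
#'   (remains in the analysis sample).
#' @param interview_cmc interview date, months since January 1900.
#' @return Object of class `pnc_generator_config` (a validated list).
#' @export
generator_config <- function(seed = 1L,
                             n_strata = 8L,
                             clusters_per_stratum = 25L,
                             births_per_cluster = 20L,
                             weight_dispersion = 0.3,
                             p_facility = 0.65,
                             p_contact = c(facility = 0.75,
                                           non_facility = 0.35),
                             p_intervention_given_contact =
                               c(0.75, 0.65, 0.50, 0.60, 0.40),
                             p_intervention_no_contact = rep(0, 5),
                             p_check_given_contact = 0.85,
                             p_check_no_contact = 0,
                             p_check_in_facility_share = 0.7,
                             tau_inconsistency = 0.10,
                             p_dont_know = 0.02,
                             p_not_most_recent = 0.03,
                             p_over_two_years = 0.05,
                             p_died_first_two_days = 0.01,
                             p_born_within_two_days = 0.005,
                             p_died_later = 0.01,
                             interview_cmc = 1416L) {
  if (length(p_contact) == 1L) {
    p_contact <- c(facility = unname(p_contact),
                   non_facility = unname(p_contact))
  }
  stopifnot(all(c("facility", "non_facility") %in% names(p_contact)))
  cfg <- list(
    seed = as.integer(seed),
    n_strata = as.integer(n_strata),
    clusters_per_stratum = as.integer(clusters_per_stratum),
    births_per_cluster = as.integer(births_per_cluster),
    weight_dispersion = weight_dispersion,
    p_facility = p_facility,
    p_contact = p_contact[c("facility", "non_facility")],
    p_intervention_given_contact = p_intervention_given_contact,
    p_intervention_no_contact = p_intervention_no_contact,
    p_check_given_contact = p_check_given_contact,
    p_check_no_contact = p_check_no_contact,
    p_check_in_facility_share = p_check_in_facility_share,
    tau_inconsistency = tau_inconsistency,
    p_dont_know = p_dont_know,
    p_not_most_recent = p_not_most_recent,
    p_over_two_years = p_over_two_years,
    p_died_first_two_days = p_died_first_two_days,
    p_born_within_two_days = p_born_within_two_days,
    p_died_later = p_died_later,
    interview_cmc = as.integer(interview_cmc)
  )
  sizes <- c(cfg$n_strata, cfg$clusters_per_stratum, cfg$births_per_cluster)
  if (any(sizes < 1L)) stop("sample sizes must be positive", call. = FALSE)
  probs <- unlist(cfg[grep("^(p_|tau_)", names(cfg))])
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$p_intervention_given_contact) != 5L ||
      length(cfg$p_intervention_no_contact) != 5L) {
    stop("per-intervention probability vectors must have length 5",
         call. = FALSE)
  }
  excl <- cfg$p_not_most_recent + cfg$p_over_two_years +
    cfg$p_died_first_two_days + cfg$p_born_within_two_days
  if (excl >= 1) stop("exclusion-planting rates must sum to less than 1",
                      call. = FALSE)
  structure(cfg, class = "pnc_generator_config")
}

#' Generate a synthetic birth-record cohort with known ground truth
#'
#' Draws a full cohort under a [generator_config()]: strata of clusters with
#' lognormal cluster weights (quantized to the 1e-6 grid so the DHS stored
#' integer weight round-trips exactly), facility/home delivery mix, latent
#' provider contact, conditionally independent intervention receipt, the
#' postnatal-check response with injected inconsistency, don't-know noise,
#' and planted ineligible records.
#'
#' @param config a [generator_config()].
#' @return A list with `records` (canonical birth-record tibble, directly
#'   usable by [filter_analysis_sample()]) and `truth`, the ground-truth
#'   ledger: the config, planted exclusion counts by reason, the
#'   closed-form expectations from [generator_truth()], and realized
#'   weighted indicator marginals among the eligible records.
#' @export
generate_births <- function(config = generator_config()) {
  stopifnot(inherits(config, "pnc_generator_config"))
  set.seed(config$seed)
  H <- config$n_strata; C <- config$clusters_per_stratum
  m <- config$births_per_cluster
  n <- H * C * m

  stratum_of_cluster <- rep(seq_len(H), each = C)
  cluster_id <- sprintf("s%02d_c%03d", stratum_of_cluster,
                        seq_len(H * C))
  w_cluster <- rlnorm(H * C, meanlog = 0, sdlog = config$weight_dispersion)
  w_cluster <- round(w_cluster * 1e6) / 1e6   # DHS integer-weight grid

  stratum <- rep(stratum_of_cluster, each = m)
  psu <- rep(cluster_id, each = m)
  weight <- rep(w_cluster, each = m)

  # eligibility planting: one mutually exclusive label per record
  plant_levels <- c("none", "not_most_recent", "over_two_years",
                    "died_first_two_days", "born_within_two_days")
  plant_p <- c(1 - config$p_not_most_recent - config$p_over_two_years -
                 config$p_died_first_two_days - config$p_born_within_two_days,
               config$p_not_most_recent, config$p_over_two_years,
               config$p_died_first_two_days, config$p_born_within_two_days)
  plant <- plant_levels[1L + findInterval(runif(n), cumsum(plant_p))]

  interval <- sample(0:23, n, replace = TRUE)
  interval[plant == "over_two_years"] <- sample(24:35,
    sum(plant == "over_two_years"), replace = TRUE)
  day_offset <- sample(0:29, n, replace = TRUE)
  day_offset[interval == 0L] <- sample(2:29, sum(interval == 0L),
                                       replace = TRUE)
  days_since_birth <- interval * 30L + day_offset
  recent <- plant == "born_within_two_days"
  interval[recent] <- 0L
  days_since_birth[recent] <- sample(0:1, sum(recent), replace = TRUE)

  is_most_recent <- plant != "not_most_recent"
  child_alive <- rep(TRUE, n)
  age_at_death <- rep(NA_integer_, n)
  early_death <- plant == "died_first_two_days"
  child_alive[early_death] <- FALSE
  age_at_death[early_death] <- sample(0:1, sum(early_death), replace = TRUE)
  late_death <- plant == "none" & runif(n) < config$p_died_later
  child_alive[late_death] <- FALSE
  age_at_death[late_death] <- pmin(
    sample(2:60, sum(late_death), replace = TRUE),
    days_since_birth[late_death])

  facility <- runif(n) < config$p_facility
  place <- ifelse(facility, "facility", "non_facility")
  p_c <- ifelse(facility, config$p_contact[["facility"]],
                config$p_contact[["non_facility"]])
  contact <- runif(n) < p_c

  B <- matrix(FALSE, n, 5L)
  for (k in 1:5) {
    pk <- ifelse(contact, config$p_intervention_given_contact[k],
                 config$p_intervention_no_contact[k])
    B[, k] <- runif(n) < pk
  }
  a_would <- runif(n) < ifelse(contact, config$p_check_given_contact,
                               config$p_check_no_contact)
  flipped <- a_would & B[, 1L] & runif(n) < config$tau_inconsistency
  a_report <- a_would & !flipped

  resp <- function(x) ifelse(x, "yes", "no")
  dk <- function(x, applicable = rep(TRUE, n)) {
    hit <- applicable & runif(n) < config$p_dont_know
    ifelse(hit, "dont_know", x)
  }

  in_fac <- facility & a_report &
    runif(n) < config$p_check_in_facility_share
  q438 <- ifelse(facility, resp(in_fac), "missing")
  q445 <- ifelse(facility, resp(facility & a_report & !in_fac), "missing")
  q453 <- ifelse(!facility, resp(a_report), "missing")
  q438 <- dk(q438, facility)
  q445 <- dk(q445, facility)
  q453 <- dk(q453, !facility)

  timing <- function(q) ifelse(q == "yes",
                               sample(0:2, n, replace = TRUE), NA_real_)

  records <- tibble::tibble(
    record_id = sprintf("r%06d", seq_len(n)),
    stratum = as.character(stratum),
    psu = psu,
    weight = weight,
    is_most_recent = is_most_recent,
    interview_cmc = config$interview_cmc,
    birth_cmc = config$interview_cmc - interval,
    days_since_birth = as.integer(days_since_birth),
    child_alive = child_alive,
    age_at_death_days = age_at_death,
    place_delivery = place,
    q438 = q438, q438_timing_days = timing(q438),
    q445 = q445, q445_timing_days = timing(q445),
    q453 = q453, q453_timing_days = timing(q453)
  )
  for (k in 1:5) {
    records[[.B_COLUMNS[k]]] <- dk(resp(B[, k]))
  }
  records <- records[, .RECORD_COLUMNS]

  planted <- tibble::tibble(
    reason = plant_levels[-1L],
    n = vapply(plant_levels[-1L], function(r) sum(plant == r), integer(1),
               USE.NAMES = FALSE)
  )

  eligible <- plant == "none"
  ind <- derive_indicators(records[eligible, ])
  w_e <- weight[eligible]
  realized <- c(
    vapply(c("A", .B_NAMES, "any_contact"),
           function(v) sum(w_e * ind[[v]]) / sum(w_e), numeric(1)),
    inconsistency =
      sum(w_e * (ind$consistency == "internal_inconsistency")) / sum(w_e)
  )

  list(
    records = records,
    truth = list(
      config = config,
      n = n,
      n_eligible = sum(eligible),
      planted_exclusions = planted,
      expected = generator_truth(config),
      realized_weighted_marginals = realized
    )
  )
}

#' Closed-form expectations implied by a generator configuration
#'
#' Under the generator's mixture model every population quantity has a
#' closed form, obtained by enumerating the latent cells
#' (place of delivery × contact × cord-check receipt) within which the
#' reported indicators are independent. This provides analytic oracles for
#' the estimation layer: indicator marginals, the expected
#' internal-inconsistency rate, the full co-coverage distribution, and the
#' 6×6 pairwise agreement matrix.
#'
#' @param config a [generator_config()].
#' @return List with `marginals` (named: `A`, `B1`–`B5`, `any_contact`),
#'   `inconsistency_rate`, `cocoverage` (a `pnc_cocoverage`), and
#'   `agreement` (6×6 matrix).
#' @export
generator_truth <- function(config) {
  stopifnot(inherits(config, "pnc_generator_config"))
  dl <- config$p_dont_know
  tau <- config$tau_inconsistency

  # latent cells: place (2) x contact (2) x B1 receipt (2)
  cells <- list(); probs <- numeric()
  for (place in c("facility", "non_facility")) {
    pi_place <- if (place == "facility") config$p_facility
                else 1 - config$p_facility
    for (ct in c(TRUE, FALSE)) {
      p_ct <- if (ct) config$p_contact[[place]]
              else 1 - config$p_contact[[place]]
      pB <- if (ct) config$p_intervention_given_contact
            else config$p_intervention_no_contact
      pA <- if (ct) config$p_check_given_contact else config$p_check_no_contact
      for (b1 in c(TRUE, FALSE)) {
        p_b1 <- if (b1) pB[1] else 1 - pB[1]
        # reported-indicator probabilities within the cell (independent)
        p_ind <- c(
          A = pA * (if (b1) 1 - tau else 1) * (1 - dl),
          B1 = if (b1) 1 - dl else 0,
          B2 = pB[2] * (1 - dl), B3 = pB[3] * (1 - dl),
          B4 = pB[4] * (1 - dl), B5 = pB[5] * (1 - dl)
        )
        cells[[length(cells) + 1L]] <- p_ind
        probs <- c(probs, pi_place * p_ct * p_b1)
      }
    }
  }
  P <- do.call(rbind, cells)   # cell x indicator

  marginals <- colSums(P * probs)
  no_any <- sum(probs * apply(1 - P, 1, prod))
  marginals <- c(marginals, any_contact = 1 - no_any)
  inconsistency <- sum(probs * (1 - P[, "A"]) * P[, "B1"])

  # co-coverage pmf: per-cell Poisson-binomial over B1..B5, mixed
  pmf <- numeric(6L)
  for (i in seq_len(nrow(P))) {
    f <- 1
    for (k in 1:5) f <- convolve_bernoulli(f, P[i, k + 1L])
    pmf <- pmf + probs[i] * f
  }

  agree <- matrix(0, 6, 6, dimnames = list(names(marginals)[1:6],
                                           names(marginals)[1:6]))
  for (u in 1:6) for (v in 1:6) {
    agree[u, v] <- sum(probs * (P[, u] * P[, v] + (1 - P[, u]) * (1 - P[, v])))
  }
  diag(agree) <- 1

  list(
    marginals = marginals,
    inconsistency_rate = inconsistency,
    cocoverage = new_cocoverage(pmf),
    agreement = agree
  )
}

convolve_bernoulli <- function(f, p) {
  out <- c(f * (1 - p), 0) + c(0, f * p)
  out
}

#' Write a synthetic cohort as a survey extract
#'
#' Serializes canonical birth records to CSV in a [column_mapping()]
#' dialect (`"dhs"`: numeric codes, CMC dates, weights stored times 1e6;
#' `"plain"`: literal categories and ISO dates) and writes the matching
#' mapping YAML alongside, so [load_births()] round-trips the records
#' identically.
#'
#' @param records canonical birth-record tibble.
#' @param path output CSV path.
#' @param dialect `"dhs"` or `"plain"`.
#' @param mapping_path where to write the mapping YAML (default: `path`
#'   with extension `.mapping.yml`); `NULL` suppresses it.
#' @return Invisibly, a list with `data` and `mapping` file paths.
#' @export
write_extract <- function(records, path, dialect = c("dhs", "plain"),
                          mapping_path = NULL) {
  dialect <- match.arg(dialect)
  mapping <- column_mapping(dialect)
  inv_resp <- inverse_dict(mapping$codes$response)
  inv_place <- inverse_dict(mapping$codes$place)
  inv_lgl <- inverse_dict(mapping$codes$logical)

  out <- records
  for (f in c("q438", "q445", "q453", .B_COLUMNS)) {
    out[[f]] <- unname(inv_resp[records[[f]]])
  }
  out$place_delivery <- unname(inv_place[records$place_delivery])
  out$is_most_recent <- unname(inv_lgl[as.character(records$is_most_recent)])
  out$child_alive <- unname(inv_lgl[as.character(records$child_alive)])
  if (dialect == "dhs") {
    out$weight <- sprintf("%.0f", records$weight * 1e6)
  } else {
    out$interview_cmc <- iso_from_cmc(records$interview_cmc)
    out$birth_cmc <- iso_from_cmc(records$birth_cmc)
  }
  names(out) <- unname(mapping$columns[names(out)])

  readr::write_csv(out, path, na = "")
  mp <- NULL
  if (is.null(mapping_path)) {
    mapping_path <- sub("\\.csv$", "", path)
    mapping_path <- paste0(mapping_path, ".mapping.yml")
  }
  if (!identical(mapping_path, NA) && !is.na(mapping_path)) {
    write_mapping(mapping, mapping_path)
    mp <- mapping_path
  }
  invisible(list(data = path, mapping = mp))
}

inverse_dict <- function(dict) {
  dict <- dict[names(dict) != ".na"]
  setNames(names(dict), unname(dict))
}
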