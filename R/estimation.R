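#' Weighted distribution of the co-coverage index
#'
#' Weighted probability mass over the co-coverage scores 0–5, with its mean
#' and standard deviation. The SD is the population SD of the weighted
#' distribution, \eqn{\sqrt{\sum_k k^2 p_k - (\sum_k k p_k)^2}}.
#'
#' @param counts integer co-coverage scores (0–5), one per record.
#' @param design a [survey_design()] over the same records.
#' @param domain optional logical domain (e.g. newborns with any provider
#'   contact); must select at least one record with positive weight.
#' @return An object of class `pnc_cocoverage`: list with `shares` (named
#'   `p0`–`p5`, summing to 1), `mean`, `sd`, unweighted `n` and weighted
#'   `N`.
#' @seealso [cocoverage_from_shares()] to build the same summary directly
#'   from a published percentage distribution.
#' @export
cocoverage_distribution <- function(counts, design, domain = NULL) {
  stopifnot(inherits(design, "pnc_design"))
  counts <- as.integer(counts)
  stopifnot(length(counts) == design$n)
  if (anyNA(counts) || any(counts < 0L | counts > 5L)) {
    stop("co-coverage counts must be integers in 0..5", call. = FALSE)
  }
  d <- if (is.null(domain)) rep(TRUE, design$n) else as.logical(domain)
  d[is.na(d)] <- FALSE
  w <- design$weight * d
  W <- sum(w)
  if (W <= 0) stop("empty domain: no record with positive weight selected",
                   call. = FALSE)

  shares <- vapply(0:5, function(k) sum(w[counts == k]) / W, numeric(1))
  new_cocoverage(shares, n = sum(d), N = W)
}

new_cocoverage <- function(shares, n = NA_integer_, N = NA_real_) {
  names(shares) <- paste0("p", 0:5)
  m <- sum((0:5) * shares)
  s <- sqrt(max(sum((0:5)^2 * shares) - m^2, 0))
  structure(list(shares = shares, mean = m, sd = s, n = n, N = N),
            class = "pnc_cocoverage")
}

#' Co-coverage summary from a published share distribution
#'
#' Builds the same mean/SD summary as [cocoverage_distribution()] directly
#' from a distribution of shares over scores 0–5, e.g. a row of percentages
#' from a published co-coverage table. Percentages (summing to about 100)
#' are detected and normalized; either way the shares are renormalized to
#' sum exactly to 1.
#'
#' @param shares numeric vector of length 6 (scores 0–5), as proportions or
#'   percentages.
#' @return A `pnc_cocoverage` object (`n` and `N` unknown).
#' @examples
#' cc <- cocoverage_from_shares(c(39.2, 6.7, 10.5, 8.1, 9.3, 26.3))
#' round(cc$mean, 1); round(cc$sd, 2)
#' @export
cocoverage_from_shares <- function(shares) {
  stopifnot(is.numeric(shares), length(shares) == 6L, all(shares >= 0))
  tot <- sum(shares)
  if (tot <= 0) stop("shares must not all be zero", call. = FALSE)
  new_cocoverage(shares / tot)
}

#' @export
print.pnc_cocoverage <- function(x, ...) {
  cat("<pnc_cocoverage>  mean", format(round(x$mean, 2)),
      " sd", format(round(x$sd, 2)), "\n")
  print(round(100 * x$shares, 1))
  invisible(x)
}

#' Coverage cascade from any contact down to full co-coverage
#'
#' Reports, as weighted shares of all newborns: the proportion with any
#' postnatal contact (a postnatal check or any specific intervention), then
#' the proportion at each co-coverage threshold, P(co-coverage ≥ 1) through
#' P(co-coverage = 5). The threshold sequence is non-increasing by
#' construction; any-contact can exceed P(≥1) because a postnatal check
#' with no specific intervention counts as contact but scores 0.
#'
#' @param indicators indicator tibble from [derive_indicators()].
#' @param design a [survey_design()] over the same records.
#' @inheritParams weighted_proportion
#' @return Tibble with `level` (`any_contact`, `co_ge_1` … `co_ge_5`) and
#'   the [weighted_proportion()] estimate columns.
#' @export
coverage_cascade <- function(indicators, design, ...) {
  rows <- list(any_contact = indicators$any_contact)
  for (k in 1:5) rows[[paste0("co_ge_", k)]] <- indicators$co_coverage >= k
  out <- do.call(rbind, lapply(rows, weighted_proportion, design = design, ...))
  tibble::tibble(level = names(rows), out)
}

#' Intervention-specific and full-content quality-coverage gaps
#'
#' Among newborns with any postnatal contact, estimates coverage of each
#' specific intervention B1–B5; the quality-coverage gap for an
#' intervention is 100 minus its coverage percentage in that domain. The
#' `all_five` row carries the full-content gap: 100 minus the percentage of
#' contacts with all five interventions (co-coverage = 5).
#'
#' @inheritParams coverage_cascade
#' @return Tibble with `indicator`, `intervention` label, the estimate
#'   columns, and `gap_pct = 100 * (1 - estimate)`.
#' @export
quality_coverage_gaps <- function(indicators, design, ...) {
  contact <- indicators$any_contact
  flags <- c(
    lapply(setNames(.B_NAMES, .B_NAMES), function(b) indicators[[b]]),
    list(all_five = indicators$co_coverage == 5L)
  )
  est <- do.call(rbind, lapply(flags, weighted_proportion, design = design,
                               domain = contact, ...))
  tibble::tibble(
    indicator = names(flags),
    intervention = c(unname(.INTERVENTION_LABELS), "all_five_interventions"),
    est,
    gap_pct = 100 * (1 - est$estimate)
  )
}

#' Internal-inconsistency rate and the two-way response classification
#'
#' The headline rate is the weighted share of all newborns whose responses
#' are contradictory — cord check reported (B1) but no postnatal check
#' reported (A) — estimated with its design-based CI. The full two-way
#' classification of (A, B1) is returned alongside; its four cell shares
#' partition the sample and sum to 1.
#'
#' @inheritParams coverage_cascade
#' @return List with `rate` (a `pnc_estimate` row) and `cells`, a tibble of
#'   the four categories with their weighted shares and CIs.
#' @export
inconsistency_rate <- function(indicators, design, ...) {
  cats <- levels(indicators$consistency)
  cells <- do.call(rbind, lapply(cats, function(cat) {
    weighted_proportion(indicators$consistency == cat, design, ...)
  }))
  cells <- tibble::tibble(category = cats, cells)
  list(
    rate = cells[cells$category == "internal_inconsistency",
                 setdiff(names(cells), "category")],
    cells = cells
  )
}

#' Pairwise observed agreement between indicators
#'
#' For each pair among the postnatal check (A) and the five interventions
#' (B1–B5), agreement is the share of newborns for whom the two indicators
#' coincide — both received or both not received — i.e.
#' \eqn{\sum_i w_i [u_i = v_i] / \sum_i w_i}. Computed on the weighted
#' sample by default; `weighted = FALSE` gives the unweighted diagnostic.
#'
#' @inheritParams coverage_cascade
#' @param weighted use sampling weights (default) or plain counts.
#' @return A symmetric 6×6 matrix with unit diagonal, rows and columns
#'   `A`, `B1`–`B5`.
#' @export
agreement_matrix <- function(indicators, design, weighted = TRUE) {
  stopifnot(inherits(design, "pnc_design"))
  M <- cbind(
    A = as.numeric(indicators$A),
    vapply(setNames(.B_NAMES, .B_NAMES),
           function(b) as.numeric(indicators[[b]]),
           numeric(nrow(indicators)))
  )
  w <- if (weighted) design$weight else rep(1, design$n)
  W <- sum(w)
  if (W <= 0) stop("weights must not all be zero", call. = FALSE)
  both <- t(M * w) %*% M
  neither <- t((1 - M) * w) %*% (1 - M)
  out <- (both + neither) / W
  out <- pmin(pmax(out, 0), 1)     # guard float spillover past the bounds
  dimnames(out) <- list(colnames(M), colnames(M))
  out
}
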