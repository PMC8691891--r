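#' Derive the postnatal-check indicator (A)
#'
#' A newborn counts as having had a postnatal check within two days of birth
#' if a check was reported within the window through any applicable route:
#' for facility births, a check while still in the facility (q438) or after
#' discharge (q445); for non-facility births, the single general question
#' (q453). `dont_know` and `missing` responses count as no check, the
#' standard convention for DHS-style coverage numerators.
#'
#' The two-day window is enforced on the reported timing of the first check
#' (in days; 0, 1 or 2 qualify, matching the usual "within 2 days"
#' tabulation). A "yes" whose timing is unknown counts as within-window
#' under `timing_unknown = "count"` (the default, mirroring how DHS
#' postnatal-care indicators treat undated checks) and as outside the
#' window under `"strict"`.
#'
#' @param records birth-record tibble (post-eligibility).
#' @param timing_unknown `"count"` or `"strict"`; treatment of a reported
#'   check whose first-check timing is unknown.
#' @return Logical vector, one element per record.
#' @export
derive_postnatal_check <- function(records,
                                   timing_unknown = c("count", "strict")) {
  timing_unknown <- match.arg(timing_unknown)
  within <- function(t) {
    ifelse(is.na(t), timing_unknown == "count", t <= 2)
  }
  yes <- function(resp, t) resp == "yes" & within(t)

  facility <- records$place_delivery == "facility"
  out <- ifelse(
    facility,
    yes(records$q438, records$q438_timing_days) |
      yes(records$q445, records$q445_timing_days),
    yes(records$q453, records$q453_timing_days)
  )
  as.logical(out)
}

#' Derive the five provider-initiated intervention indicators (B1–B5)
#'
#' B1 cord check, B2 temperature measurement, B3 danger-sign counselling,
#' B4 breastfeeding counselling, B5 breastfeeding observation. Each is true
#' iff the response is `yes`; the two-day window is embedded in the question
#' wording so no timing test applies. `dont_know`/`missing` count as no.
#'
#' @param records birth-record tibble (post-eligibility).
#' @return Logical matrix with columns `B1`–`B5`.
#' @export
derive_interventions <- function(records) {
  out <- vapply(.B_COLUMNS, function(col) records[[col]] == "yes",
                logical(nrow(records)))
  out <- matrix(out, nrow = nrow(records),
                dimnames = list(NULL, .B_NAMES))
  out
}

#' Composite measures: any provider contact and the co-coverage index
#'
#' `any_contact` is true if the newborn had a postnatal check (A) and/or any
#' of the five specific interventions — a deliberately broad denominator so
#' that a respondent who misunderstood the postnatal-check question but
#' reported interventions still counts as having had contact.
#' `co_coverage` counts the interventions received (0–5); the postnatal
#' check itself does not contribute to the count.
#'
#' @param A logical vector from [derive_postnatal_check()].
#' @param B logical matrix from [derive_interventions()].
#' @return A list with logical `any_contact` and integer `co_coverage`.
#' @export
derive_composites <- function(A, B) {
  stopifnot(is.logical(A), is.matrix(B), ncol(B) == 5L,
            nrow(B) == length(A))
  list(
    any_contact = A | rowSums(B) > 0,
    co_coverage = as.integer(rowSums(B))
  )
}

#' Classify internal consistency of the check and cord-check responses
#'
#' The postnatal-check question uses a cord examination as its example of a
#' health check, so a reported cord check (B1) logically implies a postnatal
#' check (A). The four response combinations are classified as:
#'
#' | A | B1 | category |
#' |---|----|----------|
#' | yes | yes | `coverage` (plausible) |
#' | yes | no  | `quality_coverage_gap` (plausible: checked, cord not examined) |
#' | no  | no  | `coverage_gap` (plausible: no care reported) |
#' | no  | yes | `internal_inconsistency` (contradictory) |
#'
#' Only the cord check is used — the other interventions are not examples
#' inside the postnatal-check question, so "B yes / A no" patterns on them
#' are not logically contradictory.
#'
#' @param A,B1 logical vectors of equal length.
#' @return Factor with levels `coverage`, `quality_coverage_gap`,
#'   `coverage_gap`, `internal_inconsistency`; the levels partition all
#'   records.
#' @export
classify_consistency <- function(A, B1) {
  stopifnot(is.logical(A), is.logical(B1), length(A) == length(B1))
  out <- ifelse(A & B1, "coverage",
         ifelse(A & !B1, "quality_coverage_gap",
         ifelse(!A & !B1, "coverage_gap", "internal_inconsistency")))
  factor(out, levels = c("coverage", "quality_coverage_gap",
                         "coverage_gap", "internal_inconsistency"))
}

#' Derive the full indicator set for every record
#'
#' Convenience wrapper running [derive_postnatal_check()],
#' [derive_interventions()], [derive_composites()] and
#' [classify_consistency()] over a record table.
#'
#' @inheritParams derive_postnatal_check
#' @param missing `"as_no"` (default) scores `dont_know`/`missing` core
#'   responses as no; `"drop"` is a sensitivity mode that removes records
#'   with any non-substantive response among the applicable postnatal-check
#'   question and the five intervention questions (dropped record ids in
#'   attribute `"dropped"`).
#' @return A tibble with `record_id`, `stratum`, `psu`, `weight`, logical
#'   `A`, `B1`–`B5`, `any_contact`, integer `co_coverage`, and factor
#'   `consistency`.
#' @export
derive_indicators <- function(records,
                              timing_unknown = c("count", "strict"),
                              missing = c("as_no", "drop")) {
  timing_unknown <- match.arg(timing_unknown)
  missing <- match.arg(missing)

  dropped <- character()
  if (missing == "drop") {
    facility <- records$place_delivery == "facility"
    core_bad <- Reduce(`|`, lapply(.B_COLUMNS, function(col) {
      records[[col]] %in% c("dont_know", "missing")
    }))
    a_bad <- ifelse(
      facility,
      records$q438 %in% c("dont_know", "missing") |
        records$q445 %in% c("dont_know", "missing"),
      records$q453 %in% c("dont_know", "missing")
    )
    bad <- core_bad | a_bad
    dropped <- records$record_id[bad]
    records <- records[!bad, ]
  }

  A <- derive_postnatal_check(records, timing_unknown)
  B <- derive_interventions(records)
  comp <- derive_composites(A, B)

  out <- tibble::tibble(
    record_id = records$record_id,
    stratum = records$stratum,
    psu = records$psu,
    weight = records$weight,
    A = A
  )
  for (k in seq_len(5L)) out[[.B_NAMES[k]]] <- B[, k]
  out$any_contact <- comp$any_contact
  out$co_coverage <- comp$co_coverage
  out$consistency <- classify_consistency(A, B[, 1L])
  attr(out, "dropped") <- dropped
  out
}
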