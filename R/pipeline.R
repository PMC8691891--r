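#' Run the full postnatal-care measurement pipeline
#'
#' Chains eligibility filtering, indicator derivation and every estimation
#' product over a loaded record table: simple coverage of A, B1–B5 and any
#' contact among all newborns; the coverage cascade; the co-coverage
#' distribution (among all newborns and among those with any contact);
#' intervention-specific and full-content quality-coverage gaps; the
#' internal-inconsistency classification; and the pairwise agreement
#' matrix. With `group_by`, estimation runs separately and independently
#' per group (e.g. per country in a pooled extract), mirroring per-survey
#' analysis; a failure in one group is reported as a warning without
#' aborting the others.
#'
#' @param records birth-record tibble from [load_births()] or
#'   [generate_births()].
#' @param group_by optional name of a column of `records` to analyse by.
#' @param timing_unknown,missing passed to [derive_indicators()].
#' @param ci_method,lonely_psu passed to [weighted_proportion()].
#' @param agreement_weighted passed to [agreement_matrix()].
#' @return A list with `tables` (named list of tibbles: `coverage`,
#'   `cascade`, `cocoverage`, `gaps`, `inconsistency`, `agreement` — in
#'   long form, carrying a `group` column when grouped), `exclusions`
#'   (the eligibility log, per group), and `meta` (record counts and
#'   options). Ready for [write_report()].
#' @export
run_pnc_analysis <- function(records, group_by = NULL,
                             timing_unknown = c("count", "strict"),
                             missing = c("as_no", "drop"),
                             ci_method = c("logit", "wald"),
                             lonely_psu = c("center", "certainty", "error"),
                             agreement_weighted = TRUE) {
  timing_unknown <- match.arg(timing_unknown)
  missing <- match.arg(missing)
  ci_method <- match.arg(ci_method)
  lonely_psu <- match.arg(lonely_psu)

  groups <- if (is.null(group_by)) {
    list(`all` = records)
  } else {
    stopifnot(group_by %in% names(records))
    split(records, records[[group_by]])
  }

  out <- list(); excl <- list(); failed <- character()
  for (g in names(groups)) {
    res <- tryCatch(
      analyze_one_group(groups[[g]], timing_unknown, missing,
                        ci_method, lonely_psu, agreement_weighted),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("group '%s' failed: %s", g, conditionMessage(res)),
              call. = FALSE)
      failed <- c(failed, g)
      next
    }
    res$tables <- lapply(res$tables, function(t) {
      tibble::tibble(group = g, t)
    })
    out[[g]] <- res$tables
    excl[[g]] <- tibble::tibble(group = g, res$exclusion_log)
  }

  table_names <- c("coverage", "cascade", "cocoverage", "gaps",
                   "inconsistency", "agreement")
  tables <- setNames(lapply(table_names, function(nm) {
    parts <- lapply(out, `[[`, nm)
    if (length(parts) == 0) tibble::tibble() else do.call(rbind, parts)
  }), table_names)
  if (is.null(group_by)) {
    tables <- lapply(tables, function(t) t[, setdiff(names(t), "group")])
  }

  list(
    tables = tables,
    exclusions = if (length(excl)) do.call(rbind, excl) else tibble::tibble(),
    meta = list(
      n_records = nrow(records),
      group_by = group_by,
      groups_failed = failed,
      options = list(timing_unknown = timing_unknown, missing = missing,
                     ci_method = ci_method, lonely_psu = lonely_psu,
                     agreement_weighted = agreement_weighted)
    )
  )
}

analyze_one_group <- function(records, timing_unknown, missing,
                              ci_method, lonely_psu, agreement_weighted) {
  elig <- filter_analysis_sample(records)
  smp <- elig$included
  if (nrow(smp) == 0) {
    stop("no eligible records after applying inclusion rules", call. = FALSE)
  }
  ind <- derive_indicators(smp, timing_unknown = timing_unknown,
                           missing = missing)
  design <- survey_design(ind$stratum, ind$psu, ind$weight)
  wp_args <- list(ci_method = ci_method, lonely_psu = lonely_psu)

  coverage <- do.call(rbind, lapply(
    setNames(c("A", .B_NAMES, "any_contact"),
             c("A", .B_NAMES, "any_contact")),
    function(v) do.call(weighted_proportion,
                        c(list(ind[[v]], design), wp_args))
  ))
  coverage <- tibble::tibble(
    indicator = c("A", .B_NAMES, "any_contact"),
    label = c("postnatal_check", unname(.INTERVENTION_LABELS),
              "any_provider_contact"),
    coverage
  )

  cascade <- do.call(coverage_cascade, c(list(ind, design), wp_args))

  cc_all <- cocoverage_distribution(ind$co_coverage, design)
  cc_contact <- cocoverage_distribution(ind$co_coverage, design,
                                        domain = ind$any_contact)
  cocoverage <- tibble::tibble(
    domain = rep(c("all", "any_contact"), each = 6L),
    score = rep(0:5, 2L),
    share = c(unname(cc_all$shares), unname(cc_contact$shares)),
    mean = rep(c(cc_all$mean, cc_contact$mean), each = 6L),
    sd = rep(c(cc_all$sd, cc_contact$sd), each = 6L)
  )

  gaps <- do.call(quality_coverage_gaps, c(list(ind, design), wp_args))
  incons <- do.call(inconsistency_rate, c(list(ind, design), wp_args))
  agree <- agreement_matrix(ind, design, weighted = agreement_weighted)
  agreement <- tibble::tibble(
    indicator_1 = rep(rownames(agree), times = ncol(agree)),
    indicator_2 = rep(colnames(agree), each = nrow(agree)),
    agreement = as.vector(agree)
  )

  list(
    tables = list(coverage = coverage, cascade = cascade,
                  cocoverage = cocoverage, gaps = gaps,
                  inconsistency = incons$cells, agreement = agreement),
    exclusion_log = elig$exclusion_log
  )
}
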