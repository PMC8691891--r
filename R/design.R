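#' Describe a stratified cluster sampling design
#'
#' Captures the design variables that govern all variance estimation:
#' stratum, primary sampling unit (PSU/cluster) and sampling weight for
#' every record. The first sampling stage is treated as with replacement
#' (no finite-population correction), the standard approximation for
#' DHS-type designs.
#'
#' @param stratum,psu vectors identifying each record's stratum and PSU;
#'   every PSU must belong to exactly one stratum.
#' @param weight non-negative sampling weights, not all zero.
#' @return An object of class `pnc_design`.
#' @examples
#' d <- survey_design(rep(1:2, each = 4), rep(1:4, each = 2), runif(8, 1, 2))
#' d
#' @export
survey_design <- function(stratum, psu, weight) {
  n <- length(weight)
  stopifnot(length(stratum) == n, length(psu) == n)
  if (anyNA(stratum) || anyNA(psu) || anyNA(weight)) {
    stop("design variables must not contain missing values", call. = FALSE)
  }
  if (any(weight < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(weight == 0)) stop("weights must not all be zero", call. = FALSE)

  stratum <- as.character(stratum)
  psu <- as.character(psu)
  psu_stratum <- unique(data.frame(psu = psu, stratum = stratum))
  if (anyDuplicated(psu_stratum$psu)) {
    dup <- psu_stratum$psu[duplicated(psu_stratum$psu)]
    stop("PSU(s) appearing in more than one stratum: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  psu_f <- factor(psu, levels = psu_stratum$psu)
  structure(
    list(
      stratum = stratum, psu = psu_f, weight = as.numeric(weight),
      n = n,
      psu_stratum = psu_stratum$stratum,    # stratum of each PSU level
      n_psu = nrow(psu_stratum),
      n_strata = length(unique(stratum))
    ),
    class = "pnc_design"
  )
}

#' @export
print.pnc_design <- function(x, ...) {
  cat(sprintf("<pnc_design> %d records, %d PSUs in %d strata (df = %d)\n",
              x$n, x$n_psu, x$n_strata, x$n_psu - x$n_strata))
  invisible(x)
}

# Taylor-linearized variance of a total of per-record scores `u` under the
# with-replacement first-stage approximation: PSU score totals t_hj are
# treated as iid within stratum h, var-hat = sum_h n_h/(n_h-1) *
# sum_j (t_hj - tbar_h)^2. Strata with a single PSU have no internal
# contrast; the lonely-PSU policy decides their contribution.
taylor_variance <- function(u, design,
                            lonely_psu = c("center", "certainty", "error")) {
  lonely_psu <- match.arg(lonely_psu)
  # integer group ids guarantee output ordered by PSU level (= psu_stratum)
  psu_tot <- as.vector(rowsum(u, as.integer(design$psu)))
  strat <- design$psu_stratum
  n_h <- table(strat)[strat]                        # per-PSU stratum size
  lone <- n_h == 1L

  if (any(lone) && lonely_psu == "error") {
    stop("stratum with a single PSU: ",
         paste(unique(strat[lone]), collapse = ", "),
         " (set lonely_psu to 'center' or 'certainty' to proceed)",
         call. = FALSE)
  }

  strat_mean <- tapply(psu_tot, strat, mean)[strat]
  dev2 <- (psu_tot - strat_mean)^2
  v <- sum((as.numeric(n_h) / pmax(as.numeric(n_h) - 1, 1)) * dev2)
  if (any(lone) && lonely_psu == "center") {
    # conservative: deviation of the lone PSU total from the grand PSU mean
    v <- v + sum((psu_tot[lone] - mean(psu_tot))^2)
  }
  v
}

#' Design-based estimate of a proportion (or mean)
#'
#' Weighted ratio-to-domain estimator
#' \eqn{\hat p = \sum_i w_i y_i d_i / \sum_i w_i d_i} with Taylor-linearized
#' variance under the stratified with-replacement-PSU approximation: the
#' linearized score of record *i* is
#' \eqn{u_i = w_i d_i (y_i - \hat p) / \sum_i w_i d_i}, PSU score totals are
#' contrasted within strata with an \eqn{n_h/(n_h-1)} factor, and the
#' design degrees of freedom are (number of PSUs) − (number of strata).
#' The 95% interval is computed on the logit scale and back-transformed,
#' falling back to a plain Wald interval when the estimate is 0 or 1 (or
#' when `ci_method = "wald"`).
#'
#' Point estimates, and standard errors under this with-replacement
#' formula, are invariant to uniform rescaling of the weights.
#'
#' @param y numeric or logical response per record (0/1 for a proportion;
#'   any numeric for a ratio mean such as the co-coverage index).
#' @param design a [survey_design()] covering the same records.
#' @param domain optional logical vector restricting estimation to a
#'   subpopulation; variance correctly accounts for the random domain size
#'   by keeping all PSUs in the contrasts. Must select at least one record
#'   with positive weight.
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"logit"` (default) or `"wald"`.
#' @param lonely_psu policy for strata containing a single PSU: `"center"`
#'   (default; contrast the lone PSU total against the grand mean —
#'   conservative), `"certainty"` (contributes zero variance), or
#'   `"error"`.
#' @return A one-row tibble of class `pnc_estimate`: `estimate`, `se`,
#'   `ci_low`, `ci_high`, `df`, unweighted `n` and weighted `N` in the
#'   domain, and the `ci_method` used.
#' @export
weighted_proportion <- function(y, design, domain = NULL,
                                conf_level = 0.95,
                                ci_method = c("logit", "wald"),
                                lonely_psu = c("center", "certainty", "error")) {
  stopifnot(inherits(design, "pnc_design"))
  ci_method <- match.arg(ci_method)
  lonely_psu <- match.arg(lonely_psu)
  y <- as.numeric(y)
  stopifnot(length(y) == design$n)
  d <- if (is.null(domain)) rep(TRUE, design$n) else as.logical(domain)
  stopifnot(length(d) == design$n)
  d[is.na(d)] <- FALSE
  if (anyNA(y[d])) stop("response contains missing values inside the domain",
                        call. = FALSE)

  w <- design$weight * d
  W <- sum(w)
  if (W <= 0) {
    stop("empty domain: no record with positive weight selected",
         call. = FALSE)
  }
  p <- sum(w * y) / W

  u <- w * (y - p) / W
  v <- taylor_variance(u, design, lonely_psu)
  se <- sqrt(max(v, 0))

  df <- design$n_psu - design$n_strata
  tq <- if (df >= 1) qt(1 - (1 - conf_level) / 2, df)
        else qnorm(1 - (1 - conf_level) / 2)

  is_prop <- all(y[d] %in% c(0, 1))
  used <- ci_method
  if (ci_method == "logit" && (!is_prop || p <= 0 || p >= 1 || se == 0)) {
    used <- "wald"
  }
  if (used == "logit") {
    l <- qlogis(p)
    se_l <- se / (p * (1 - p))
    ci <- plogis(l + c(-1, 1) * tq * se_l)
  } else {
    ci <- p + c(-1, 1) * tq * se
    if (is_prop) ci <- pmin(pmax(ci, 0), 1)
  }

  out <- tibble::tibble(
    estimate = p, se = se, ci_low = ci[1], ci_high = ci[2],
    df = df, n = sum(d), N = W, ci_method = used
  )
  class(out) <- c("pnc_estimate", class(out))
  out
}
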