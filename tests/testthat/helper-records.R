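# builders and independent brute-force oracles shared across tests

make_records <- function(n = 1, ...) {
  base <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    stratum = "1",
    psu = sprintf("p%03d", seq_len(n)),
    weight = 1,
    is_most_recent = TRUE,
    interview_cmc = 1416L,
    birth_cmc = 1410L,
    days_since_birth = 180L,
    child_alive = TRUE,
    age_at_death_days = NA_integer_,
    place_delivery = "facility",
    q438 = "no", q438_timing_days = NA_real_,
    q445 = "no", q445_timing_days = NA_real_,
    q453 = "missing", q453_timing_days = NA_real_,
    q457a = "no", q457b = "no", q457c = "no", q457d = "no", q457e = "no"
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

# brute-force weighted domain proportion: plain loop, no shared code path
bf_proportion <- function(y, w, domain = rep(TRUE, length(y))) {
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    if (domain[i]) {
      num <- num + w[i] * y[i]
      den <- den + w[i]
    }
  }
  num / den
}

bf_cocoverage_shares <- function(counts, w, domain = rep(TRUE, length(w))) {
  tot <- 0; acc <- numeric(6)
  for (i in seq_along(counts)) {
    if (domain[i]) {
      acc[counts[i] + 1] <- acc[counts[i] + 1] + w[i]
      tot <- tot + w[i]
    }
  }
  acc / tot
}

bf_agreement <- function(M, w) {
  k <- ncol(M)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(M), colnames(M)))
  for (u in 1:k) for (v in 1:k) {
    s <- 0
    for (i in seq_len(nrow(M))) {
      if (M[i, u] == M[i, v]) s <- s + w[i]
    }
    out[u, v] <- s / sum(w)
  }
  out
}

# a random small indicator dataset with a valid nested design
random_indicator_data <- function() {
  n_str <- sample(1:3, 1)
  psu_per <- sample(2:4, 1)
  m <- sample(2:6, 1)
  n <- n_str * psu_per * m
  tibble::tibble(
    stratum = rep(seq_len(n_str), each = psu_per * m),
    psu = rep(seq_len(n_str * psu_per), each = m),
    weight = round(runif(n, 0.2, 3), 4),
    A = runif(n) < 0.5,
    B1 = runif(n) < 0.5, B2 = runif(n) < 0.5, B3 = runif(n) < 0.5,
    B4 = runif(n) < 0.5, B5 = runif(n) < 0.5
  )
}

# Rao-Wu rescaled cluster bootstrap SE of a weighted proportion
bootstrap_se <- function(y, stratum, psu, w, B = 10000) {
  psu_rows <- split(seq_along(y), psu)
  psu_stratum <- vapply(psu_rows, function(r) stratum[r[1]], stratum[1])
  strata <- unique(psu_stratum)
  est <- numeric(B)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(strata, function(h) {
      ps <- names(psu_rows)[psu_stratum == h]
      unlist(psu_rows[sample(ps, length(ps), replace = TRUE)],
             use.names = FALSE)
    }), use.names = FALSE)
    est[b] <- sum(w[idx] * y[idx]) / sum(w[idx])
  }
  n_h <- length(psu_rows) / length(strata)
  sqrt(stats::var(est) * n_h / (n_h - 1))
}
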