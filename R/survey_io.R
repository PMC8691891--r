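#' Load a birth-level survey extract
#'
#' Reads a flat CSV extract (one row per most-recent live birth) and
#' translates it into the internal birth-record table through a
#' [column_mapping()]. Raw response codes are translated via the mapping's
#' value dictionaries; an unknown code is a hard error naming the row and
#' column. Rows violating record invariants (negative or absent weight,
#' responses present on the wrong side of the facility/non-facility routing)
#' are rejected into a row-indexed report rather than silently coerced, so
#' that `rows in = records out + rejections` always holds.
#'
#' @param path path to a CSV file with a header row.
#' @param mapping a [column_mapping()] describing the file.
#' @return A tibble of birth records (one row per accepted record) with
#'   canonical columns: design variables (`stratum`, `psu`, `weight` on the
#'   true scale), dates as CMC months (`interview_cmc`, `birth_cmc`) plus
#'   `days_since_birth`, survival fields, `place_delivery`, the three
#'   postnatal-check responses `q438`/`q445`/`q453` with their first-check
#'   timing in days, and the five intervention responses `q457a`–`q457e`.
#'   The attribute `"rejections"` holds a tibble with columns `row` and
#'   `reason` for every rejected input row.
#' @export
load_births <- function(path, mapping = column_mapping("dhs")) {
  stopifnot(inherits(mapping, "pnc_mapping"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    stop("empty extract: ", path, " contains a header but no rows",
         call. = FALSE)
  }

  missing_cols <- setdiff(unname(mapping$columns), names(raw))
  if (length(missing_cols) > 0) {
    stop("extract is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  src <- function(field) raw[[mapping$columns[[field]]]]
  num <- function(field) {
    x <- src(field)
    x[x == ""] <- NA_character_
    suppressWarnings(as.numeric(x))
  }

  response_fields <- c("q438", "q445", "q453", .B_COLUMNS)
  rec <- tibble::tibble(
    record_id = {
      id <- src("record_id")
      if (is.null(id)) as.character(seq_len(nrow(raw))) else id
    },
    stratum = src("stratum"),
    psu = src("psu"),
    weight = num("weight") / mapping$weight_scale,
    is_most_recent = as.logical(translate_codes(
      src("is_most_recent"), mapping$codes$logical, mapping$columns[["is_most_recent"]])),
    interview_cmc = if (mapping$dates == "cmc") as.integer(num("interview_cmc"))
                    else cmc_from_iso(src("interview_cmc")),
    birth_cmc = if (mapping$dates == "cmc") as.integer(num("birth_cmc"))
                else cmc_from_iso(src("birth_cmc")),
    days_since_birth = as.integer(num("days_since_birth")),
    child_alive = as.logical(translate_codes(
      src("child_alive"), mapping$codes$logical, mapping$columns[["child_alive"]])),
    age_at_death_days = as.integer(num("age_at_death_days")),
    place_delivery = translate_codes(
      src("place_delivery"), mapping$codes$place, mapping$columns[["place_delivery"]])
  )
  for (f in response_fields) {
    rec[[f]] <- translate_codes(src(f), mapping$codes$response,
                                mapping$columns[[f]])
  }
  for (f in c("q438_timing_days", "q445_timing_days", "q453_timing_days")) {
    rec[[f]] <- num(f)
  }
  rec <- rec[, .RECORD_COLUMNS]

  # invariant screen: rejected rows are reported, never silently dropped
  reason <- rep(NA_character_, nrow(rec))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(rec$weight), "missing_weight")
  flag(rec$weight < 0, "negative_weight")
  facility <- rec$place_delivery == "facility"
  flag(facility & rec$q453 != "missing", "routing_violation")
  flag(!facility & (rec$q438 != "missing" | rec$q445 != "missing"),
       "routing_violation")
  flag(!rec$child_alive & is.na(rec$age_at_death_days),
       "dead_child_without_age_at_death")
  flag(rec$child_alive & !is.na(rec$age_at_death_days),
       "age_at_death_on_living_child")

  keep <- is.na(reason)
  rejections <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  out <- rec[keep, ]
  attr(out, "rejections") <- rejections
  out
}

#' Write analysis result tables and run metadata
#'
#' Writes one CSV per named table plus a `run_metadata.json` file recording
#' the seed, a configuration hash, record counts and the table manifest.
#' Numeric columns are written at full precision; `digits` applies display
#' rounding at write time only.
#'
#' @param tables named list of data frames (may be empty).
#' @param path output directory, created if needed.
#' @param meta named list merged into the metadata JSON (e.g. `seed`,
#'   `config`, record counts). A `config` entry is hashed into
#'   `config_hash`.
#' @param digits optional integer; if supplied, numeric columns are rounded
#'   to this many digits in the written CSVs (presentation only).
#' @return A tibble manifest with columns `table`, `file`, `rows`, invisibly
#'   also written into the metadata file.
#' @export
write_report <- function(tables, path, meta = list(), digits = NULL) {
  if (length(tables) > 0 &&
      (is.null(names(tables)) || any(names(tables) == ""))) {
    stop("`tables` must be a fully named list", call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path,
                              call. = FALSE)

  manifest <- tibble::tibble(
    table = names(tables) %||% character(),
    file = file.path(path, paste0(names(tables) %||% character(), ".csv")),
    rows = vapply(tables, nrow, integer(1), USE.NAMES = FALSE)
  )
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    numcols <- vapply(tab, is.double, logical(1))
    if (!is.null(digits)) {
      tab[numcols] <- lapply(tab[numcols], round, digits = digits)
    } else {
      # 17 significant digits: doubles survive the round trip bit-exactly
      tab[numcols] <- lapply(tab[numcols], function(x) {
        ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
      })
    }
    readr::write_csv(tab, manifest$file[i])
  }

  if (!is.null(meta$config)) {
    meta$config_hash <- rlang::hash(meta$config)
    meta$config <- rapply(unclass(meta$config), unclass, how = "replace")
  }
  meta$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  meta$tables <- manifest$table
  meta$table_rows <- as.list(setNames(manifest$rows, manifest$table))
  jsonlite::write_json(meta, file.path(path, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
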