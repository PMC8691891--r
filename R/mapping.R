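#' Column mapping between a survey extract and the internal birth record
#'
#' A mapping names, for every logical field of a birth record, the source
#' column in a flat CSV extract, together with value dictionaries that
#' translate raw response codes into the canonical categories
#' `yes` / `no` / `dont_know` / `missing`, a date convention, and the
#' weight-scaling convention.
#'
#' Two dialects ship with the package:
#' \describe{
#'   \item{`"dhs"`}{numeric codes as in DHS recodes: responses coded
#'     `1` = yes, `0` = no, `8` = don't know, `9`/blank = missing; dates as
#'     century-month codes (months since January 1900); stored weights equal
#'     the true weight multiplied by 1e6.}
#'   \item{`"plain"`}{human-readable: literal `yes`/`no`/`dont_know`/`missing`
#'     strings, ISO calendar dates, unscaled weights.}
#' }
#'
#' Value dictionaries must be exhaustive over the codes present in a file:
#' [load_births()] fails loudly on any unmapped code rather than coercing it
#' to missing, because the consistency analysis downstream depends on
#' distinguishing a reported "no" from an absent response.
#'
#' @param dialect `"dhs"` or `"plain"`; selects the default column names,
#'   code dictionaries, date convention and weight scale.
#' @param columns named character vector overriding source-column names;
#'   names are logical field names (see [load_births()]).
#' @param response_codes named character vector mapping raw response codes to
#'   canonical categories, overriding the dialect default.
#' @param weight_scale divisor applied to the stored weight (1e6 for DHS
#'   convention, 1 for plain).
#' @param dates `"cmc"` (months since January 1900) or `"iso"`
#'   (`YYYY-MM-DD` calendar dates, converted to CMC months on load).
#'
#' @return An object of class `pnc_mapping`.
#' @examples
#' m <- column_mapping("dhs")
#' m$weight_scale
#' @export
column_mapping <- function(dialect = c("dhs", "plain"),
                           columns = NULL,
                           response_codes = NULL,
                           weight_scale = NULL,
                           dates = NULL) {
  dialect <- match.arg(dialect)

  cols <- setNames(.RECORD_COLUMNS, .RECORD_COLUMNS)
  if (dialect == "plain") {
    cols[["interview_cmc"]] <- "interview_date"
    cols[["birth_cmc"]] <- "birth_date"
  }
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), .RECORD_COLUMNS)
    if (length(bad) > 0) {
      stop("unknown logical field(s) in `columns`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cols[names(columns)] <- columns
  }
  if (anyDuplicated(cols)) {
    stop("each logical field must map to a distinct source column",
         call. = FALSE)
  }

  codes <- if (dialect == "dhs") {
    list(
      response = c("1" = "yes", "0" = "no", "8" = "dont_know",
                   "9" = "missing", ".na" = "missing"),
      place = c("1" = "facility", "2" = "non_facility"),
      logical = c("1" = "TRUE", "0" = "FALSE")
    )
  } else {
    list(
      response = c(yes = "yes", no = "no", dont_know = "dont_know",
                   missing = "missing", .na = "missing"),
      place = c(facility = "facility", non_facility = "non_facility"),
      logical = c("TRUE" = "TRUE", "FALSE" = "FALSE")
    )
  }
  if (!is.null(response_codes)) codes$response <- response_codes

  structure(
    list(
      dialect = dialect,
      columns = cols,
      codes = codes,
      weight_scale = weight_scale %||%
        if (dialect == "dhs") 1e6 else 1,
      dates = dates %||% if (dialect == "dhs") "cmc" else "iso"
    ),
    class = "pnc_mapping"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.pnc_mapping <- function(x, ...) {
  cat("<pnc_mapping> dialect:", x$dialect,
      "| dates:", x$dates,
      "| weight scale: 1/", format(x$weight_scale), "\n", sep = " ")
  invisible(x)
}

#' Write or read a column mapping as YAML
#'
#' @param mapping a [column_mapping()] object.
#' @param path file path of the YAML mapping.
#' @return `write_mapping()` returns `path` invisibly; `read_mapping()`
#'   returns a `pnc_mapping`.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "pnc_mapping"))
  out <- list(
    dialect = mapping$dialect,
    columns = as.list(mapping$columns),
    codes = lapply(mapping$codes, as.list),
    weight_scale = mapping$weight_scale,
    dates = mapping$dates
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  raw <- yaml::read_yaml(path)
  m <- column_mapping(raw$dialect)
  m$columns[names(raw$columns)] <- unlist(raw$columns)
  m$codes <- lapply(raw$codes, function(d) unlist(d))
  m$weight_scale <- raw$weight_scale
  m$dates <- raw$dates
  m
}

# translate one coded column via a value dictionary; error names offending
# rows and the source column so bad files fail loudly, never silently
translate_codes <- function(x, dict, column) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- ".na"
  unknown <- !(x %in% names(dict))
  if (any(unknown)) {
    rows <- which(unknown)
    stop(sprintf(
      "unknown code(s) in column '%s' at row(s) %s: %s",
      column,
      paste(head(rows, 5L), collapse = ", "),
      paste(unique(head(x[unknown], 5L)), collapse = ", ")
    ), call. = FALSE)
  }
  unname(dict[x])
}

cmc_from_iso <- function(x) {
  d <- as.Date(x)
  if (anyNA(d) && !all(is.na(x) | x == "")) {
    stop("unparseable ISO date(s): ",
         paste(unique(head(x[is.na(d) & !(is.na(x) | x == "")], 5L)),
               collapse = ", "), call. = FALSE)
  }
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  (y - 1900L) * 12L + m
}

iso_from_cmc <- function(cmc) {
  y <- 1900L + (cmc - 1L) %/% 12L
  m <- (cmc - 1L) %% 12L + 1L
  sprintf("%04d-%02d-15", y, m)
}
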