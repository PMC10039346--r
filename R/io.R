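#' @name io
#' @title Reading and writing the canonical flat tables
#'
#' @description
#' The pipeline consumes three tab-separated tables with a header row:
#'
#' * `persons`: `person_id`, `sex` (`male`/`female`), `birth_year`
#' * `measurements`: `person_id`, `analyte_code`, `value`, `unit`, `date`
#'   (ISO-8601), `ref_low`, `ref_high` (either bound may be empty)
#' * `events`: `person_id`, `code_type` (`ICD10`/`ATC`), `code`, `date`
#'
#' `read_ehr_table()` validates rows and returns both the accepted records and
#' a rejection report; `write_results()` writes any result table so that a
#' round-trip read reproduces the values.
NULL

.schemas <- list(
  persons = c("person_id", "sex", "birth_year"),
  measurements = c("person_id", "analyte_code", "value", "unit", "date",
                   "ref_low", "ref_high"),
  events = c("person_id", "code_type", "code", "date")
)

#' Read one of the three canonical EHR tables
#'
#' Reads a tab-separated file with a header, checks the header against the
#' requested schema, and validates every row. Invalid rows are not fatal:
#' they are returned in a rejection report with their 1-based data row number
#' and the reason.
#'
#' @param path Path to a TSV file.
#' @param schema One of `"persons"`, `"measurements"`, `"events"`.
#' @return A list with elements `records` (validated data.frame; dates as
#'   `Date`, numerics as numeric) and `rejected` (data.frame with columns
#'   `row`, `reason`).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("person_id\tsex\tbirth_year", "p1\tmale\t1950"), tf)
#' read_ehr_table(tf, "persons")$records
#' @export
read_ehr_table <- function(path, schema = c("persons", "measurements", "events")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file does not exist: ", path)
  cols <- .schemas[[schema]]
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0L)
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " for schema '", schema, "'")
  raw <- raw[, cols, drop = FALSE]
  n <- nrow(raw)
  reason <- character(n)

  parse_num <- function(x) suppressWarnings(as.numeric(x))
  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")

  if (schema == "persons") {
    by <- parse_num(raw$birth_year)
    bad_sex <- !(raw$sex %in% c("male", "female"))
    bad_by <- is.na(by) | by != floor(by) | by < 1900 |
      by > as.integer(format(Sys.Date(), "%Y"))
    reason[bad_sex] <- "invalid sex"
    reason[bad_by & reason == ""] <- "invalid birth_year"
    dup <- duplicated(raw$person_id) | duplicated(raw$person_id, fromLast = TRUE)
    first_of_dup <- duplicated(raw$person_id)
    reason[first_of_dup & reason == ""] <- "duplicate person_id"
    ok <- reason == ""
    rec <- data.frame(person_id = raw$person_id[ok], sex = raw$sex[ok],
                      birth_year = as.integer(by[ok]), stringsAsFactors = FALSE)
  } else if (schema == "measurements") {
    val <- parse_num(raw$value)
    dt <- parse_date(raw$date)
    lo <- parse_num(raw$ref_low)   # empty -> NA, allowed
    hi <- parse_num(raw$ref_high)
    lo[raw$ref_low == ""] <- NA_real_
    hi[raw$ref_high == ""] <- NA_real_
    reason[!is.finite(val)] <- "non-finite value"
    reason[is.na(dt) & reason == ""] <- "unparseable date"
    bad_ref <- !is.na(lo) & !is.na(hi) & !(lo < hi)
    reason[bad_ref & reason == ""] <- "ref_low not below ref_high"
    bad_lo <- raw$ref_low != "" & is.na(lo)
    bad_hi <- raw$ref_high != "" & is.na(hi)
    reason[(bad_lo | bad_hi) & reason == ""] <- "unparseable reference bound"
    ok <- reason == ""
    rec <- data.frame(person_id = raw$person_id[ok],
                      analyte_code = raw$analyte_code[ok],
                      value = val[ok], unit = raw$unit[ok], date = dt[ok],
                      ref_low = lo[ok], ref_high = hi[ok],
                      stringsAsFactors = FALSE)
  } else {
    dt <- parse_date(raw$date)
    bad_type <- !(raw$code_type %in% c("ICD10", "ATC"))
    empty_code <- raw$code == ""
    bad_icd <- raw$code_type == "ICD10" & !grepl("^[A-Z][0-9]{2}", raw$code)
    reason[bad_type] <- "invalid code_type"
    reason[empty_code & reason == ""] <- "empty code"
    reason[bad_icd & reason == ""] <- "malformed ICD-10 code"
    reason[is.na(dt) & reason == ""] <- "unparseable date"
    ok <- reason == ""
    rec <- data.frame(person_id = raw$person_id[ok],
                      code_type = raw$code_type[ok], code = raw$code[ok],
                      date = dt[ok], stringsAsFactors = FALSE)
  }
  rejected <- data.frame(row = which(reason != ""),
                         reason = reason[reason != ""],
                         stringsAsFactors = FALSE)
  list(records = rec, rejected = rejected)
}

#' Write a result table as TSV
#'
#' Tab-separated with header, no quoting, no row names. Numeric columns are
#' formatted at 12 significant digits so a round-trip read reproduces values
#' to declared precision; `Date` columns are written as ISO-8601.
#'
#' @param records A data.frame (may have zero rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (inherits(out[[j]], "Date")) {
      out[[j]] <- format(out[[j]], "%Y-%m-%d")
    } else if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 12, format = "g"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write the three simulation tables to a directory
#'
#' @param sim A simulation result as produced by [sim_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results(sim$persons, file.path(dir, "persons.tsv"))
  write_results(sim$measurements, file.path(dir, "measurements.tsv"))
  write_results(sim$events, file.path(dir, "events.tsv"))
  invisible(dir)
}
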