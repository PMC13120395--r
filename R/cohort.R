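# Cohort table: domain types, CSV reader/writer, validation, and the
# inflammation scoring rule used for oral smears.

COHORT_MANDATORY <- c(
  "cat_id", "exposure", "age", "sex", "smoker_owners", "cigarettes_per_day"
)
COHORT_OPTIONAL <- c(
  "cotinine_ng_ml", "inflammation_score", "dysplasia_grade", "case_nc_ratio"
)

# normalize a header name: lower-case, strip everything non-alphanumeric
.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# accepted spellings for each canonical column, in normalized form
.header_aliases <- function() {
  list(
    cat_id             = c("catid", "id"),
    exposure           = "exposure",
    age                = c("age", "ageyears"),
    sex                = "sex",
    smoker_owners      = c("smokerowners", "smokerownersn", "nsmokers"),
    cigarettes_per_day = c("cigarettesperday", "cigarettesday", "cigsperday"),
    cotinine_ng_ml     = c("cotininengml", "cotinine"),
    inflammation_score = c("inflammationscore", "inflammation"),
    dysplasia_grade    = c("dysplasiagrade", "dysplasia"),
    case_nc_ratio      = c("casencratio", "ncratio")
  )
}

#' Construct a validated cohort
#'
#' A cohort is an ordered table of animals with household tobacco-smoke
#' exposure covariates and optional cytology / biomarker measurements.
#' Validation enforces unique animal ids, a binary exposure label, and the
#' consistency rule that non-exposed animals have zero smoker owners and
#' zero cigarettes per day.
#'
#' @param records data.frame with at least the mandatory columns
#'   `cat_id, exposure, age, sex, smoker_owners, cigarettes_per_day`; optional
#'   columns `cotinine_ng_ml, inflammation_score, dysplasia_grade,
#'   case_nc_ratio` may be present (missing values allowed).
#' @param provenance free-text label recording where the table came from.
#' @return an object of class `cohort` (a data.frame).
#' @export
cohort <- function(records, provenance = "unspecified") {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_MANDATORY, names(records))
  if (length(missing_cols) > 0) {
    stop_oralcyto(
      sprintf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")),
      "oralcyto_schema_error"
    )
  }
  records <- validate_cohort_records(records)
  keep <- intersect(c(COHORT_MANDATORY, COHORT_OPTIONAL), names(records))
  records <- records[, keep, drop = FALSE]
  structure(records,
    provenance = provenance,
    class = c("cohort", "data.frame")
  )
}

# field-level validation; returns the cleaned records or signals a classed error
validate_cohort_records <- function(df) {
  df$cat_id <- as.character(df$cat_id)
  if (anyDuplicated(df$cat_id)) {
    stop_oralcyto(
      sprintf("duplicate cat_id: %s",
              paste(unique(df$cat_id[duplicated(df$cat_id)]), collapse = ", ")),
      "oralcyto_validation_error"
    )
  }

  exp_raw <- tolower(gsub("[^a-zA-Z]", "_", trimws(as.character(df$exposure))))
  exp_map <- c(exposed = "exposed", non_exposed = "non_exposed")
  if (!all(exp_raw %in% names(exp_map)) && nrow(df) > 0) {
    bad <- which(!exp_raw %in% names(exp_map))
    stop_oralcyto(
      sprintf("row %d: unrecognized exposure value '%s'", bad[1], df$exposure[bad[1]]),
      "oralcyto_validation_error"
    )
  }
  df$exposure <- unname(exp_map[exp_raw])

  num_field <- function(col, allow_missing = FALSE) {
    v <- df[[col]]
    if (is.null(v)) return(NULL)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad) > 0) {
      stop_oralcyto(
        sprintf("row %d: non-numeric value '%s' in column %s", bad[1], v[bad[1]], col),
        "oralcyto_validation_error"
      )
    }
    if (!allow_missing && anyNA(out) && nrow(df) > 0) {
      stop_oralcyto(sprintf("missing value in mandatory column %s", col),
                    "oralcyto_validation_error")
    }
    out
  }
  df$age <- num_field("age")
  df$smoker_owners <- num_field("smoker_owners")
  df$cigarettes_per_day <- num_field("cigarettes_per_day")
  for (col in COHORT_OPTIONAL) {
    if (col %in% names(df)) df[[col]] <- num_field(col, allow_missing = TRUE)
  }

  if (nrow(df) > 0) {
    if (any(df$age <= 0)) {
      stop_oralcyto("age must be positive", "oralcyto_validation_error")
    }
    df$sex <- toupper(trimws(as.character(df$sex)))
    if (!all(df$sex %in% c("M", "F"))) {
      stop_oralcyto("sex must be 'M' or 'F'", "oralcyto_validation_error")
    }
    if (any(df$smoker_owners < 0) || any(df$smoker_owners != round(df$smoker_owners))) {
      stop_oralcyto("smoker_owners must be a non-negative integer",
                    "oralcyto_validation_error")
    }
    if (any(df$cigarettes_per_day < 0)) {
      stop_oralcyto("cigarettes_per_day must be non-negative",
                    "oralcyto_validation_error")
    }
    ne <- df$exposure == "non_exposed"
    if (any(ne & (df$smoker_owners != 0 | df$cigarettes_per_day != 0))) {
      stop_oralcyto(
        "non-exposed records must have smoker_owners == 0 and cigarettes_per_day == 0",
        "oralcyto_validation_error"
      )
    }
    for (col in c("inflammation_score", "dysplasia_grade")) {
      if (col %in% names(df)) {
        v <- df[[col]]
        ok <- is.na(v) | (v %in% 0:3)
        if (!all(ok)) {
          stop_oralcyto(sprintf("%s must be an integer in 0..3", col),
                        "oralcyto_validation_error")
        }
      }
    }
    if ("cotinine_ng_ml" %in% names(df) &&
        any(!is.na(df$cotinine_ng_ml) & df$cotinine_ng_ml < 0)) {
      stop_oralcyto("cotinine_ng_ml must be >= 0", "oralcyto_validation_error")
    }
    if ("case_nc_ratio" %in% names(df) &&
        any(!is.na(df$case_nc_ratio) & df$case_nc_ratio <= 0)) {
      stop_oralcyto("case_nc_ratio must be positive", "oralcyto_validation_error")
    }
  }
  df
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated UTF-8 table with a header. Column names are matched
#' case-insensitively and ignoring punctuation, so both the machine-readable
#' schema (`cat_id,exposure,...`) and report-style headers
#' (`Cat ID, Exposure, Age, Sex, Smoker Owners (n), Cigarettes/Day`) are
#' accepted. Exposure values `exposed`/`Exposed` and
#' `non_exposed`/`Non-exposed`/`non-exposed` are recognized. Optional columns
#' that are absent stay missing (they are never imputed as zero).
#'
#' @param path path to a CSV file.
#' @param provenance optional provenance label; defaults to the file name.
#' @return a [cohort()] object.
#' @export
read_cohort_table <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) {
    stop_oralcyto(sprintf("file not found: %s", path), "oralcyto_io_error")
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  aliases <- .header_aliases()
  normed <- .norm_header(names(raw))
  out <- list()
  for (canon in names(aliases)) {
    hit <- which(normed %in% c(.norm_header(canon), aliases[[canon]]))
    if (length(hit) > 0) out[[canon]] <- raw[[hit[1]]]
  }
  missing_cols <- setdiff(COHORT_MANDATORY, names(out))
  if (length(missing_cols) > 0) {
    stop_oralcyto(
      sprintf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")),
      "oralcyto_schema_error"
    )
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  # empty strings in optional numeric columns are missing values
  for (col in COHORT_OPTIONAL) {
    if (col %in% names(df)) df[[col]][df[[col]] == ""] <- NA
  }
  cohort(df, provenance = provenance)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort_table()]: the canonical column schema is used so
#' that a write/read round trip reproduces every field.
#'
#' @param x a [cohort()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Inflammation score from inflammatory-cell density
#'
#' Maps a mean inflammatory-cell count per high-power field (HPF) onto the
#' ordinal 0-3 smear inflammation scale: 0 = no inflammation (near-complete
#' absence of inflammatory cells, operationalized as fewer than
#' `none_below` cells/HPF), 1 = mild (< 30), 2 = moderate (30-100,
#' inclusive on both ends), 3 = marked (> 100).
#'
#' @param cells_per_hpf non-negative numeric vector of mean inflammatory-cell
#'   counts per HPF.
#' @param none_below counts strictly below this value score 0; default 1.
#' @return integer vector of scores in 0..3.
#' @export
inflammation_score_from_count <- function(cells_per_hpf, none_below = 1) {
  if (!is.numeric(cells_per_hpf) || any(is.na(cells_per_hpf))) {
    stop_oralcyto("cells_per_hpf must be numeric and non-missing",
                  "oralcyto_domain_error")
  }
  if (any(cells_per_hpf < 0)) {
    stop_oralcyto("cells_per_hpf must be >= 0", "oralcyto_domain_error")
  }
  score <- ifelse(cells_per_hpf < none_below, 0L,
           ifelse(cells_per_hpf < 30, 1L,
           ifelse(cells_per_hpf <= 100, 2L, 3L)))
  as.integer(score)
}

#' Summarize exposure covariates per group
#'
#' Tabulates, within each exposure group, the number of animals by
#' smoker-owner count and by sex.
#'
#' @param x a [cohort()] object with at least one record.
#' @return a list with one element per exposure group, each containing `n`,
#'   `by_smoker_owners` (named count table) and `by_sex`.
#' @export
summarize_exposure <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (nrow(x) == 0) {
    stop_oralcyto("cohort is empty", "oralcyto_domain_error")
  }
  out <- lapply(split(as.data.frame(x), x$exposure), function(g) {
    list(
      n = nrow(g),
      by_smoker_owners = table(g$smoker_owners),
      by_sex = table(factor(g$sex, levels = c("F", "M")))
    )
  })
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d records (%d exposed, %d non-exposed); provenance: %s\n",
              nrow(x), sum(x$exposure == "exposed"),
              sum(x$exposure == "non_exposed"),
              attr(x, "provenance")))
  NextMethod()
}

#' Path to the bundled smoke-exposure cohort table
#'
#' Individual-level demographics and household-exposure covariates for a
#' 30-cat indoor cohort (20 exposed to household tobacco smoke, 10
#' non-exposed); the worked dataset used throughout the package's examples
#' and statistical report.
#'
#' @return file path of the CSV inside the installed package.
#' @export
example_cohort_path <- function() {
  system.file("extdata", "smoke_exposure_cohort.csv", package = "oralcyto",
              mustWork = TRUE)
}
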