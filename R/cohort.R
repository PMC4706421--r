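# Canonical subject-level column vocabulary. All scoring code addresses
# columns by these names; read_cohort() maps common clinical-export labels
# onto them.
cohort_columns <- function() {
  c("subject_id", "sex", "age", "height", "weight", "waist",
    "systolic_bp", "diastolic_bp", "glucose", "insulin",
    "triglycerides", "hdl", "family_history_cv",
    "treated_lipids", "treated_bp", "treated_glucose", "treated_hdl")
}

cohort_numeric_columns <- function() {
  c("age", "height", "weight", "waist", "systolic_bp", "diastolic_bp",
    "glucose", "insulin", "triglycerides", "hdl")
}

cohort_logical_columns <- function() {
  c("family_history_cv", "treated_lipids", "treated_bp",
    "treated_glucose", "treated_hdl")
}

# Alias map: normalized header label -> canonical column. Headers are
# normalized by lower-casing and stripping everything but letters/digits, so
# "TA_systolic", "ta systolic" and "TASystolic" all resolve identically.
column_aliases <- function() {
  c(
    subjectid = "subject_id", id = "subject_id", patientid = "subject_id",
    patient = "subject_id", subject = "subject_id",
    sex = "sex", gender = "sex",
    age = "age", ageyears = "age",
    height = "height", heightcm = "height", bodyheight = "height",
    weight = "weight", weightkg = "weight", bodyweight = "weight",
    waist = "waist", waistcm = "waist", waistcircumference = "waist",
    wc = "waist",
    systolicbp = "systolic_bp", sbp = "systolic_bp", systolic = "systolic_bp",
    tasystolic = "systolic_bp", bpsystolic = "systolic_bp",
    diastolicbp = "diastolic_bp", dbp = "diastolic_bp",
    diastolic = "diastolic_bp", tadiastolic = "diastolic_bp",
    bpdiastolic = "diastolic_bp",
    glucose = "glucose", gly = "glucose", fastingglucose = "glucose",
    glu = "glucose",
    insulin = "insulin", fastinginsulin = "insulin", ins = "insulin",
    triglycerides = "triglycerides", tg = "triglycerides",
    trig = "triglycerides", triglyceride = "triglycerides",
    hdl = "hdl", hdlcholesterol = "hdl", hdlc = "hdl",
    familyhistorycv = "family_history_cv", familyhistory = "family_history_cv",
    fhcv = "family_history_cv", fh = "family_history_cv",
    famhistory = "family_history_cv",
    treatedlipids = "treated_lipids", lipidtreatment = "treated_lipids",
    treatedbp = "treated_bp", bptreatment = "treated_bp",
    antihypertensives = "treated_bp",
    treatedglucose = "treated_glucose", glucosetreatment = "treated_glucose",
    treatedhdl = "treated_hdl", hdltreatment = "treated_hdl"
  )
}

normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# Plausibility ceilings guarding against mg/dL (or other wrong-unit) input.
# Fasting glucose above 30 mmol/L, HDL above 12 mmol/L or triglycerides above
# 40 mmol/L are physiologically impossible on the mmol/L scale but typical of
# mg/dL exports; such files are rejected rather than silently mis-scored.
unit_ceilings <- function() {
  c(glucose = 30, hdl = 12, triglycerides = 40)
}

parse_sex <- function(x) {
  raw <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("m", "male", "1")] <- "male"
  out[raw %in% c("f", "female", "2")] <- "female"
  bad <- !is.na(raw) & raw != "" & is.na(out)
  if (any(bad)) {
    warning(sum(bad), " unrecognized sex value(s) set to missing (first: '",
            raw[which(bad)[1]], "').", call. = FALSE)
  }
  out
}

parse_flag <- function(x, column) {
  if (is.logical(x)) return(x)
  raw <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(raw))
  out[raw %in% c("true", "t", "yes", "y", "1", "+")] <- TRUE
  out[raw %in% c("false", "f", "no", "n", "0", "-")] <- FALSE
  bad <- !is.na(raw) & raw != "" & is.na(out)
  if (any(bad)) {
    warning(sum(bad), " unparseable value(s) in '", column,
            "' set to missing.", call. = FALSE)
  }
  out
}

parse_quantity <- function(x, column) {
  if (is.numeric(x)) return(as.numeric(x))
  raw <- trimws(as.character(x))
  raw[raw == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & is.na(out)
  if (any(bad)) {
    warning(sum(bad), " unparseable cell(s) in '", column,
            "' set to missing (first: '", raw[which(bad)[1]], "').",
            call. = FALSE)
  }
  out
}

#' Coerce a data frame to a validated cohort
#'
#' Maps column names through the package alias vocabulary, coerces types,
#' enforces subject-level invariants and returns a tibble with the full
#' canonical column set (absent fields become all-missing columns).
#' Missingness stays explicit: nothing is imputed.
#'
#' Validation rules: `subject_id`, `sex` and `age` columns are mandatory and
#' subject ids must be unique (errors); unparseable cells, non-positive
#' physical quantities and systolic <= diastolic pressure pairs become
#' missing values with a warning; glucose, HDL or triglyceride values beyond
#' physiological mmol/L ceilings abort with a unit error (they indicate
#' mg/dL input, which this package never converts silently).
#'
#' @param df A data frame, one row per subject.
#' @param provenance Optional string recorded as the cohort's origin.
#' @return A tibble of class `sims_cohort`.
#' @export
as_cohort <- function(df, provenance = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  aliases <- column_aliases()
  norm <- normalize_header(names(df))
  mapped <- unname(aliases[norm])
  keep <- !is.na(mapped)
  if (any(duplicated(mapped[keep]))) {
    dup <- unique(mapped[keep][duplicated(mapped[keep])])
    stop("Multiple input columns map to: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- df[keep]
  names(out) <- mapped[keep]

  mandatory <- c("subject_id", "sex", "age")
  missing_cols <- setdiff(mandatory, names(out))
  if (length(missing_cols) > 0) {
    stop("Mandatory column(s) missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  out$subject_id <- as.character(out$subject_id)
  if (anyNA(out$subject_id) || any(out$subject_id == "")) {
    stop("subject_id must be present for every row.", call. = FALSE)
  }
  if (anyDuplicated(out$subject_id)) {
    dup <- unique(out$subject_id[duplicated(out$subject_id)])
    stop("Duplicate subject_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  out$sex <- parse_sex(out$sex)

  for (col in intersect(cohort_numeric_columns(), names(out))) {
    out[[col]] <- parse_quantity(out[[col]], col)
  }
  for (col in intersect(cohort_logical_columns(), names(out))) {
    out[[col]] <- parse_flag(out[[col]], col)
  }
  for (col in setdiff(cohort_columns(), names(out))) {
    out[[col]] <- rep(if (col %in% cohort_logical_columns()) NA else NA_real_,
                      nrow(out))
  }
  out <- out[cohort_columns()]

  ceilings <- unit_ceilings()
  for (col in names(ceilings)) {
    over <- !is.na(out[[col]]) & out[[col]] > ceilings[[col]]
    if (any(over)) {
      stop("Column '", col, "' has values above ", ceilings[[col]],
           " mmol/L (e.g. ", format(max(out[[col]], na.rm = TRUE)),
           "); input looks like mg/dL. Convert units before loading.",
           call. = FALSE)
    }
  }
  for (col in cohort_numeric_columns()) {
    nonpos <- !is.na(out[[col]]) & out[[col]] <= 0
    if (any(nonpos)) {
      warning(sum(nonpos), " non-positive value(s) in '", col,
              "' set to missing.", call. = FALSE)
      out[[col]][nonpos] <- NA_real_
    }
  }
  inverted <- !is.na(out$systolic_bp) & !is.na(out$diastolic_bp) &
    out$systolic_bp <= out$diastolic_bp
  if (any(inverted)) {
    warning(sum(inverted), " row(s) with systolic <= diastolic pressure; ",
            "both pressures set to missing.", call. = FALSE)
    out$systolic_bp[inverted] <- NA_real_
    out$diastolic_bp[inverted] <- NA_real_
  }

  out <- tibble::as_tibble(out)
  attr(out, "provenance") <- provenance
  class(out) <- c("sims_cohort", class(out))
  out
}

#' Read a cohort from CSV or XLSX
#'
#' Reads one row per subject, resolving headers through the package's
#' case-insensitive alias map (so `TA_systolic`, `SBP` and `systolic_bp`
#' are all accepted) and applying the validation rules of [as_cohort()].
#' Units are fixed: cm, kg, mmHg, mmol/L, mIU/L, years; no auto-conversion.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (RFC 4180, UTF-8, "." decimal) or `"xlsx"`
#'   (first sheet, same header contract; requires the readxl package).
#' @return A `sims_cohort` tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = 1:2, sex = c("f", "m"), age = c(30, 40),
#'                      waist = c(80, 95), height = c(165, 180)),
#'           f, row.names = FALSE)
#' read_cohort(f)
#' @export
read_cohort <- function(path, dialect = c("csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- switch(dialect,
    csv = readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("XLSX input requires the 'readxl' package.", call. = FALSE)
      }
      readxl::read_excel(path, sheet = 1, col_types = "text")
    }
  )
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    stop("File is empty: ", path, call. = FALSE)
  }
  as_cohort(raw, provenance = path)
}

#' Write a cohort to CSV
#'
#' Canonical column order, missing values as empty cells; round-trips through
#' [read_cohort()] losslessly at double precision.
#'
#' @param cohort A `sims_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "sims_cohort"))
  readr::write_csv(as.data.frame(cohort), path, na = "")
  invisible(path)
}

#' Write or read a score table
#'
#' Score tables are plain tibbles (one row per subject, `subject_id` first,
#' score columns afterwards) produced by [score_cohort()] or
#' [validate_cohort()]. Missing scores are serialized as empty cells and the
#' numeric round trip is lossless well below 6 significant digits.
#'
#' @param table A score table (data frame with a `subject_id` column).
#' @param path File path.
#' @return `write_score_table()` returns `path` invisibly;
#'   `read_score_table()` returns a tibble.
#' @export
write_score_table <- function(table, path) {
  stopifnot(is.data.frame(table), "subject_id" %in% names(table))
  readr::write_csv(as.data.frame(table), path, na = "")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  readr::read_csv(path,
                  col_types = readr::cols(subject_id = readr::col_character(),
                                          .default = readr::col_guess()),
                  progress = FALSE, show_col_types = FALSE)
}

#' Per-column complete-data counts
#'
#' @param table A data frame.
#' @return Named integer vector: non-missing entries per column.
#' @export
column_completeness <- function(table) {
  vapply(table, function(col) sum(!is.na(col)), integer(1))
}
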