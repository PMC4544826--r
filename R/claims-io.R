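#' @keywords internal
"_PACKAGE"

# Coding systems accepted on claims and in codebooks. ICD-10 is deliberately
# unsupported: the study era (2000-2010) is entirely ICD-9-CM.
CODE_SYSTEMS <- c("ICD9_DX", "ICD9_PX", "HCPCS")

# SRE subtypes: pathologic fracture, spinal cord compression,
# bone palliative radiation, bone surgery.
SRE_TYPES <- c("PF", "SCC", "RAD", "BS")

#' Normalize a diagnosis or procedure code
#'
#' Strips surrounding whitespace and embedded dots and upper-cases letters, so
#' that `"733.14"`, `" 73314 "` and `"73314"` all compare equal. The
#' transformation is idempotent.
#'
#' @param raw Character vector of raw code strings as they appear on claims.
#' @param system Coding system, one of `"ICD9_DX"`, `"ICD9_PX"`, `"HCPCS"`.
#'   Checked for validity; the normalization itself is system-independent.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code("733.14", "ICD9_DX")
#' normalize_code("e885", "ICD9_DX")
#' @export
normalize_code <- function(raw, system = "ICD9_DX") {
  system <- match.arg(system, CODE_SYSTEMS)
  out <- toupper(gsub(".", "", trimws(raw), fixed = TRUE))
  if (any(!nzchar(out)) || any(is.na(out))) {
    stop("invalid code: empty or whitespace-only code string", call. = FALSE)
  }
  out
}

#' Study configuration
#'
#' Bundles the study-design constants: the administrative end of follow-up,
#' the continuous-enrollment lookback before diagnosis, the prior-cancer
#' lookback, the fracture trauma-exclusion lookback, and the minimum age at
#' diagnosis.
#'
#' @param study_end Last calendar date of observation (administrative
#'   censoring), default `"2010-12-31"`.
#' @param enrollment_lookback_days Days before diagnosis over which continuous
#'   Parts A/B enrollment is required (default 365).
#' @param prior_cancer_lookback_years Years before diagnosis screened for a
#'   cancer history (default 5; the screen itself is carried on the patient
#'   table as `prior_cancer_flag`).
#' @param trauma_lookback_days Length of the window before an "other fracture"
#'   claim within which a non-exempt trauma code voids the fracture
#'   (default 14, inclusive at both ends).
#' @param age_minimum Minimum age at diagnosis for inclusion (default 66).
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(study_end = as.Date("2010-12-31"),
                         enrollment_lookback_days = 365L,
                         prior_cancer_lookback_years = 5L,
                         trauma_lookback_days = 14L,
                         age_minimum = 66L) {
  stopifnot(enrollment_lookback_days > 0, prior_cancer_lookback_years > 0,
            trauma_lookback_days >= 0, age_minimum > 0)
  structure(list(study_end = as.Date(study_end),
                 enrollment_lookback_days = as.integer(enrollment_lookback_days),
                 prior_cancer_lookback_years = as.integer(prior_cancer_lookback_years),
                 trauma_lookback_days = as.integer(trauma_lookback_days),
                 age_minimum = as.integer(age_minimum)),
            class = "study_config")
}

# ---- claims ----------------------------------------------------------------

CLAIM_COLUMNS <- c("claim_id", "patient_id", "service_date", "code", "system")

#' Read a claims table
#'
#' Reads a delimited file with one row per billed service line. Codes are
#' normalized on ingest; row order is preserved. Claims dated outside any
#' enrollment interval are retained here -- censoring is study logic, not
#' parsing logic.
#'
#' @param path Path to a CSV file with columns `claim_id, patient_id,
#'   service_date, code, system`.
#' @return A data.frame of claims with `service_date` as `Date` and `code`
#'   normalized.
#' @export
read_claims <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(CLAIM_COLUMNS, names(df))
  if (length(missing)) {
    stop("claims file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[CLAIM_COLUMNS]
  if (nrow(df) == 0) {
    df$service_date <- as.Date(character())
    return(df)
  }
  bad <- which(!df$system %in% CODE_SYSTEMS)
  if (length(bad)) {
    stop("claims file ", path, ": unsupported coding system '",
         df$system[bad[1]], "' at data row ", bad[1],
         " (supported: ", paste(CODE_SYSTEMS, collapse = ", "), ")",
         call. = FALSE)
  }
  df$service_date <- as.Date(df$service_date)
  if (anyNA(df$service_date)) {
    stop("claims file ", path, ": unparseable service_date at data row ",
         which(is.na(df$service_date))[1], call. = FALSE)
  }
  df$code <- normalize_code(df$code)
  df
}

#' Write a claims table
#'
#' @param claims Claims data.frame as returned by [read_claims()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  utils::write.csv(claims[CLAIM_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- patients --------------------------------------------------------------

PATIENT_CSV_COLUMNS <- c("patient_id", "diagnosis_date", "age_at_diagnosis",
                         "death_date", "enrollment_start", "enrollment_end",
                         "hmo_start", "hmo_end", "prior_cancer_flag",
                         "diagnosis_month_known", "post_mortem_diagnosis")

# Sort closed date intervals and merge any that overlap or touch.
merge_intervals <- function(start, end) {
  keep <- !is.na(start) & !is.na(end)
  start <- start[keep]; end <- end[keep]
  if (!length(start)) {
    return(data.frame(start = as.Date(character()), end = as.Date(character())))
  }
  if (any(end < start)) {
    stop("interval end date precedes start date", call. = FALSE)
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- as.Date(character()); out_e <- as.Date(character())
  for (k in seq_along(start)[-1]) {
    if (as.integer(start[k] - me) <= 1L) {
      me <- max(me, end[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[k]; me <- end[k]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Read a patients table
#'
#' Reads a delimited file with one row per (patient, enrollment interval).
#' Rows sharing a `patient_id` are merged into a single patient whose Parts
#' A/B enrollment and HMO coverage are lists of sorted, non-overlapping closed
#' date intervals (overlapping or abutting intervals are coalesced).
#'
#' @param path Path to a CSV with columns `patient_id, diagnosis_date,
#'   age_at_diagnosis, death_date, enrollment_start, enrollment_end,
#'   hmo_start, hmo_end, prior_cancer_flag, diagnosis_month_known,
#'   post_mortem_diagnosis`. Empty strings denote absent dates.
#' @return A data.frame with one row per patient; `ab_enrollment` and
#'   `hmo_intervals` are list-columns of `data.frame(start, end)`.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(PATIENT_CSV_COLUMNS, names(df))
  if (length(missing)) {
    stop("patients file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as_date <- function(x) as.Date(ifelse(nzchar(trimws(x)), x, NA))
  as_flag <- function(x) {
    v <- toupper(trimws(x))
    out <- v %in% c("TRUE", "T", "1", "YES")
    bad <- !v %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO", "")
    if (any(bad)) stop("patients file ", path, ": unparseable flag value '",
                       x[bad][1], "'", call. = FALSE)
    out
  }
  ids <- unique(df$patient_id)
  rows <- lapply(ids, function(id) {
    sub <- df[df$patient_id == id, , drop = FALSE]
    first <- sub[1, ]
    dd <- as_date(first$death_date)
    data.frame(
      patient_id = id,
      diagnosis_date = as_date(first$diagnosis_date),
      age_at_diagnosis = as.integer(first$age_at_diagnosis),
      death_date = dd,
      prior_cancer_flag = as_flag(first$prior_cancer_flag),
      diagnosis_month_known = as_flag(first$diagnosis_month_known),
      post_mortem_diagnosis = as_flag(first$post_mortem_diagnosis),
      ab_enrollment = I(list(merge_intervals(as_date(sub$enrollment_start),
                                             as_date(sub$enrollment_end)))),
      hmo_intervals = I(list(merge_intervals(as_date(sub$hmo_start),
                                             as_date(sub$hmo_end)))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), diagnosis_date = as.Date(character()),
                      age_at_diagnosis = integer(), death_date = as.Date(character()),
                      prior_cancer_flag = logical(), diagnosis_month_known = logical(),
                      post_mortem_diagnosis = logical(),
                      ab_enrollment = I(list()), hmo_intervals = I(list()))
  }
  rownames(out) <- NULL
  if (anyNA(out$diagnosis_date)) {
    stop("patients file ", path, ": missing diagnosis_date for patient ",
         out$patient_id[is.na(out$diagnosis_date)][1], call. = FALSE)
  }
  out
}

#' Write a patients table
#'
#' Inverse of [read_patients()]: expands the interval list-columns back into
#' one row per (patient, enrollment interval), pairing HMO intervals
#' positionally and padding with blanks.
#'
#' @param patients Patients data.frame as returned by [read_patients()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  fmt <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    ab <- p$ab_enrollment[[1]]
    hmo <- p$hmo_intervals[[1]]
    n <- max(1L, nrow(ab), nrow(hmo))
    pad <- function(x, n) c(x, rep(as.Date(NA), n - length(x)))
    data.frame(
      patient_id = p$patient_id,
      diagnosis_date = fmt(p$diagnosis_date),
      age_at_diagnosis = p$age_at_diagnosis,
      death_date = fmt(p$death_date),
      enrollment_start = fmt(pad(ab$start, n)),
      enrollment_end = fmt(pad(ab$end, n)),
      hmo_start = fmt(pad(hmo$start, n)),
      hmo_end = fmt(pad(hmo$end, n)),
      prior_cancer_flag = p$prior_cancer_flag,
      diagnosis_month_known = p$diagnosis_month_known,
      post_mortem_diagnosis = p$post_mortem_diagnosis,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- as.data.frame(setNames(
    rep(list(character()), length(PATIENT_CSV_COLUMNS)), PATIENT_CSV_COLUMNS))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Symmetric half-up rounding (ties away from zero) at the reporting precision.
# base::round() rounds half to even, which is not how the tables are printed.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
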