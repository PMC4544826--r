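EXCLUSION_REASONS <- c("UNDER_AGE", "UNKNOWN_DX_DATE", "POST_MORTEM_DX",
                       "PRIOR_CANCER", "NOT_CONTINUOUSLY_ENROLLED", "PRIOR_SRE")

# TRUE if [from, to] is fully covered by the union of the enrollment
# intervals with no gap day (abutting intervals count as continuous).
covers_window <- function(intervals, from, to) {
  if (!nrow(intervals)) return(FALSE)
  merged <- merge_intervals(intervals$start, intervals$end)
  any(merged$start <= from & merged$end >= to)
}

#' End of follow-up for one patient
#'
#' Follow-up runs from diagnosis to the earliest of: the first HMO enrollment
#' starting on or after diagnosis; the first day after the Parts A/B interval
#' covering the diagnosis ends (fee-for-service disenrollment); death; and
#' the administrative study end.
#'
#' @param patient One-row patient data.frame (see [read_patients()]).
#' @param config A [study_config()].
#' @return A `Date`.
#' @export
follow_up_end <- function(patient, config = study_config()) {
  dx <- patient$diagnosis_date
  candidates <- config$study_end
  if (!is.na(patient$death_date)) candidates <- c(candidates, patient$death_date)
  hmo <- patient$hmo_intervals[[1]]
  hmo_starts <- hmo$start[hmo$start >= dx]
  if (length(hmo_starts)) candidates <- c(candidates, min(hmo_starts))
  ab <- patient$ab_enrollment[[1]]
  covering <- ab$start <= dx & ab$end >= dx
  if (any(covering)) candidates <- c(candidates, min(ab$end[covering]) + 1L)
  min(candidates)
}

#' Select the study cohort
#'
#' Applies the inclusion and exclusion rules in a fixed order and computes
#' each included patient's follow-up interval. Rules, in order of
#' application (the first failure is the logged reason):
#' \enumerate{
#'   \item age at diagnosis at least `age_minimum` (`UNDER_AGE`);
#'   \item diagnosis month known (`UNKNOWN_DX_DATE`);
#'   \item diagnosis not post mortem (`POST_MORTEM_DX`);
#'   \item no cancer history in the lookback before diagnosis
#'     (`PRIOR_CANCER`, carried as a flag on the patient table);
#'   \item continuous Parts A/B enrollment over the year before diagnosis,
#'     diagnosis day included, with zero gap tolerance
#'     (`NOT_CONTINUOUSLY_ENROLLED`);
#'   \item no claim before the diagnosis date matching any EVENT code of any
#'     tier or subtype (`PRIOR_SRE`). The union of both tiers is screened so
#'     the included cohort is identical under every case definition.
#' }
#' Day-of-diagnosis claims belong to follow-up and never trigger the prior-SRE
#' exclusion.
#'
#' @param patients Patients data.frame.
#' @param claims Claims data.frame.
#' @param cb An `"sre_codebook"`.
#' @param config A [study_config()].
#' @return A list of class `"sre_cohort"` with `included` (character vector of
#'   patient ids), `exclusion_log` (data.frame `patient_id, reason`) and
#'   `follow_up` (data.frame `patient_id, start, end`).
#' @export
select_cohort <- function(patients, claims, cb, config = study_config()) {
  orphan <- setdiff(unique(claims$patient_id), patients$patient_id)
  if (length(orphan)) {
    stop("claims reference patient id(s) absent from the patients table: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  event_cb <- cb[cb$role == "EVENT", , drop = FALSE]

  # patients with any pre-diagnosis claim matching any EVENT entry
  dx_of <- setNames(patients$diagnosis_date, patients$patient_id)
  pre <- claims[claims$service_date < dx_of[claims$patient_id], , drop = FALSE]
  prior_sre_ids <- character()
  if (nrow(pre)) {
    hits <- match_claims(event_cb, pre)
    prior_sre_ids <- unique(pre$patient_id[hits$claim_row])
  }

  reasons <- character(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    dx <- p$diagnosis_date
    reasons[i] <- if (p$age_at_diagnosis < config$age_minimum) "UNDER_AGE"
      else if (!p$diagnosis_month_known) "UNKNOWN_DX_DATE"
      else if (p$post_mortem_diagnosis) "POST_MORTEM_DX"
      else if (p$prior_cancer_flag) "PRIOR_CANCER"
      else if (!covers_window(p$ab_enrollment[[1]],
                              dx - config$enrollment_lookback_days, dx))
        "NOT_CONTINUOUSLY_ENROLLED"
      else if (p$patient_id %in% prior_sre_ids) "PRIOR_SRE"
      else ""
  }

  included <- patients$patient_id[reasons == ""]
  excluded <- data.frame(patient_id = patients$patient_id[reasons != ""],
                         reason = reasons[reasons != ""],
                         stringsAsFactors = FALSE)
  inc <- patients[reasons == "", , drop = FALSE]
  fu <- data.frame(
    patient_id = inc$patient_id,
    start = inc$diagnosis_date,
    end = as.Date(vapply(seq_len(nrow(inc)), function(i)
      as.character(follow_up_end(inc[i, ], config)), character(1))),
    stringsAsFactors = FALSE
  )
  bad <- fu$end < fu$start
  if (any(bad)) {
    # death recorded before diagnosis for a non-post-mortem record is a data
    # inconsistency; surfaced here rather than silently clipped
    stop("follow-up end precedes diagnosis for patient(s): ",
         paste(fu$patient_id[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(included = included, exclusion_log = excluded,
                 follow_up = fu, config = config),
            class = "sre_cohort")
}

#' @export
print.sre_cohort <- function(x, ...) {
  cat("SRE study cohort\n")
  cat("  included patients:", length(x$included), "\n")
  cat("  excluded patients:", nrow(x$exclusion_log), "\n")
  if (nrow(x$exclusion_log)) {
    tab <- table(factor(x$exclusion_log$reason, levels = EXCLUSION_REASONS))
    for (r in names(tab)) if (tab[[r]] > 0)
      cat(sprintf("    %-26s %d\n", r, tab[[r]]))
  }
  if (length(x$included)) {
    yrs <- as.numeric(x$follow_up$end - x$follow_up$start) / 365.25
    cat(sprintf("  median follow-up: %.1f years\n", stats::median(yrs)))
  }
  invisible(x)
}
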