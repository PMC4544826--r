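# Fixture builders shared across the suite. Everything is constructed in
# code; no data files.

D <- function(x) as.Date(x)

make_patient <- function(id = "P1", dx = D("2005-01-01"), age = 70L,
                         death = as.Date(NA),
                         enr_start = dx - 400L, enr_end = D("2011-12-31"),
                         hmo_start = as.Date(NA), hmo_end = as.Date(NA),
                         prior_cancer = FALSE, month_known = TRUE,
                         post_mortem = FALSE) {
  hmo <- if (is.na(hmo_start)) {
    data.frame(start = as.Date(character()), end = as.Date(character()))
  } else data.frame(start = hmo_start, end = hmo_end)
  data.frame(patient_id = id, diagnosis_date = dx,
             age_at_diagnosis = as.integer(age), death_date = death,
             prior_cancer_flag = prior_cancer,
             diagnosis_month_known = month_known,
             post_mortem_diagnosis = post_mortem,
             ab_enrollment = I(list(data.frame(start = enr_start, end = enr_end))),
             hmo_intervals = I(list(hmo)), stringsAsFactors = FALSE)
}

make_claim <- function(id, pid, date, code, system = "ICD9_DX") {
  data.frame(claim_id = id, patient_id = pid, service_date = as.Date(date),
             code = normalize_code(code, system), system = system,
             stringsAsFactors = FALSE)
}

claims_table <- function(...) do.call(rbind, list(...))

# Small codebook exercising every role and tier.
tiny_codebook <- function() {
  codebook(data.frame(
    pattern = c("7331*", "805*", "3369", "7211", "9224", "77418", "7851",
                "E881*", "E885*", "1985"),
    system = c("ICD9_DX", "ICD9_DX", "ICD9_DX", "ICD9_DX", "ICD9_PX",
               "HCPCS", "ICD9_PX", "ICD9_DX", "ICD9_DX", "ICD9_DX"),
    sre_type = c("PF", "PF", "SCC", "SCC", "RAD", "RAD", "BS",
                 "NONE", "NONE", "NONE"),
    tier = c("SPECIFICITY", "SENSITIVITY_EXT", "SPECIFICITY",
             "SENSITIVITY_EXT", "SPECIFICITY", "SENSITIVITY_EXT",
             "SPECIFICITY", "SPECIFICITY", "SPECIFICITY", "SPECIFICITY"),
    role = c("EVENT", "EVENT", "EVENT", "EVENT", "EVENT", "EVENT", "EVENT",
             "TRAUMA", "SAME_LEVEL_FALL", "RAD_CONTEXT"),
    stringsAsFactors = FALSE
  ))
}

# Build an events table directly (already deduplicated), for clustering and
# measure tests that do not need the identification stage.
make_events <- function(pid, dates, sre_type = "PF", status = "KEPT",
                        tier = "SPECIFICITY") {
  n <- length(dates)
  data.frame(patient_id = rep(pid, n), date = as.Date(dates),
             sre_type = rep(sre_type, n), matched_tier = rep(tier, n),
             status = rep(status, n), source_claim_ids = rep("", n),
             stringsAsFactors = FALSE)
}

# One-patient cohort wrapper for identification tests.
one_patient_cohort <- function(patient, claims = NULL, cb = tiny_codebook()) {
  if (is.null(claims)) {
    claims <- make_claim("CX", patient$patient_id[1],
                         patient$diagnosis_date[1], "V7231")
  }
  select_cohort(patient, claims, cb)
}
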