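EVENT_STATUSES <- c("KEPT", "EXCLUDED_TRAUMA", "EXCLUDED_HIERARCHY",
                    "EXCLUDED_CONCURRENCY", "EXCLUDED_OUTSIDE_FOLLOWUP")

empty_events <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             sre_type = character(), matched_tier = character(),
             status = character(), source_claim_ids = character(),
             stringsAsFactors = FALSE)
}

# Service dates, per patient, of claims that carry a non-exempt trauma code:
# the code matches a TRAUMA entry and no SAME_LEVEL_FALL entry. A same-level
# fall code never triggers exclusion, but it does not shield a distinct
# trauma code on another claim.
trauma_claim_dates <- function(claims, cb) {
  aux <- cb[cb$role %in% c("TRAUMA", "SAME_LEVEL_FALL"), , drop = FALSE]
  if (!nrow(aux) || !nrow(claims)) return(list())
  hits <- match_claims(aux, claims)
  if (!nrow(hits)) return(list())
  is_trauma <- tapply(hits$role == "TRAUMA", hits$claim_row, any)
  is_exempt <- tapply(hits$role == "SAME_LEVEL_FALL", hits$claim_row, any)
  rows <- as.integer(names(is_trauma))[is_trauma & !is_exempt]
  if (!length(rows)) return(list())
  split(claims$service_date[rows], claims$patient_id[rows])
}

#' Apply the fracture trauma-exclusion rule
#'
#' An "other fracture" event (a PF event matched only through the sensitivity
#' extension) on day `d` is voided when the same patient has at least one
#' claim carrying a non-exempt accident or fall code dated in
#' `[d - lookback_days, d]` -- both boundaries inclusive, so a trauma code on
#' the fracture day itself, or exactly `lookback_days` before it, excludes.
#' Such fractures are attributed to the preceding trauma rather than to bone
#' weakened by cancer. Falls on the same level are exempt: they are more
#' plausibly a consequence of the weakened bone than its cause. Events
#' matched at the high-specificity tier (733.1X) are never excluded here.
#'
#' @param events Candidate event data.frame from [identify_events()].
#' @param claims Claims data.frame (all claims of the patients, not only
#'   follow-up claims: a trauma code just before diagnosis still counts).
#' @param cb An `"sre_codebook"` supplying the TRAUMA and SAME_LEVEL_FALL
#'   entries.
#' @param lookback_days Window length, default 14.
#' @return `events` with `status` set to `"EXCLUDED_TRAUMA"` where the rule
#'   fires.
#' @export
apply_trauma_exclusion <- function(events, claims, cb, lookback_days = 14L) {
  stopifnot(lookback_days >= 0)
  target <- events$sre_type == "PF" & events$matched_tier == "SENSITIVITY_EXT" &
    events$status == "KEPT"
  flag_trauma(events, claims, cb, lookback_days, target)
}

flag_trauma <- function(events, claims, cb, lookback_days, target) {
  if (!any(target)) return(events)
  tdates <- trauma_claim_dates(claims, cb)
  for (i in which(target)) {
    td <- tdates[[events$patient_id[i]]]
    if (!is.null(td) &&
        any(td >= events$date[i] - lookback_days & td <= events$date[i])) {
      events$status[i] <- "EXCLUDED_TRAUMA"
    }
  }
  events
}

#' Apply the same-day clinical-over-treatment hierarchy
#'
#' An optional literature variant: when enabled, a treatment event (RAD or
#' BS) on a day that also carries a kept clinical event (PF or SCC) for the
#' same patient is suppressed, on the view that the treatment codes bill the
#' management of that clinical event rather than a distinct SRE. Identity
#' when disabled (the default -- the built-in definitions impose no
#' hierarchy).
#'
#' @param events Event data.frame.
#' @param enabled Logical flag.
#' @return `events`, with `status` `"EXCLUDED_HIERARCHY"` where suppressed.
#' @export
apply_same_day_hierarchy <- function(events, enabled = FALSE) {
  if (!enabled || !nrow(events)) return(events)
  clinical <- events$status == "KEPT" & events$sre_type %in% c("PF", "SCC")
  clin_key <- paste(events$patient_id[clinical], events$date[clinical])
  hit <- events$status == "KEPT" & events$sre_type %in% c("RAD", "BS") &
    paste(events$patient_id, events$date) %in% clin_key
  events$status[hit] <- "EXCLUDED_HIERARCHY"
  events
}

#' Identify SRE events from claims under a case definition
#'
#' Matches every claim of an included patient against the codebook's EVENT
#' entries, keeps matches whose tier the definition selects for that subtype,
#' and collapses same-day matches of one subtype into a single event-day
#' (claims carry no intra-day ordering). Every candidate is retained in the
#' output with an audit status; the analytic set is the rows with status
#' `"KEPT"`. Processing order: follow-up bounds, fracture trauma exclusion
#' (and the optional BS trauma variant), the optional radiation concurrency
#' filter, then the optional same-day hierarchy.
#'
#' @param claims Claims data.frame.
#' @param cb An `"sre_codebook"`.
#' @param definition An [sre_definition()].
#' @param cohort An `"sre_cohort"` from [select_cohort()].
#' @param config A [study_config()] (supplies the trauma lookback).
#' @return data.frame of class `"sre_events"` with columns `patient_id, date,
#'   sre_type, matched_tier, status, source_claim_ids` (semicolon-joined),
#'   sorted by patient, date and subtype; at most one row per
#'   (patient, date, subtype).
#' @export
identify_events <- function(claims, cb, definition, cohort,
                            config = study_config()) {
  stopifnot(inherits(cohort, "sre_cohort"), inherits(definition, "sre_definition"))
  cl <- claims[claims$patient_id %in% cohort$included, , drop = FALSE]
  ev <- empty_events()
  if (nrow(cl)) {
    hits <- match_claims(cb[cb$role == "EVENT", , drop = FALSE], cl)
    keep <- mapply(function(t, tier) tier %in% definition$tiers[[t]],
                   hits$sre_type, hits$tier)
    hits <- hits[as.logical(keep), , drop = FALSE]
    if (nrow(hits)) {
      cand <- data.frame(
        patient_id = cl$patient_id[hits$claim_row],
        date = cl$service_date[hits$claim_row],
        sre_type = hits$sre_type,
        tier = hits$tier,
        claim_id = cl$claim_id[hits$claim_row],
        stringsAsFactors = FALSE
      )
      key <- paste(cand$patient_id, cand$date, cand$sre_type, sep = "\r")
      grp <- split(seq_len(nrow(cand)), key)
      rows <- lapply(grp, function(idx) {
        # a day with any high-specificity match is a specificity event-day
        tier <- if (any(cand$tier[idx] == "SPECIFICITY")) "SPECIFICITY"
                else "SENSITIVITY_EXT"
        data.frame(patient_id = cand$patient_id[idx[1]],
                   date = cand$date[idx[1]],
                   sre_type = cand$sre_type[idx[1]],
                   matched_tier = tier,
                   status = "KEPT",
                   source_claim_ids = paste(sort(unique(cand$claim_id[idx])),
                                            collapse = ";"),
                   stringsAsFactors = FALSE)
      })
      ev <- do.call(rbind, rows)
    }
  }
  if (nrow(ev)) {
    fu <- cohort$follow_up
    m <- match(ev$patient_id, fu$patient_id)
    outside <- ev$date < fu$start[m] | ev$date > fu$end[m]
    ev$status[outside] <- "EXCLUDED_OUTSIDE_FOLLOWUP"

    ev <- apply_trauma_exclusion(ev, claims, cb, config$trauma_lookback_days)
    if (definition$options$bs_trauma_lookback) {
      ev <- flag_trauma(ev, claims, cb, config$trauma_lookback_days,
                        ev$sre_type == "BS" & ev$status == "KEPT")
    }
    if (definition$options$rad_concurrency_filter) {
      ev <- apply_rad_concurrency(ev, claims, cb)
    }
    ev <- apply_same_day_hierarchy(ev, definition$options$same_day_hierarchy)

    ev <- ev[order(ev$patient_id, ev$date, match(ev$sre_type, SRE_TYPES)), ]
    rownames(ev) <- NULL
  }
  class(ev) <- c("sre_events", "data.frame")
  attr(ev, "definition") <- definition$name
  ev
}

# Optional literature variant: a RAD event is kept only when a same-day claim
# of the same patient carries a bone-metastasis/bone-pain diagnosis
# (RAD_CONTEXT role) or a PF/SCC event diagnosis of either tier.
apply_rad_concurrency <- function(events, claims, cb) {
  target <- which(events$sre_type == "RAD" & events$status == "KEPT")
  if (!length(target)) return(events)
  ctx <- cb[cb$role == "RAD_CONTEXT" |
              (cb$role == "EVENT" & cb$sre_type %in% c("PF", "SCC")), ,
            drop = FALSE]
  hits <- match_claims(ctx, claims)
  ctx_key <- unique(paste(claims$patient_id[hits$claim_row],
                          claims$service_date[hits$claim_row]))
  miss <- !paste(events$patient_id[target], events$date[target]) %in% ctx_key
  events$status[target[miss]] <- "EXCLUDED_CONCURRENCY"
  events
}

#' Kept (analytic) events
#'
#' @param events An `"sre_events"` data.frame.
#' @return The rows with status `"KEPT"`.
#' @export
kept_events <- function(events) {
  out <- events[events$status == "KEPT", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the event audit table
#'
#' @param events `"sre_events"` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
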