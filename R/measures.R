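MEASURE_ROWS <- c(SRE_TYPES, "ANY")

pct <- function(num, den, digits = 1) {
  r <- round_half_up(100 * num / den, digits)
  r[!is.finite(r)] <- NA_real_
  r
}

new_prevalence <- function(n_patients, cohort_n, definition) {
  stopifnot(cohort_n > 0)
  out <- data.frame(
    sre_type = MEASURE_ROWS,
    n_patients = as.integer(n_patients[MEASURE_ROWS]),
    pct_of_cohort = pct(n_patients[MEASURE_ROWS], cohort_n),
    pct_of_sre_patients = pct(n_patients[MEASURE_ROWS], n_patients[["ANY"]]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, cohort_n = as.integer(cohort_n), definition = definition,
            class = c("sre_prevalence", "data.frame"))
}

#' SRE prevalence table
#'
#' Per subtype and for any SRE: the number of cohort patients with at least
#' one kept event, as a count, a percent of the full cohort, and a percent
#' of the patients with at least one SRE of any type. Percents are printed
#' half-up at one decimal and always recompute exactly from the counts.
#'
#' @param events `"sre_events"` from one case definition (only `KEPT` rows
#'   are counted).
#' @param cohort An `"sre_cohort"`.
#' @param definition_name Label for the definition the events came from.
#' @return A data.frame of class `"sre_prevalence"`.
#' @export
prevalence_table <- function(events, cohort, definition_name =
                               attr(events, "definition")) {
  if (!length(cohort$included)) stop("empty cohort", call. = FALSE)
  ke <- kept_events(events)
  n <- vapply(SRE_TYPES, function(t)
    length(unique(ke$patient_id[ke$sre_type == t])), integer(1))
  n[["ANY"]] <- length(unique(ke$patient_id))
  new_prevalence(n, length(cohort$included),
                 if (is.null(definition_name)) "" else definition_name)
}

#' Prevalence table from published counts
#'
#' Builds an `"sre_prevalence"` from per-subtype patient counts and a cohort
#' size, for re-deriving or checking the rates a study prints from its
#' printed counts.
#'
#' @param n_patients Named vector of patient counts with names `PF, SCC,
#'   RAD, BS, ANY`.
#' @param cohort_n Cohort size.
#' @param definition_name Label.
#' @return An `"sre_prevalence"`.
#' @export
prevalence_from_counts <- function(n_patients, cohort_n, definition_name = "") {
  stopifnot(all(MEASURE_ROWS %in% names(n_patients)))
  new_prevalence(n_patients, cohort_n, definition_name)
}

#' @export
print.sre_prevalence <- function(x, ...) {
  cat("SRE prevalence (definition: ", attr(x, "definition"),
      ", cohort N = ", attr(x, "cohort_n"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$pct_of_cohort <- sprintf("%.1f%%", df$pct_of_cohort)
  df$pct_of_sre_patients <- sprintf("%.1f%%", df$pct_of_sre_patients)
  print(df, row.names = FALSE)
  invisible(x)
}

# ---- cumulative incidence --------------------------------------------------

#' SRE cumulative incidence table
#'
#' Per subtype and overall: the total number of SRE episodes during
#' follow-up, the per-patient mean (episode total over patients with at
#' least one episode of that subtype, half-up at one decimal), the
#' per-patient median (mean of the middle two for even counts), and the
#' distribution of patients with 1, 2, and 3+ episodes.
#'
#' @param episodes `"sre_episodes"` from one window policy.
#' @param cohort An `"sre_cohort"` (carried for the cohort size).
#' @return A data.frame of class `"sre_incidence"` with columns `sre_type,
#'   episode_total, n_patients, per_patient_mean, per_patient_median,
#'   dist_1, dist_2, dist_3plus`.
#' @export
incidence_table <- function(episodes, cohort = NULL) {
  per_row <- function(t) {
    sub <- if (t == "ANY") episodes else episodes[episodes$sre_type == t, ]
    counts <- if (nrow(sub)) as.integer(table(sub$patient_id)) else integer()
    data.frame(
      sre_type = t,
      episode_total = nrow(sub),
      n_patients = length(counts),
      per_patient_mean = if (length(counts))
        round_half_up(nrow(sub) / length(counts), 1) else NA_real_,
      per_patient_median = if (length(counts))
        stats::median(counts) else NA_real_,
      dist_1 = sum(counts == 1L),
      dist_2 = sum(counts == 2L),
      dist_3plus = sum(counts >= 3L),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(MEASURE_ROWS, per_row))
  rownames(out) <- NULL
  structure(out,
            window_days = if (nrow(episodes)) episodes$window_days[1] else NA_integer_,
            anchoring = if (nrow(episodes)) episodes$anchoring[1] else NA_character_,
            cohort_n = if (!is.null(cohort)) length(cohort$included) else NA_integer_,
            class = c("sre_incidence", "data.frame"))
}

#' Cumulative incidence table from published counts
#'
#' Builds an `"sre_incidence"` from per-subtype episode totals and patient
#' counts, recomputing the per-patient means; the per-patient distribution
#' is taken as given when supplied and left `NA` otherwise.
#'
#' @param episode_totals Named vector (`PF, SCC, RAD, BS`; `ANY` is derived
#'   as their sum unless supplied).
#' @param n_patients Named vector of patients with at least one episode, same
#'   names.
#' @param window_days Window length label.
#' @return An `"sre_incidence"`.
#' @export
incidence_from_counts <- function(episode_totals, n_patients,
                                  window_days = NA_integer_) {
  stopifnot(all(SRE_TYPES %in% names(episode_totals)),
            all(SRE_TYPES %in% names(n_patients)))
  if (!"ANY" %in% names(episode_totals)) {
    episode_totals[["ANY"]] <- sum(episode_totals[SRE_TYPES])
  }
  if (!"ANY" %in% names(n_patients)) n_patients[["ANY"]] <- NA_integer_
  out <- data.frame(
    sre_type = MEASURE_ROWS,
    episode_total = as.integer(episode_totals[MEASURE_ROWS]),
    n_patients = as.integer(n_patients[MEASURE_ROWS]),
    per_patient_mean = round_half_up(
      as.numeric(episode_totals[MEASURE_ROWS]) /
        as.numeric(n_patients[MEASURE_ROWS]), 1),
    per_patient_median = NA_real_,
    dist_1 = NA_integer_, dist_2 = NA_integer_, dist_3plus = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, window_days = as.integer(window_days),
            anchoring = NA_character_, cohort_n = NA_integer_,
            class = c("sre_incidence", "data.frame"))
}

#' @export
print.sre_incidence <- function(x, ...) {
  cat("SRE cumulative incidence (window: ", attr(x, "window_days"),
      " days)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

# ---- comparisons -----------------------------------------------------------

#' Percent change in episode totals between two configurations
#'
#' For each subtype and overall, the percent change in episode totals from
#' configuration `a` to configuration `b`, computed as
#' `(b - a) / a * 100` and reported half-up at integer precision, so a
#' decrease carries a negative sign. A zero baseline yields `NA` (flagged,
#' not an error). Typical uses: the same events clustered under two window
#' lengths, or (via [prevalence_from_counts()] totals) two case definitions.
#'
#' @param a,b `"sre_incidence"` tables.
#' @param digits Reporting precision (default 0, as percent changes are
#'   printed).
#' @return data.frame of class `"sre_comparison"` with columns `sre_type,
#'   value_a, value_b, pct_change`.
#' @export
episode_count_change <- function(a, b, digits = 0) {
  stopifnot(identical(a$sre_type, b$sre_type))
  out <- data.frame(
    sre_type = a$sre_type,
    value_a = a$episode_total,
    value_b = b$episode_total,
    pct_change = ifelse(a$episode_total > 0,
                        round_half_up((b$episode_total - a$episode_total) /
                                        a$episode_total * 100, digits),
                        NA_real_),
    stringsAsFactors = FALSE
  )
  structure(out, from = attr(a, "window_days"), to = attr(b, "window_days"),
            class = c("sre_comparison", "data.frame"))
}

#' Percent change between two scalar measures
#'
#' `(b - a) / a * 100`, half-up at the reporting precision. The direction
#' convention is explicit: `a` is the reference (denominator). Before
#' rounding, `change(a, b)` and `change(b, a)` satisfy
#' `(1 + d_ab/100) * (1 + d_ba/100) = 1`.
#'
#' @param a Reference value.
#' @param b Comparison value.
#' @param digits Reporting precision (default 0).
#' @return Numeric percent change (`NA` if `a` is zero).
#' @export
pct_change <- function(a, b, digits = 0) {
  ifelse(a != 0, round_half_up((b - a) / a * 100, digits), NA_real_)
}

#' @export
print.sre_comparison <- function(x, ...) {
  cat("Episode total change")
  if (!is.na(attr(x, "from"))) {
    cat(" (", attr(x, "from"), "-day vs ", attr(x, "to"), "-day window)",
        sep = "")
  }
  cat("\n")
  df <- as.data.frame(x)
  df$pct_change <- sprintf("%+.0f%%", df$pct_change)
  print(df, row.names = FALSE)
  invisible(x)
}

# ---- time to event ---------------------------------------------------------

med_mean <- function(x) {
  if (!length(x)) return(c(median = NA_real_, mean = NA_real_))
  c(median = stats::median(x), mean = round_half_up(mean(x), 1))
}

#' Time-to-event summary
#'
#' Among patients with at least one SRE episode: days from diagnosis to the
#' first episode anchor (any subtype), from the first to the second distinct
#' anchor date, and from diagnosis to death (patients with a recorded death
#' date). Medians over even counts are the mean of the two middle values.
#' Episode anchors, not raw claims, mark the first and second SRE.
#'
#' @param episodes `"sre_episodes"`.
#' @param patients Patients data.frame.
#' @param cohort An `"sre_cohort"`.
#' @return A list of class `"sre_tte"`: per quantity, `c(median, mean)` in
#'   days plus the n it was computed over.
#' @export
time_to_event_summary <- function(episodes, patients, cohort) {
  dx <- setNames(patients$diagnosis_date, patients$patient_id)
  death <- setNames(patients$death_date, patients$patient_id)
  ids <- unique(episodes$patient_id)
  first <- second <- rep(as.Date(NA), length(ids))
  for (k in seq_along(ids)) {
    anchors <- sort(unique(episodes$anchor_date[episodes$patient_id == ids[k]]))
    first[k] <- anchors[1]
    if (length(anchors) > 1) second[k] <- anchors[2]
  }
  to_first <- as.numeric(first - dx[ids])
  to_second <- as.numeric(second - first)[!is.na(second)]
  dd <- death[ids]
  to_death <- as.numeric(dd[!is.na(dd)] - dx[ids][!is.na(dd)])
  structure(list(
    dx_to_first_sre = c(med_mean(to_first), n = length(to_first)),
    first_to_second_sre = c(med_mean(to_second), n = length(to_second)),
    dx_to_death = c(med_mean(to_death), n = length(to_death))
  ), class = "sre_tte")
}

#' @export
print.sre_tte <- function(x, ...) {
  cat("Time-to-event summary (days, median (mean) [n])\n")
  lab <- c(dx_to_first_sre = "diagnosis to first SRE",
           first_to_second_sre = "first SRE to second SRE",
           dx_to_death = "diagnosis to death")
  for (k in names(lab)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s (%s) [%d]\n", lab[[k]],
                format(v[["median"]]), format(v[["mean"]]), v[["n"]]))
  }
  invisible(x)
}

# ---- type combinations -----------------------------------------------------

#' Tally of SRE subtype combinations
#'
#' Assigns each patient with at least one kept event to exactly one subset
#' of \{PF, SCC, RAD, BS\} (the set of subtypes they experienced) and counts
#' patients per subset; the counts partition the SRE patients. Also reports
#' the share of SRE patients with two or more subtypes, half-up at one
#' decimal.
#'
#' @param events `"sre_events"` (only `KEPT` rows are counted).
#' @return A list of class `"sre_combinations"`: `combos` (data.frame
#'   `combination, n_types, n_patients`), `n_sre_patients`,
#'   `multi_type_share_pct`.
#' @export
type_combination_tally <- function(events) {
  ke <- kept_events(events)
  sets <- tapply(ke$sre_type, ke$patient_id, function(t)
    paste(SRE_TYPES[SRE_TYPES %in% t], collapse = "+"))
  tab <- table(sets)
  combos <- data.frame(
    combination = names(tab),
    n_types = lengths(strsplit(names(tab), "+", fixed = TRUE)),
    n_patients = as.integer(tab),
    stringsAsFactors = FALSE
  )
  combos <- combos[order(combos$n_types, combos$combination), ]
  rownames(combos) <- NULL
  n_sre <- length(sets)
  structure(list(
    combos = combos,
    n_sre_patients = n_sre,
    multi_type_share_pct = if (n_sre)
      round_half_up(100 * sum(combos$n_patients[combos$n_types >= 2]) / n_sre, 1)
      else NA_real_
  ), class = "sre_combinations")
}

#' @export
print.sre_combinations <- function(x, ...) {
  cat("SRE subtype combinations (", x$n_sre_patients, " SRE patients, ",
      sprintf("%.1f%%", x$multi_type_share_pct), " with >1 type)\n", sep = "")
  print(x$combos, row.names = FALSE)
  invisible(x)
}
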