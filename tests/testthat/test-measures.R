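test_that("half-up rounding at reporting precision", {
  expect_equal(skelevent:::round_half_up(2.95, 1), 3.0)
  expect_equal(skelevent:::round_half_up(1.75, 1), 1.8)
  expect_equal(skelevent:::round_half_up(8.44), 8)
  expect_equal(skelevent:::round_half_up(-8.5), -9)
  expect_equal(skelevent:::round_half_up(46.35, 1), 46.4)
})

make_small_study <- function() {
  # three patients: PF-only; PF+RAD; PF+RAD+SCC with repeat PF episodes
  ev <- rbind(
    make_events("A", D("2005-02-01")),
    make_events("B", D(c("2005-02-01", "2005-06-01"))),
    make_events("B", D("2005-02-01"), sre_type = "RAD"),
    make_events("C", D(c("2005-03-01", "2005-05-01", "2005-07-01"))),
    make_events("C", D("2005-03-01"), sre_type = "RAD"),
    make_events("C", D("2005-04-01"), sre_type = "SCC")
  )
  class(ev) <- c("sre_events", "data.frame")
  pts <- rbind(make_patient("A", D("2005-01-01"), death = D("2006-06-01")),
               make_patient("B", D("2005-01-01")),
               make_patient("C", D("2005-01-10")))
  cb <- tiny_codebook()
  coh <- select_cohort(pts, make_claim("CX", "A", D("2005-01-02"), "V1"), cb)
  list(ev = ev, pts = pts, coh = coh)
}

test_that("prevalence counts, percents, and zero-event edge case", {
  s <- make_small_study()
  prev <- prevalence_table(s$ev, s$coh, "base_case")
  get <- function(t, col) prev[[col]][prev$sre_type == t]
  expect_equal(get("PF", "n_patients"), 3L)
  expect_equal(get("RAD", "n_patients"), 2L)
  expect_equal(get("SCC", "n_patients"), 1L)
  expect_equal(get("BS", "n_patients"), 0L)
  expect_equal(get("ANY", "n_patients"), 3L)
  expect_equal(get("ANY", "pct_of_cohort"), 100)
  expect_equal(get("RAD", "pct_of_sre_patients"), 66.7)
  # percents recompute exactly from counts under the stated rounding
  expect_equal(prev$pct_of_cohort,
               skelevent:::round_half_up(100 * prev$n_patients / 3, 1))
  none <- s$ev[0, ]
  class(none) <- c("sre_events", "data.frame")
  prev0 <- prevalence_table(none, s$coh, "base_case")
  expect_true(all(prev0$n_patients == 0))
})

test_that("incidence totals, means, medians and distribution invariants", {
  s <- make_small_study()
  eps <- cluster_episodes(kept_events(s$ev), window_policy(21))
  inc <- incidence_table(eps, s$coh)
  get <- function(t, col) inc[[col]][inc$sre_type == t]
  expect_equal(get("PF", "episode_total"), 6L)
  expect_equal(get("ANY", "episode_total"),
               sum(inc$episode_total[inc$sre_type != "ANY"]))
  expect_equal(get("PF", "per_patient_mean"), 2.0)
  expect_equal(get("PF", "per_patient_median"), 2)
  # dist partition: 1 + 2 + 3+ = patients with >= 1 episode
  expect_equal(inc$dist_1 + inc$dist_2 + inc$dist_3plus, inc$n_patients)
  expect_equal(get("PF", "dist_1"), 1L)
  expect_equal(get("PF", "dist_2"), 1L)
  expect_equal(get("PF", "dist_3plus"), 1L)
  # single patient, single episode
  one <- cluster_episodes(make_events("Z", D("2005-05-05")), window_policy(21))
  inc1 <- incidence_table(one)
  expect_equal(inc1$episode_total[inc1$sre_type == "PF"], 1L)
  expect_equal(inc1$per_patient_mean[inc1$sre_type == "PF"], 1.0)
  expect_equal(inc1$dist_1[inc1$sre_type == "PF"], 1L)
})

test_that("measure invariants hold on arbitrary synthetic inputs", {
  sim <- simulate_claims(sim_config(n_patients = 70, seed = 5))
  cbf <- default_codebook()
  coh <- select_cohort(sim$patients, sim$claims, cbf)
  ev <- identify_events(sim$claims, cbf, sre_definition("base_case"), coh)
  prev <- prevalence_table(ev, coh)
  n_any <- prev$n_patients[prev$sre_type == "ANY"]
  expect_lte(n_any, length(coh$included))
  expect_true(all(prev$n_patients <= n_any))
  inc <- incidence_table(cluster_episodes(kept_events(ev), window_policy(21)),
                         coh)
  expect_equal(inc$episode_total[inc$sre_type == "ANY"],
               sum(inc$episode_total[inc$sre_type != "ANY"]))
  expect_equal(inc$dist_1 + inc$dist_2 + inc$dist_3plus, inc$n_patients)
  combos <- type_combination_tally(ev)
  expect_equal(sum(combos$combos$n_patients), combos$n_sre_patients)
  expect_equal(combos$n_sre_patients, n_any)
})

test_that("percent change convention, zero baseline, and inverse identity", {
  expect_equal(pct_change(12930, 11889), -8)
  expect_equal(pct_change(5, 5), 0)
  expect_true(is.na(pct_change(0, 7)))
  set.seed(13)
  for (rep in 1:20) {
    a <- sample(50:5000, 1); b <- sample(50:5000, 1)
    dab <- pct_change(a, b, digits = 10)
    dba <- pct_change(b, a, digits = 10)
    expect_equal((1 + dab / 100) * (1 + dba / 100), 1, tolerance = 1e-6)
  }
})

test_that("episode comparison table signs decreases per subtype", {
  a <- incidence_from_counts(c(PF = 100, SCC = 50, RAD = 200, BS = 10),
                             c(PF = 40, SCC = 30, RAD = 80, BS = 10, ANY = 100),
                             14)
  b <- incidence_from_counts(c(PF = 90, SCC = 55, RAD = 150, BS = 10),
                             c(PF = 40, SCC = 30, RAD = 80, BS = 10, ANY = 100),
                             28)
  cmp <- episode_count_change(a, b)
  expect_equal(cmp$pct_change[cmp$sre_type == "PF"], -10)
  expect_equal(cmp$pct_change[cmp$sre_type == "SCC"], 10)
  expect_equal(cmp$pct_change[cmp$sre_type == "BS"], 0)
})

test_that("time-to-event summary uses anchors and the even-n median rule", {
  pts <- rbind(make_patient("A", D("2005-01-01"), death = D("2006-01-01")),
               make_patient("B", D("2005-01-01")))
  coh <- select_cohort(pts, make_claim("CX", "A", D("2005-01-02"), "V1"),
                       tiny_codebook())
  eps <- cluster_episodes(rbind(
    make_events("A", D("2005-06-04")),                     # dx + 154
    make_events("B", D(c("2005-04-11", "2005-10-28")))     # dx + 100, +300
  ), window_policy(21))
  tte <- time_to_event_summary(eps, pts, coh)
  # gaps to first SRE {154, 100}: even count, mean of the middle two
  expect_equal(tte$dx_to_first_sre[["median"]], 127)
  expect_equal(tte$dx_to_first_sre[["n"]], 2)
  expect_equal(tte$first_to_second_sre[["median"]], 200)
  expect_equal(tte$first_to_second_sre[["n"]], 1)
  expect_equal(tte$dx_to_death[["median"]], 365)
  expect_equal(tte$dx_to_death[["n"]], 1)
  # no SRE patients: strata reported absent, not an error
  none <- cluster_episodes(make_events("A", as.Date(character())),
                           window_policy(21))
  tte0 <- time_to_event_summary(none, pts, coh)
  expect_true(is.na(tte0$dx_to_first_sre[["median"]]))
  expect_equal(tte0$dx_to_first_sre[["n"]], 0)
})

test_that("type combinations partition SRE patients", {
  ev <- rbind(make_events("A", D("2005-02-01")),
              make_events("B", D("2005-02-01")),
              make_events("B", D("2005-03-01"), sre_type = "RAD"),
              make_events("C", D("2005-02-01")),
              make_events("C", D("2005-03-01"), sre_type = "RAD"),
              make_events("C", D("2005-04-01"), sre_type = "SCC"))
  class(ev) <- c("sre_events", "data.frame")
  tally <- type_combination_tally(ev)
  expect_equal(tally$n_sre_patients, 3)
  expect_equal(sum(tally$combos$n_patients), 3)
  expect_equal(tally$combos$n_patients[tally$combos$combination == "PF+RAD"], 1L)
  expect_equal(tally$multi_type_share_pct, 66.7)
  # all single-type: share zero
  solo <- ev[ev$sre_type == "PF", ]
  class(solo) <- c("sre_events", "data.frame")
  expect_equal(type_combination_tally(solo)$multi_type_share_pct, 0)
})
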