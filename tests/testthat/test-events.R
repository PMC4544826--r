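cb <- tiny_codebook()
dx <- D("2005-01-01")

setup_one <- function(claims) {
  p <- make_patient("P1", dx)
  coh <- select_cohort(p, claims, cb)
  list(patient = p, cohort = coh, claims = claims)
}

test_that("claims become deduplicated per-day subtype events", {
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "733.14"),
    make_claim("C2", "P1", dx + 100L, "733.15"),   # same day, same subtype
    make_claim("C3", "P1", dx + 100L, "9224", "ICD9_PX"),
    make_claim("C4", "P1", dx + 200L, "3369"),
    make_claim("C5", "P1", dx + 150L, "V7231")     # non-matching
  )
  s <- setup_one(claims)
  ev <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
  expect_equal(nrow(ev), 3)
  pf <- ev[ev$sre_type == "PF", ]
  expect_equal(nrow(pf), 1)
  expect_equal(pf$source_claim_ids, "C1;C2")
  expect_true(all(ev$status == "KEPT"))
  # empty claim stream: empty event list
  empty <- identify_events(claims[0, ], cb, sre_definition("base_case"),
                           s$cohort)
  expect_equal(nrow(empty), 0)
})

test_that("definition tiers gate which matches become events", {
  claims <- claims_table(
    make_claim("C1", "P1", dx + 50L, "8052"),            # other fracture
    make_claim("C2", "P1", dx + 90L, "7211"),            # myelopathy ext
    make_claim("C3", "P1", dx + 120L, "77418", "HCPCS")  # IMRT ext
  )
  s <- setup_one(claims)
  base <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
  alt <- identify_events(claims, cb, sre_definition("alternative"), s$cohort)
  expect_equal(base$sre_type[base$status == "KEPT"], "PF")
  expect_setequal(alt$sre_type[alt$status == "KEPT"], c("SCC", "RAD"))
})

test_that("trauma lookback boundary: offsets 13, 14, 15 and same-day", {
  for (off in c(0L, 13L, 14L, 15L)) {
    claims <- claims_table(
      make_claim("C1", "P1", dx + 100L, "8052"),
      make_claim("C2", "P1", dx + 100L - off, "E8810")
    )
    s <- setup_one(claims)
    ev <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
    expected <- if (off <= 14L) "EXCLUDED_TRAUMA" else "KEPT"
    expect_equal(ev$status[ev$sre_type == "PF"], expected,
                 label = paste("offset", off))
  }
  # trauma strictly after the fracture never excludes
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "8052"),
    make_claim("C2", "P1", dx + 101L, "E8810")
  )
  s <- setup_one(claims)
  ev <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
  expect_equal(ev$status[ev$sre_type == "PF"], "KEPT")
})

test_that("same-level falls are exempt but do not shield other trauma", {
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "8052"),
    make_claim("C2", "P1", dx + 98L, "E8850")   # exempt fall only
  )
  s <- setup_one(claims)
  ev <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
  expect_equal(ev$status[ev$sre_type == "PF"], "KEPT")

  claims2 <- rbind(claims, make_claim("C3", "P1", dx + 92L, "E8810"))
  ev2 <- identify_events(claims2, cb, sre_definition("base_case"),
                         setup_one(claims2)$cohort)
  expect_equal(ev2$status[ev2$sre_type == "PF"], "EXCLUDED_TRAUMA")
})

test_that("specificity-tier fractures are immune to the trauma rule", {
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "733.14"),
    make_claim("C2", "P1", dx + 92L, "E8810")
  )
  s <- setup_one(claims)
  ev <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
  expect_equal(ev$status[ev$sre_type == "PF"], "KEPT")
  # a day carrying both a 733.1X and an other-fracture claim is a
  # specificity event-day and stays immune
  claims3 <- rbind(claims, make_claim("C3", "P1", dx + 100L, "8052"))
  ev3 <- identify_events(claims3, cb, sre_definition("base_case"),
                         setup_one(claims3)$cohort)
  pf <- ev3[ev3$sre_type == "PF", ]
  expect_equal(pf$matched_tier, "SPECIFICITY")
  expect_equal(pf$status, "KEPT")
})

test_that("adding a trauma claim never increases kept events (property)", {
  set.seed(301)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    claims <- do.call(rbind, lapply(seq_len(n), function(k)
      make_claim(paste0("C", k), "P1", dx + sample(10:300, 1),
                 sample(c("8052", "733.14", "3369"), 1))))
    s <- setup_one(claims)
    ev0 <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
    claims_t <- rbind(claims, make_claim("CT", "P1", dx + sample(10:300, 1),
                                         "E8810"))
    ev1 <- identify_events(claims_t, cb, sre_definition("base_case"), s$cohort)
    expect_lte(sum(ev1$status == "KEPT"), sum(ev0$status == "KEPT"))
  }
})

test_that("identification is invariant to claim-row order", {
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "8052"),
    make_claim("C2", "P1", dx + 92L, "E8810"),
    make_claim("C3", "P1", dx + 50L, "733.14"),
    make_claim("C4", "P1", dx + 120L, "9224", "ICD9_PX"),
    make_claim("C5", "P1", dx + 120L, "3369")
  )
  s <- setup_one(claims)
  ev <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
  set.seed(9)
  for (rep in 1:5) {
    shuffled <- claims[sample(nrow(claims)), ]
    evs <- identify_events(shuffled, cb, sre_definition("base_case"), s$cohort)
    expect_identical(as.data.frame(evs), as.data.frame(ev))
  }
})

test_that("events outside follow-up are flagged, not kept", {
  p <- make_patient("P1", dx, death = dx + 150L)
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "733.14"),
    make_claim("C2", "P1", dx + 200L, "733.14")  # after death
  )
  coh <- select_cohort(p, claims, cb)
  ev <- identify_events(claims, cb, sre_definition("base_case"), coh)
  expect_equal(ev$status[ev$date == dx + 100L], "KEPT")
  expect_equal(ev$status[ev$date == dx + 200L], "EXCLUDED_OUTSIDE_FOLLOWUP")
})

test_that("same-day hierarchy suppresses treatment events only when enabled", {
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "733.14"),
    make_claim("C2", "P1", dx + 100L, "9224", "ICD9_PX"),
    make_claim("C3", "P1", dx + 200L, "9224", "ICD9_PX")
  )
  s <- setup_one(claims)
  off <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
  expect_true(all(off$status == "KEPT"))
  on <- identify_events(claims, cb,
                        sre_definition("base_case", same_day_hierarchy = TRUE),
                        s$cohort)
  expect_equal(on$status[on$sre_type == "RAD" & on$date == dx + 100L],
               "EXCLUDED_HIERARCHY")
  # RAD alone on its day stays kept
  expect_equal(on$status[on$sre_type == "RAD" & on$date == dx + 200L], "KEPT")
  expect_equal(on$status[on$sre_type == "PF"], "KEPT")
})

test_that("optional radiation concurrency filter requires a bone context", {
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "9224", "ICD9_PX"),
    make_claim("C2", "P1", dx + 200L, "9224", "ICD9_PX"),
    make_claim("C3", "P1", dx + 200L, "1985")  # bone metastasis same day
  )
  s <- setup_one(claims)
  ev <- identify_events(claims, cb,
    sre_definition("base_case", rad_concurrency_filter = TRUE), s$cohort)
  expect_equal(ev$status[ev$date == dx + 100L], "EXCLUDED_CONCURRENCY")
  expect_equal(ev$status[ev$date == dx + 200L], "KEPT")
})

test_that("optional BS trauma lookback mirrors the fracture rule", {
  claims <- claims_table(
    make_claim("C1", "P1", dx + 100L, "7851", "ICD9_PX"),
    make_claim("C2", "P1", dx + 95L, "E8810")
  )
  s <- setup_one(claims)
  off <- identify_events(claims, cb, sre_definition("base_case"), s$cohort)
  expect_equal(off$status[off$sre_type == "BS"], "KEPT")
  on <- identify_events(claims, cb,
    sre_definition("base_case", bs_trauma_lookback = TRUE), s$cohort)
  expect_equal(on$status[on$sre_type == "BS"], "EXCLUDED_TRAUMA")
})

test_that("definition monotonicity holds per patient on synthetic data", {
  sim <- simulate_claims(sim_config(n_patients = 80, seed = 23))
  full <- default_codebook()
  coh <- select_cohort(sim$patients, sim$claims, full)
  ev_b <- kept_events(identify_events(sim$claims, full,
                                      sre_definition("base_case"), coh))
  ev_a <- kept_events(identify_events(sim$claims, full,
                                      sre_definition("alternative"), coh))
  key <- function(ev, t) paste(ev$patient_id, ev$date)[ev$sre_type == t]
  # PF: base case (sensitive list) is a superset of alternative
  expect_true(all(key(ev_a, "PF") %in% key(ev_b, "PF")))
  # SCC, RAD: alternative (sensitive lists) is a superset of base case
  expect_true(all(key(ev_b, "SCC") %in% key(ev_a, "SCC")))
  expect_true(all(key(ev_b, "RAD") %in% key(ev_a, "RAD")))
  # BS: identical
  expect_setequal(key(ev_b, "BS"), key(ev_a, "BS"))
})
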