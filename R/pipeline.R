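#' Default pipeline configuration
#'
#' Every study parameter is a config key with the study's value as its
#' default: window 21 days (episode-start anchoring), definition
#' `base_case`, trauma lookback 14 days, all option flags off, study end
#' 2010-12-31. Configs are read from YAML by [run_pipeline()]; keys given
#' there override these defaults.
#'
#' @return Nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    inputs = list(patients = NULL, claims = NULL, codebook = NULL),
    definition = "base_case",
    window = 21L,
    anchoring = "episode_start",
    compare_windows = c(14L, 21L, 28L),
    study = list(study_end = "2010-12-31", enrollment_lookback_days = 365L,
                 trauma_lookback_days = 14L, age_minimum = 66L),
    options = list(same_day_hierarchy = FALSE, rad_concurrency_filter = FALSE,
                   bs_trauma_lookback = FALSE),
    simulate = NULL
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

write_stage <- function(writer, obj, path) {
  tmp <- paste0(path, ".partial")
  writer(obj, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the end-to-end SRE measurement pipeline
#'
#' Orchestrates cohort selection, event identification, episode clustering,
#' the summary measures, and window comparisons, writing all outputs plus a
#' run manifest to `out_dir`. Inputs come from the config's `inputs` paths,
#' or are generated by the synthetic module when a `simulate` section is
#' present. Stage outputs are written to `<name>.csv.partial` and renamed on
#' stage success, so a failed run leaves its partial file marked.
#'
#' @param config Path to a YAML config, or a config list; keys override
#'   [default_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config's simulation seed.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim_used <- !is.null(cfg$simulate)
  inputs <- stage("ingest", {
    if (sim_used) {
      sc_args <- cfg$simulate
      if (!is.null(seed)) sc_args$seed <- seed
      if (!is.null(sc_args$episode_rates))
        sc_args$episode_rates <- unlist(sc_args$episode_rates)
      sim <- simulate_claims(do.call(sim_config, sc_args))
      write_stage(write_patients, sim$patients, file.path(out_dir, "patients.csv"))
      write_stage(write_claims, sim$claims, file.path(out_dir, "claims.csv"))
      write_stage(function(x, p) utils::write.csv(x, p, row.names = FALSE),
                  sim$truth$episodes, file.path(out_dir, "truth.csv"))
      sim
    } else {
      if (is.null(cfg$inputs$patients) || is.null(cfg$inputs$claims)) {
        stop("config must name inputs$patients and inputs$claims ",
             "(or a simulate section)")
      }
      list(patients = read_patients(cfg$inputs$patients),
           claims = read_claims(cfg$inputs$claims))
    }
  })
  cb <- stage("codebook", {
    if (!is.null(cfg$inputs$codebook)) load_codebook(cfg$inputs$codebook)
    else default_codebook()
  })
  study <- stage("config", do.call(study_config, cfg$study))
  definition <- stage("definition", do.call(sre_definition,
    c(list(name = cfg$definition), cfg$options)))

  cohort <- stage("cohort", select_cohort(inputs$patients, inputs$claims, cb, study))
  write_stage(function(x, p) utils::write.csv(
    data.frame(patient_id = x), p, row.names = FALSE),
    cohort$included, file.path(out_dir, "included_ids.csv"))
  write_stage(function(x, p) utils::write.csv(x, p, row.names = FALSE),
              cohort$exclusion_log, file.path(out_dir, "exclusion_log.csv"))

  events <- stage("identify",
                  identify_events(inputs$claims, cb, definition, cohort, study))
  write_stage(write_events, events, file.path(out_dir, "events.csv"))

  policy <- window_policy(cfg$window, cfg$anchoring)
  episodes <- stage("cluster", cluster_episodes(kept_events(events), policy))
  write_stage(write_episodes, episodes, file.path(out_dir, "episodes.csv"))

  summaries <- stage("summarize", {
    prev <- prevalence_table(events, cohort, cfg$definition)
    inc <- incidence_table(episodes, cohort)
    tte <- time_to_event_summary(episodes, inputs$patients, cohort)
    combos <- type_combination_tally(events)
    write_stage(function(x, p) utils::write.csv(as.data.frame(x), p,
                                                row.names = FALSE),
                prev, file.path(out_dir, "prevalence.csv"))
    write_stage(function(x, p) utils::write.csv(as.data.frame(x), p,
                                                row.names = FALSE),
                inc, file.path(out_dir, "incidence.csv"))
    list(prevalence = prev, incidence = inc, tte = tte, combinations = combos)
  })

  comparisons <- stage("compare", {
    wins <- sort(unique(as.integer(cfg$compare_windows)))
    incs <- lapply(wins, function(w) incidence_table(
      cluster_episodes(kept_events(events), window_policy(w, cfg$anchoring)),
      cohort))
    names(incs) <- as.character(wins)
    cmp <- list()
    if (length(wins) > 1) {
      for (k in seq_len(length(wins) - 1)) {
        cmp[[paste0(wins[k], "_to_", wins[k + 1])]] <-
          episode_count_change(incs[[k]], incs[[k + 1]])
      }
    }
    if (length(cmp)) {
      flat <- do.call(rbind, lapply(names(cmp), function(nm)
        cbind(comparison = nm, as.data.frame(cmp[[nm]]))))
      write_stage(function(x, p) utils::write.csv(x, p, row.names = FALSE),
                  flat, file.path(out_dir, "comparisons.csv"))
    }
    list(incidence_by_window = incs, changes = cmp)
  })

  manifest <- list(
    tool = "skelevent",
    version = as.character(utils::packageVersion("skelevent")),
    inputs = cfg$inputs,
    simulated = sim_used,
    codebook_md5 = if (!is.null(cfg$inputs$codebook))
      unname(tools::md5sum(cfg$inputs$codebook))
      else unname(tools::md5sum(system.file("extdata", "default_codebook.csv",
                                            package = "skelevent"))),
    definition = cfg$definition,
    window_days = policy$length_days,
    anchoring = policy$anchoring,
    seed = if (sim_used) {
      if (!is.null(seed)) seed else cfg$simulate$seed
    },
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(cohort = cohort, events = events, episodes = episodes,
                 summaries = summaries, comparisons = comparisons,
                 manifest = manifest))
}
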