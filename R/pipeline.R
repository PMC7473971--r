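#' Default pipeline configuration
#'
#' A nested list mirroring each module's parameters, serializable to YAML.
#' Sections: `seed`, `timing`, `synthesis`, `design`, `sdt`, and `render`
#' switches.
#'
#' @param seed Global seed; fanned out per stage via [split_seed()].
#' @return Nested configuration list of class `melofractal_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    subject = 1L,
    n_subjects = 1L,
    timing = list(leaf_tone_dur = 0.22, g1 = 0.04, g2 = 0.09, g3 = 0.10,
                  cue_dur = 0.84, inter_step_gap = 1.00),
    design = list(root_set = as.integer(default_root_set()),
                  yoked_intervals = TRUE, jitter_range = c(2, 4),
                  jitter_grid = 0.5, iti = 2.0, decision_cap = 5.0),
    synthesis = list(sample_rate = 44100L,
                     level_gain = c(0.25, 0.24, 0.23, 0.22),
                     ramp_dur = 0.010, bits = "pcm16"),
    sdt = list(dprime = c(recursion = 1.06, iteration = 0.88,
                          repetition = 1.31),
               criterion = 0,
               rt_median = c(recursion = 0.78, iteration = 0.74,
                             repetition = 0.58),
               rt_sdlog = 0.35, rt_cap = 5),
    render = list(pool_midi = FALSE, pool_wav = FALSE)
  ), class = "melofractal_config")
}

#' Read a YAML pipeline configuration
#'
#' Unspecified fields fall back to [default_config()]; unknown fields are an
#' error (schema check).
#'
#' @param path YAML file path.
#' @return Configuration list of class `melofractal_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- unclass(default_config())
  merge_cfg <- function(base, user, where = "config") {
    for (nm in names(user)) {
      if (!nm %in% names(base))
        stop("unknown ", where, " field: ", nm)
      if (is.list(base[[nm]])) {
        base[[nm]] <- merge_cfg(base[[nm]], as.list(user[[nm]]),
                                paste0(where, "$", nm))
      } else {
        val <- user[[nm]]
        if (!is.null(names(base[[nm]])) && is.list(val))
          val <- unlist(val)
        base[[nm]] <- val
      }
    }
    base
  }
  cfg <- merge_cfg(base, user)
  validate_config(structure(cfg, class = "melofractal_config"))
}

#' Write a configuration to YAML
#' @param cfg A `melofractal_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  # named atomic vectors must serialize as YAML maps, not bare sequences
  mapify <- function(x) {
    if (is.list(x)) lapply(x, mapify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(mapify(unclass(cfg)), path)
  invisible(path)
}

#' Validate a pipeline configuration
#' @param cfg A `melofractal_config`.
#' @return The configuration, invisibly, after constructing every module
#'   config (which enforces each module's invariants).
#' @export
validate_config <- function(cfg) {
  do.call(timing_config, cfg$timing)
  do.call(synth_config, cfg$synthesis)
  config_design(cfg)
  config_sdt(cfg)
  invisible(cfg)
}

config_design <- function(cfg) {
  design_config(root_set = cfg$design$root_set,
                yoked_intervals = cfg$design$yoked_intervals,
                jitter_range = cfg$design$jitter_range,
                jitter_grid = cfg$design$jitter_grid,
                iti = cfg$design$iti, decision_cap = cfg$design$decision_cap,
                timing = do.call(timing_config, cfg$timing))
}

config_sdt <- function(cfg) {
  sdt_config(dprime = unlist(cfg$sdt$dprime),
             criterion = unlist(cfg$sdt$criterion),
             rt_median = unlist(cfg$sdt$rt_median),
             rt_sdlog = cfg$sdt$rt_sdlog, rt_cap = cfg$sdt$rt_cap)
}

#' Run the full stimulus-to-analysis pipeline
#'
#' Executes pool enumeration, plan construction and validation, event-table
#' export, optional pool rendering to MIDI/WAV, response simulation, and
#' behavioral analysis (summary, per-subject d-prime, repeated-measures
#' ANOVA). Writes a `manifest.json` listing every output file with its MD5
#' checksum; the whole bundle is reproducible from `(config, seed)`.
#'
#' @param cfg A `melofractal_config` (or path to a YAML file).
#' @param out_dir Output directory.
#' @return List with the plan, records, behavior summary, ANOVA result and
#'   the manifest, invisibly.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_msg <- function(...) message("[melofractal] ", sprintf(...))
  log_msg("seed %d -> stages: plan=%d jitter=%d responses=%d", cfg$seed,
          split_seed(cfg$seed, "plan"), split_seed(cfg$seed, "jitter"),
          split_seed(cfg$seed, "responses"))

  files <- character(0)
  add <- function(p) files <<- c(files, p)

  # resolved config
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(cfg, cfg_path)
  add(cfg_path)

  # stage: pool
  pool <- enumerate_pool(cfg$design$root_set)
  pool_path <- file.path(out_dir, "pool.tsv")
  utils::write.table(pool, pool_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(pool_path)
  log_msg("pool: %d stimuli", nrow(pool))

  # stage: plan
  dcfg <- config_design(cfg)
  plan <- build_experiment_plan(cfg$seed, subject = cfg$subject, cfg = dcfg)
  validate_plan(plan)
  plan_path <- file.path(out_dir, "plan.json")
  jsonlite::write_json(list(subject = plan$subject, seed = plan$seed,
                            trials = plan$trials),
                       plan_path, auto_unbox = TRUE, digits = NA)
  add(plan_path)
  log_msg("plan: %d trials, invariants OK", nrow(plan$trials))

  # stage: events
  ev_paths <- export_events_tsv(plan, out_dir)
  for (p in ev_paths) add(p)

  # stage: render (optional; one file per pool stimulus)
  tcfg <- do.call(timing_config, cfg$timing)
  if (isTRUE(cfg$render$pool_midi) || isTRUE(cfg$render$pool_wav)) {
    scfg <- do.call(synth_config, cfg$synthesis)
    for (i in seq_len(nrow(pool))) {
      p <- pool_row_params(pool[i, ], cfg$design$root_set)
      ev <- schedule_events(steps_recursion(p)[[4]], tcfg)
      stem <- sprintf("stim_x%02d_l%d_t%d_c%s", p$x0, p$l, p$t,
                      if (p$c > 0) "asc" else "desc")
      if (isTRUE(cfg$render$pool_midi)) {
        mp <- file.path(out_dir, paste0(stem, ".mid"))
        render_midi(ev, mp)
        add(mp)
      }
      if (isTRUE(cfg$render$pool_wav)) {
        wp <- file.path(out_dir, paste0(stem, ".wav"))
        render_wav(ev, wp, scfg)
        add(wp)
      }
    }
    log_msg("rendered %d pool stimuli", nrow(pool))
  }

  # stage: simulate
  records <- simulate_responses(plan, config_sdt(cfg),
                                seed = split_seed(cfg$seed, "responses"),
                                subjects = cfg$n_subjects)
  rec_path <- file.path(out_dir, "responses.tsv")
  utils::write.table(records, rec_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(rec_path)

  # stage: analyze
  summary <- summarize_behavior(records)
  sum_path <- file.path(out_dir, "behavior_summary.tsv")
  utils::write.table(summary$per_cell, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(sum_path)
  anova <- if (cfg$n_subjects >= 2L) {
    res <- rm_anova_oneway(dprime_table(records))
    an_path <- file.path(out_dir, "anova.json")
    jsonlite::write_json(res[c("F", "df1", "df2", "p")], an_path,
                         auto_unbox = TRUE, digits = NA)
    add(an_path)
    res
  } else NULL

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         row.names = NULL)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  log_msg("wrote %d files + manifest", nrow(manifest))

  invisible(list(plan = plan, records = records, summary = summary,
                 anova = anova, manifest = manifest))
}
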