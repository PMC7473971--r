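## Seed management: one global seed is fanned out to per-stage child seeds by
## a fixed affine map, so every stage is independently reproducible and no
## stage perturbs the caller's RNG state.

#' Derive a child seed from a global seed
#'
#' `child = (seed * 7919 + 104729 * k) mod (2^31 - 1)` where `k` indexes the
#' stage. Purely deterministic; keeps seeds within 32-bit integer range.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (one of the pipeline stages) or an integer index.
#' @return Integer child seed.
#' @export
split_seed <- function(seed, stage) {
  stages <- c(pool = 1, plan = 2, jitter = 3, order = 4, twoafc = 5,
              responses = 6, render = 7, subject = 8)
  k <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else as.numeric(stage)
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

# Evaluate code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

#' Enumerate the stimulus pool
#'
#' All combinations of inter-level interval `l` in {4, 8}, inter-tone
#' interval `t` in {4, 8} and contour `c` in {-1, +1} (8 parameter
#' combinations), crossed with the four root pitches: 32 distinct fractals.
#'
#' @param root_set Root pitches (default [default_root_set()]).
#' @return `data.frame` with columns `x0`, `l`, `t`, `c`, one row per
#'   stimulus.
#' @export
enumerate_pool <- function(root_set = default_root_set()) {
  pool <- expand.grid(x0 = as.integer(root_set), l = c(4L, 8L), t = c(4L, 8L),
                      c = c(1L, -1L), KEEP.OUT.ATTRS = FALSE)
  pool <- pool[order(pool$x0, pool$l, pool$t, -pool$c), , drop = FALSE]
  rownames(pool) <- NULL
  pool
}

pool_row_params <- function(row, root_set = default_root_set()) {
  rule_params(row$x0, row$l, row$t, row$c, root_set = root_set)
}

#' Sample generation-phase jitters
#'
#' Seeded uniform draws on a grid spanning the generation-phase range
#' (default 2-4 s in 0.5 s steps).
#'
#' @param seed Integer seed.
#' @param n Number of draws.
#' @param range Length-2 numeric, jitter bounds in seconds.
#' @param grid Grid step in seconds; `NULL` for continuous uniform.
#' @return Numeric vector of `n` jitters.
#' @export
sample_jitter <- function(seed, n, range = c(2, 4), grid = 0.5) {
  stopifnot(n >= 1, length(range) == 2, range[2] > range[1])
  with_seed(seed, {
    if (is.null(grid)) {
      stats::runif(n, range[1], range[2])
    } else {
      sample(seq(range[1], range[2], by = grid), n, replace = TRUE)
    }
  })
}

#' Design configuration
#'
#' @param n_sessions Number of scanning sessions.
#' @param trials_per_rule_session Trials per rule per session.
#' @param root_set Root pitches.
#' @param yoked_intervals When `TRUE` (default) the inter-level and
#'   inter-tone intervals are yoked (`t = l`), giving the 12 interval-8 / 12
#'   interval-4 split per rule; when `FALSE`, `l` and `t` are balanced
#'   marginally over all 8 combinations.
#' @param jitter_range,jitter_grid Generation-phase jitter, s.
#' @param iti Inter-trial interval, s.
#' @param decision_cap Decision-phase maximum, s.
#' @param timing A [timing_config].
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_sessions = 4L, trials_per_rule_session = 6L,
                          root_set = default_root_set(),
                          yoked_intervals = TRUE,
                          jitter_range = c(2, 4), jitter_grid = 0.5,
                          iti = 2.0, decision_cap = 5.0,
                          timing = timing_config()) {
  if (n_sessions != 4L)
    stop("the balancing scheme requires 4 sessions")
  if (trials_per_rule_session %% 2L != 0L)
    stop("trials per rule per session must be even (half correct, half foil)")
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_rule_session = as.integer(trials_per_rule_session),
                 root_set = as.integer(root_set),
                 yoked_intervals = yoked_intervals,
                 jitter_range = jitter_range, jitter_grid = jitter_grid,
                 iti = iti, decision_cap = decision_cap, timing = timing),
            class = "design_config")
}

# Deal 12 rule x correctness trials (4 contour-by-interval cells x 3
# replicates) into 4 sessions so each session receives 3 trials of distinct
# cells; the foil group's cell cycle is offset by 2 relative to the correct
# group's, which makes contour come out exactly 3/3 per session x rule once
# correct and foil trials are pooled.
deal_cells <- function(offset) {
  out <- data.frame(rep = integer(0), cell = integer(0), session = integer(0))
  for (r in 0:2) {
    for (cell in 0:3) {
      out <- rbind(out, data.frame(
        rep = r, cell = cell, session = ((cell + r + offset) %% 4L) + 1L))
    }
  }
  out
}

rule_names <- function() c("recursion", "iteration", "repetition")

#' Build a balanced four-session experiment plan
#'
#' Each session holds 18 trials, 6 per rule (recursion, iteration,
#' repetition), half correct and half foils. Across the four sessions each
#' rule contributes 24 trials balanced 12/12 on correctness, ascending vs
#' descending contour, and interval 8 vs interval 4 (6 correct and 6 foils
#' within each interval). In-scanner foils are positional only. Trial order
#' within a session is pseudorandomized from the seed; the session sequence
#' is permuted across subjects from the seed. The full plan is deterministic
#' given `(seed, subject)`.
#'
#' @param seed Integer seed.
#' @param subject Subject index (drives the session-order permutation) or a
#'   BIDS-style label like `"sub-03"`.
#' @param cfg A [design_config].
#' @return An object of class `experiment_plan`: list with `subject`, `seed`,
#'   `cfg` and `trials` (one row per trial; repetition trials carry their two
#'   distractor parameter sets in `d1_*`/`d2_*` columns).
#' @export
build_experiment_plan <- function(seed, subject = 1L, cfg = design_config()) {
  sub_idx <- if (is.character(subject)) {
    as.integer(sub(".*?(\\d+)$", "\\1", subject))
  } else as.integer(subject)
  if (is.na(sub_idx)) stop("subject must be an integer or end in digits")
  sub_label <- if (is.character(subject)) subject else
    sprintf("sub-%02d", sub_idx)

  reps_per_cell <- cfg$trials_per_rule_session * cfg$n_sessions / 8L
  if (reps_per_cell != round(reps_per_cell))
    stop("infeasible balance: trials per rule (", cfg$trials_per_rule_session *
           cfg$n_sessions, ") not divisible by the 8 balancing cells")

  # cells: 0 = (asc, 4), 1 = (asc, 8), 2 = (desc, 4), 3 = (desc, 8)
  cell_contour <- c(1L, 1L, -1L, -1L)
  cell_interval <- c(4L, 8L, 4L, 8L)

  trials <- list()
  for (ri in seq_along(rule_names())) {
    rule <- rule_names()[ri]
    for (ci in 1:2) {
      correctness <- c("correct", "foil")[ci]
      deal <- deal_cells(offset = if (ci == 1L) 0L else 2L)
      df <- data.frame(
        rule = rule, correctness = correctness,
        session = deal$session,
        c = cell_contour[deal$cell + 1L],
        interval = cell_interval[deal$cell + 1L],
        rep = deal$rep)
      if (cfg$yoked_intervals) {
        df$l <- df$interval
        df$t <- df$interval
      } else {
        # alternate t within each cell's replicates so t is 6/6 marginally
        # and all 8 (l, t, c) combos appear equally often over the plan
        df$l <- df$interval
        flip <- (deal$cell + ci) %% 2L
        df$t <- ifelse((deal$rep + flip) %% 2L == 0L, 4L, 8L)
      }
      trials[[length(trials) + 1L]] <- df
    }
  }
  trials <- do.call(rbind, trials)

  # roots: balanced per rule, seeded assignment
  plan_seed <- split_seed(seed, "plan")
  trials$x0 <- NA_integer_
  with_seed(plan_seed, {
    for (rule in rule_names()) {
      idx <- which(trials$rule == rule)
      roots <- rep(cfg$root_set, length.out = length(idx))
      trials$x0[idx] <- sample(roots)
    }
  })

  trials$foil_type <- ifelse(trials$correctness == "foil", "positional",
                             "none")

  # distractor hierarchies for repetition trials
  pool <- enumerate_pool(cfg$root_set)
  for (col in c("d1_x0", "d1_l", "d1_t", "d1_c", "d2_x0", "d2_l", "d2_t",
                "d2_c"))
    trials[[col]] <- NA_integer_
  rep_idx <- which(trials$rule == "repetition")
  with_seed(split_seed(seed, "pool"), {
    for (i in rep_idx) {
      ref_key <- paste(trials$x0[i], trials$l[i], trials$t[i], trials$c[i])
      pool_key <- paste(pool$x0, pool$l, pool$t, pool$c)
      pick <- sample(which(pool_key != ref_key), 2L)
      trials[i, c("d1_x0", "d1_l", "d1_t", "d1_c")] <-
        as.integer(pool[pick[1], c("x0", "l", "t", "c")])
      trials[i, c("d2_x0", "d2_l", "d2_t", "d2_c")] <-
        as.integer(pool[pick[2], c("x0", "l", "t", "c")])
    }
  })

  # jitter, seeded
  trials$jitter <- sample_jitter(split_seed(seed, "jitter"), nrow(trials),
                                 range = cfg$jitter_range,
                                 grid = cfg$jitter_grid)

  # pseudorandom trial order within each session
  with_seed(split_seed(seed, "order"), {
    ord <- unlist(lapply(1:cfg$n_sessions, function(s) {
      idx <- which(trials$session == s)
      sample(idx)
    }))
    trials <- trials[ord, , drop = FALSE]
  })

  # session-order permutation across subjects
  perm <- with_seed(split_seed(seed, "subject") + sub_idx,
                    sample(cfg$n_sessions))
  trials$session <- order(perm)[trials$session]
  trials <- trials[order(trials$session), , drop = FALSE]
  trials$index_in_session <- stats::ave(seq_len(nrow(trials)), trials$session,
                                        FUN = seq_along)
  trials$rep <- NULL
  trials$interval <- NULL
  rownames(trials) <- NULL

  structure(list(subject = sub_label, seed = as.integer(seed), cfg = cfg,
                 trials = trials),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("experiment_plan: %s  seed=%d  %d sessions x %d trials\n",
              x$subject, x$seed, x$cfg$n_sessions,
              nrow(x$trials) / x$cfg$n_sessions))
  print(table(rule = x$trials$rule, session = x$trials$session))
  invisible(x)
}

#' Validate an experiment plan against the design invariants
#'
#' Checks, per session: 18 trials with 6 per rule, 3 correct / 3 foil per
#' rule, contour 3/3 per rule; across sessions, per rule: 12 correct / 12
#' foils, 12 ascending / 12 descending, 12 interval-8 (6 correct, 6 foils) /
#' 12 interval-4; foils positional only; jitters inside the configured range.
#'
#' @param plan An `experiment_plan`.
#' @return `TRUE` invisibly; stops with the violated constraint otherwise.
#' @export
validate_plan <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  tr <- plan$trials
  cfg <- plan$cfg
  fail <- function(...) stop("plan invariant violated: ", ...)
  n_rs <- cfg$trials_per_rule_session
  for (s in 1:cfg$n_sessions) {
    ss <- tr[tr$session == s, ]
    if (nrow(ss) != 3L * n_rs)
      fail(sprintf("session %d has %d trials, expected %d", s, nrow(ss),
                   3L * n_rs))
    for (rule in rule_names()) {
      rr <- ss[ss$rule == rule, ]
      if (nrow(rr) != n_rs)
        fail(sprintf("session %d: %d %s trials, expected %d", s, nrow(rr),
                     rule, n_rs))
      if (sum(rr$correctness == "correct") != n_rs / 2L)
        fail(sprintf("session %d %s: correctness not balanced", s, rule))
      if (sum(rr$c == 1L) != n_rs / 2L)
        fail(sprintf("session %d %s: contour not balanced", s, rule))
    }
  }
  for (rule in rule_names()) {
    rr <- tr[tr$rule == rule, ]
    n <- nrow(rr)
    if (sum(rr$correctness == "correct") != n / 2L)
      fail(rule, ": correctness not 12/12 across sessions")
    if (sum(rr$c == 1L) != n / 2L)
      fail(rule, ": contour not 12/12 across sessions")
    if (sum(rr$l == 8L) != n / 2L)
      fail(rule, ": inter-level interval not 12/12 across sessions")
    if (sum(rr$t == 8L) != n / 2L)
      fail(rule, ": inter-tone interval not 12/12 across sessions")
    i8 <- rr[rr$l == 8L, ]
    if (sum(i8$correctness == "correct") != nrow(i8) / 2L)
      fail(rule, ": interval-8 stimuli not split 6 correct / 6 foils")
  }
  if (!all(tr$foil_type %in% c("none", "positional")))
    fail("in-scanner foils must be positional only")
  if (any(tr$correctness == "foil" & tr$foil_type == "none") ||
      any(tr$correctness == "correct" & tr$foil_type != "none"))
    fail("foil_type inconsistent with correctness")
  if (any(tr$jitter < cfg$jitter_range[1] | tr$jitter > cfg$jitter_range[2]))
    fail("generation jitter outside configured range")
  rp <- tr[tr$rule == "repetition", ]
  key <- function(p) paste(p[[1]], p[[2]], p[[3]], p[[4]])
  for (i in seq_len(nrow(rp))) {
    ks <- c(key(rp[i, c("x0", "l", "t", "c")]),
            key(rp[i, c("d1_x0", "d1_l", "d1_t", "d1_c")]),
            key(rp[i, c("d2_x0", "d2_l", "d2_t", "d2_c")]))
    if (anyDuplicated(ks))
      fail("repetition trial with non-distinct distractor hierarchies")
  }
  invisible(TRUE)
}

#' Phase timeline of a single trial
#'
#' @param jitter Generation-phase duration, s.
#' @param cfg A [design_config] (its timing and decision cap are used).
#' @return `data.frame` with columns `phase`, `onset`, `duration`; onsets
#'   relative to trial onset. The prior phase spans cue onset through the end
#'   of step 3 (26.04 s by default); the test sound is split at the end of
#'   its first cluster (2.4 s).
#' @export
trial_phases <- function(jitter, cfg = design_config()) {
  tc <- cfg$timing
  prior <- prior_phase_dur(tc)
  test_on <- prior + jitter
  part1 <- cluster_span(tc)
  total <- step_span(tc)
  data.frame(
    phase = c("prior", "generation", "test_part1", "test_part2", "decision"),
    onset = c(0, prior, test_on, test_on + part1, test_on + total),
    duration = c(prior, jitter, part1, total - part1, cfg$decision_cap))
}

#' Export BIDS-style event tables for an experiment plan
#'
#' One `events.tsv` per session with columns `onset`, `duration`,
#' `trial_type` (prior / generation / test_part1 / test_part2 / decision),
#' `rule`, `correctness`; onsets in seconds from session start, strictly
#' increasing, trials separated by the configured inter-trial interval.
#'
#' @param plan An `experiment_plan`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
export_events_tsv <- function(plan, dir) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- plan$cfg
  paths <- character(0)
  for (s in 1:cfg$n_sessions) {
    ss <- plan$trials[plan$trials$session == s, , drop = FALSE]
    ss <- ss[order(ss$index_in_session), , drop = FALSE]
    t0 <- 0
    rows <- list()
    for (i in seq_len(nrow(ss))) {
      ph <- trial_phases(ss$jitter[i], cfg)
      rows[[i]] <- data.frame(
        onset = t0 + ph$onset, duration = ph$duration,
        trial_type = ph$phase, rule = ss$rule[i],
        correctness = ss$correctness[i])
      t0 <- t0 + ph$onset[nrow(ph)] + ph$duration[nrow(ph)] + cfg$iti
    }
    ev <- do.call(rbind, rows)
    path <- file.path(dir, sprintf("%s_ses-%02d_events.tsv", plan$subject, s))
    utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Build a two-alternative forced-choice pretesting block
#'
#' The pretesting discrimination variant: per trial, the correct fourth step
#' and one foil are presented consecutively in seeded random order, and the
#' participant picks the correct one. Default 12 recursion + 12 iteration
#' trials with all three foil categories in the mix.
#'
#' @param seed Integer seed.
#' @param n_per_rule Trials per rule.
#' @param foil_mix Named weights over `positional`, `odd`, `repeat`.
#' @param root_set Root pitches.
#' @return `data.frame` with one row per trial: rule, stimulus parameters,
#'   `foil_type`, and `correct_first` (presentation order).
#' @export
make_2afc_block <- function(seed, n_per_rule = 12L,
                            foil_mix = c(positional = 1, odd = 1, `repeat` = 1),
                            root_set = default_root_set()) {
  stopifnot(all(names(foil_mix) %in% foil_types()), sum(foil_mix) > 0)
  pool <- enumerate_pool(root_set)
  with_seed(split_seed(seed, "twoafc"), {
    rules <- rep(c("recursion", "iteration"), each = n_per_rule)
    n <- length(rules)
    pick <- sample(nrow(pool), n, replace = n > nrow(pool))
    data.frame(
      trial = seq_len(n), rule = rules,
      pool[pick, c("x0", "l", "t", "c")],
      foil_type = sample(names(foil_mix), n, replace = TRUE,
                         prob = foil_mix / sum(foil_mix)),
      correct_first = sample(c(TRUE, FALSE), n, replace = TRUE),
      row.names = NULL)
  })
}
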