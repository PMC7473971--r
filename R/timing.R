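#' Timing configuration for stimulus scheduling
#'
#' All sounds, whatever the rule or step, are laid out on a fixed depth-4
#' grid of 27 terminal tone slots grouped as 3 clusters x 3 triplets x 3
#' tones, with a hierarchy of silent pauses: `g1` within a triplet, `g2`
#' between triplets, `g3` between clusters (`g2 > g1`, `g3 >= g2`). The
#' defaults solve the design's printed constraints exactly:
#'
#' * triplet span = `3*leaf + 2*g1` = 0.74 s,
#' * cluster span = `3*triplet + 2*g2` = 2.40 s,
#' * total span = `3*cluster + 2*g3` = 7.40 s,
#' * leaf/parent duration ratio 0.22/0.74 ~ 0.30 ("approximately 1/3").
#'
#' `cue_dur` and `inter_step_gap` place the four steps inside a trial so that
#' the prior phase (cue onset through end of step 3) lasts
#' `cue + 3*(7.4 + gap)` = 26.04 s.
#'
#' @param leaf_tone_dur Terminal tone duration, s.
#' @param g1 Pause within a triplet, s.
#' @param g2 Pause between triplets, s (must exceed `g1`).
#' @param g3 Pause between clusters, s (at least `g2`).
#' @param cue_dur Visual rule-cue duration at trial onset, s.
#' @param inter_step_gap Silence after each of steps 1-3, s.
#' @return An object of class `timing_config`.
#' @export
timing_config <- function(leaf_tone_dur = 0.22, g1 = 0.04, g2 = 0.09,
                          g3 = 0.10, cue_dur = 0.84, inter_step_gap = 1.00) {
  if (any(c(leaf_tone_dur, g1, g2, g3, cue_dur, inter_step_gap) <= 0))
    stop("all durations must be positive")
  if (g2 <= g1)
    stop("pause between triplets (g2) must exceed pause within triplets (g1)")
  if (g3 < g2)
    stop("pause between clusters (g3) must be at least the pause between triplets (g2)")
  structure(
    list(leaf_tone_dur = leaf_tone_dur, g1 = g1, g2 = g2, g3 = g3,
         cue_dur = cue_dur, inter_step_gap = inter_step_gap),
    class = "timing_config"
  )
}

#' @export
print.timing_config <- function(x, ...) {
  cat(sprintf(
    "timing_config: leaf=%.3gs g1=%.3gs g2=%.3gs g3=%.3gs (step span %.4gs)\n",
    x$leaf_tone_dur, x$g1, x$g2, x$g3, step_span(x)))
  invisible(x)
}

triplet_span <- function(cfg) 3 * cfg$leaf_tone_dur + 2 * cfg$g1
cluster_span <- function(cfg) 3 * triplet_span(cfg) + 2 * cfg$g2

#' Total span of one step sound under a timing configuration
#' @param cfg A [timing_config].
#' @return Seconds from first tone onset to last tone offset (7.4 with
#'   defaults).
#' @export
step_span <- function(cfg = timing_config()) 3 * cluster_span(cfg) + 2 * cfg$g3

#' Duration of the prior phase (cue onset through end of step 3)
#' @param cfg A [timing_config].
#' @return Seconds (26.04 with defaults).
#' @export
prior_phase_dur <- function(cfg = timing_config()) {
  cfg$cue_dur + 3 * (step_span(cfg) + cfg$inter_step_gap)
}

# Onset of 0-based terminal slot s (0..26) on the depth-4 grid.
leaf_onset <- function(s, cfg) {
  i <- s %/% 9L          # cluster
  k <- (s %% 9L) %/% 3L  # triplet within cluster
  q <- s %% 3L           # tone within triplet
  i * (cluster_span(cfg) + cfg$g3) + k * (triplet_span(cfg) + cfg$g2) +
    q * (cfg$leaf_tone_dur + cfg$g1)
}

#' Schedule a step structure as timed note events
#'
#' Implements the subtree-span timing model: every tone sounds for exactly
#' the temporal extent of its subtree on the fixed depth-4 grid, so dominant
#' tones play simultaneously with (and throughout) their subordinates, and
#' terminal tones occupy grid slots separated by the pause hierarchy. A
#' node's grid slots are derived from its temporal position path, so partial
#' structures (early iteration steps) keep every tone in the slot it holds in
#' the complete sound, and the sound envelope is the same 7.4 s whatever the
#' rule or step.
#'
#' @param step A `step_structure`.
#' @param cfg A [timing_config].
#' @param mode `"sustained"` schedules every node (the experiment's playback
#'   model); `"leaves"` schedules terminal nodes only (for inspection).
#' @return `data.frame` of class `note_events` with columns `onset`,
#'   `duration`, `pitch`, `level`, `triplet_index`, `cluster_index`, sorted
#'   by onset then level.
#' @export
schedule_events <- function(step, cfg = timing_config(),
                            mode = c("sustained", "leaves")) {
  stopifnot(inherits(step, "step_structure"), inherits(cfg, "timing_config"))
  mode <- match.arg(mode)
  rows <- list()
  walk <- function(node) {
    m <- length(node$position_path)
    # first 0-based terminal slot under this node, and slot count
    first <- if (m == 0L) 0L else
      as.integer(sum((node$position_path - 1L) * 3^(3L - seq_len(m))))
    count <- as.integer(3^(3L - m))
    onset <- leaf_onset(first, cfg)
    offset <- leaf_onset(first + count - 1L, cfg) + cfg$leaf_tone_dur
    keep <- if (mode == "sustained") TRUE else length(node$children) == 0L
    if (keep) {
      rows[[length(rows) + 1L]] <<- data.frame(
        onset = onset, duration = offset - onset, pitch = node$pitch,
        level = node$level,
        triplet_index = if (node$level >= 3L) first %/% 3L + 1L else NA_integer_,
        cluster_index = if (node$level >= 2L) first %/% 9L + 1L else NA_integer_)
    }
    for (ch in node$children) walk(ch)
  }
  walk(step$root)
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset, ev$level), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("note_events", "data.frame")
  ev
}

#' Write note events as a TSV table
#' @param events A `note_events` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
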