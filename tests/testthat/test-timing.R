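test_that("default timing reproduces the printed stimulus constants", {
  cfg <- timing_config()
  expect_equal(step_span(cfg), 7.4)
  expect_equal(prior_phase_dur(cfg), 26.04)
  ev <- schedule_events(steps_recursion(test_params())[[4]], cfg)
  expect_equal(max(ev$onset + ev$duration) - min(ev$onset), 7.4)
  # the first cluster (level-2 subtree) spans 2.4 s
  lvl2 <- ev[ev$level == 2L, ]
  expect_equal(lvl2$duration[1], 2.4)
  # a level-3 tone lasts 0.74 s; leaf/parent ratio ~ 1/3
  lvl3 <- ev[ev$level == 3L, ]
  expect_equal(lvl3$duration[1], 0.74)
  ratio <- ev$duration[ev$level == 4L][1] / lvl3$duration[1]
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.35)
})

test_that("timing invariants are enforced at construction", {
  expect_error(timing_config(g1 = 0.09, g2 = 0.04), "g2")
  expect_error(timing_config(g2 = 0.09, g3 = 0.05), "g3")
  expect_error(timing_config(leaf_tone_dur = 0), "positive")
})

test_that("subtree-span model: fully expanded parents span exactly their children", {
  # in complete structures every expanded node's span equals its children's
  # joint span; in partial iteration steps a parent still holds its full grid
  # slot (so the envelope stays fixed) and its children start with it
  nesting <- function(ev, complete) {
    for (lv in 1:3) {
      parents <- ev[ev$level == lv, , drop = FALSE]
      kids <- ev[ev$level == lv + 1L, , drop = FALSE]
      if (!nrow(kids)) next
      for (i in seq_len(nrow(parents))) {
        inside <- kids[kids$onset >= parents$onset[i] - 1e-9 &
                         kids$onset + kids$duration <=
                           parents$onset[i] + parents$duration[i] + 1e-9, ]
        if (!nrow(inside)) next
        expect_equal(min(inside$onset), parents$onset[i])
        if (complete)
          expect_equal(max(inside$onset + inside$duration),
                       parents$onset[i] + parents$duration[i])
      }
    }
    # same-level events never overlap; table sorted by onset
    expect_false(is.unsorted(ev$onset))
    for (lv in unique(ev$level)) {
      lev <- ev[ev$level == lv, , drop = FALSE]
      if (nrow(lev) > 1L)
        expect_true(all(diff(lev$onset) >= lev$duration[-nrow(lev)] - 1e-9))
    }
  }
  for (p in pool_params()[c(3, 17, 30)]) {
    for (step in steps_recursion(p)) nesting(schedule_events(step), TRUE)
    it <- steps_iteration(p)
    for (k in 1:3) nesting(schedule_events(it[[k]]), FALSE)
    nesting(schedule_events(it[[4]]), TRUE)
  }
})

test_that("every step of every rule fills the same 7.4 s envelope", {
  p <- test_params()
  all_steps <- c(steps_recursion(p), steps_iteration(p))
  for (step in all_steps) {
    ev <- schedule_events(step)
    expect_equal(min(ev$onset), 0)
    expect_equal(max(ev$onset + ev$duration), 7.4)
  }
  # recursion step 1 is a single tone spanning the whole grid
  ev1 <- schedule_events(steps_recursion(p)[[1]])
  expect_identical(nrow(ev1), 1L)
  expect_equal(ev1$duration, 7.4)
})

test_that("contour changes pitch-to-slot assignment but no onset or duration", {
  up <- schedule_events(steps_recursion(rule_params(40, 4, 8, +1))[[4]])
  down <- schedule_events(steps_recursion(rule_params(40, 4, 8, -1))[[4]])
  expect_identical(up[, c("onset", "duration", "level")],
                   down[, c("onset", "duration", "level")])
  expect_false(identical(up$pitch, down$pitch))
  expect_identical(sort(up$pitch), sort(down$pitch))
})

test_that("leaves-only mode schedules terminal tones on the pause grid", {
  cfg <- timing_config()
  ev <- schedule_events(steps_recursion(test_params())[[4]], cfg,
                        mode = "leaves")
  expect_identical(nrow(ev), 27L)
  expect_equal(ev$duration, rep(cfg$leaf_tone_dur, 27L))
  gaps <- round(diff(ev$onset) - cfg$leaf_tone_dur, 9)
  expect_identical(sort(unique(gaps)), c(cfg$g1, cfg$g2, cfg$g3))
  # pause hierarchy: 18 within-triplet, 6 between-triplet, 2 between-cluster
  expect_identical(as.integer(table(gaps)), c(18L, 6L, 2L))
  # triplet and cluster indices follow the 3 x 3 x 3 grid
  expect_identical(ev$cluster_index, rep(1:3, each = 9L))
  expect_identical(ev$triplet_index, rep(1:9, each = 3L))
})

test_that("events table writes as TSV and reads back", {
  ev <- schedule_events(steps_recursion(test_params())[[2]])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  back <- utils::read.delim(path)
  expect_equal(back$onset, ev$onset)
  expect_equal(back$pitch, ev$pitch)
})
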