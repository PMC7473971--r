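test_that("expand_tone applies the embedding rule in temporal order", {
  # hand substitutions into x -> [x - t*c + phi, x + phi, x + t*c + phi]
  expect_identical(expand_tone(64, test_params(c = +1)), c(68L, 72L, 76L))
  expect_identical(expand_tone(64, test_params(c = -1)), c(76L, 72L, 68L))
  expect_identical(expand_tone(40, rule_params(40, 8, 8, +1)),
                   c(48L, 56L, 64L))

  # contour flips temporal order only: same pitch set either way
  for (p in pool_params()) {
    up <- expand_tone(p$x0, rule_params(p$x0, p$l, p$t, +1))
    down <- expand_tone(p$x0, rule_params(p$x0, p$l, p$t, -1))
    expect_identical(up, rev(down))
    # lowest child sits exactly l above the parent, for both contours
    expect_identical(min(up), p$x0 + p$l)
  }
})

test_that("parameter domain is enforced", {
  expect_error(rule_params(40, 5, 4, 1), "l must be")
  expect_error(rule_params(40, 4, 6, 1), "t must be")
  expect_error(rule_params(40, 4, 4, 0), "c must be")
  expect_error(rule_params(41, 4, 4, 1), "root-pitch set")
  expect_error(node_pitch_closed_form(test_params(), c(1, 4)), "\\{1, 2, 3\\}")
  expect_error(node_pitch_closed_form(test_params(), c(1, 2, 3, 1)), "deeper")
  expect_error(build_fractal(test_params(), 5), "1-4")
})

test_that("closed-form pitch matches hand-derived cases", {
  p <- test_params()
  expect_identical(node_pitch_closed_form(p, c(3, 3, 3)), 100L)  # 64+24+4*3
  expect_identical(node_pitch_closed_form(p, c(2, 2, 2)), 88L)   # 64+24+0
  expect_identical(node_pitch_closed_form(p, integer(0)), 64L)   # root
})

test_that("recursive expansion agrees with the closed form for the whole pool", {
  # exhaustive oracle equivalence: 32 stimuli x 40 nodes each
  for (p in pool_params()) {
    tree <- build_fractal(p, 4)
    nodes <- flatten_tree(tree)
    expect_equal(nrow(nodes), 40L)
    for (i in seq_len(nrow(nodes))) {
      path <- if (nodes$path[i] == "") integer(0) else
        as.integer(strsplit(nodes$path[i], ".", fixed = TRUE)[[1]])
      expect_identical(nodes$pitch[i], node_pitch_closed_form(p, path))
    }
    # all pitches stay in MIDI range for the default root set
    expect_true(all(nodes$pitch >= 0 & nodes$pitch <= 127))
    # extreme leaf: three same-direction positions contribute 3t beyond 3*phi
    expect_identical(max(nodes$pitch), p$x0 + 3L * (p$l + p$t) + 3L * p$t)
  }
})

test_that("fractal trees are self-similar across levels", {
  # the interval pattern parent -> triplet is the same at every level
  for (p in pool_params()[c(1, 10, 23, 32)]) {
    tree <- build_fractal(p, 4)
    check <- function(node) {
      if (length(node$children)) {
        ivs <- vapply(node$children, function(ch) ch$pitch, integer(1)) -
          node$pitch
        expect_identical(ivs, p$l + p$t + p$t * p$c * c(-1L, 0L, 1L))
        expect_identical(min(ivs), p$l)  # lowest-child law
        for (ch in node$children) check(ch)
      }
    }
    check(tree)
  }
})

test_that("recursion steps grow by whole levels", {
  steps <- steps_recursion(test_params())
  expect_identical(vapply(steps, function(s) count_nodes(s$root), integer(1)),
                   c(1L, 4L, 13L, 40L))
  expect_identical(steps[[1]]$root$pitch, 64L)
  expect_length(steps[[1]]$root$children, 0)
  # deepest level of step 4 holds 27 tones; 9 per level-2 subtree
  nodes <- flatten_tree(steps[[4]]$root)
  expect_identical(sum(nodes$level == 4L), 27L)
  expect_identical(sum(nodes$level == 4L & startsWith(nodes$path, "1.")), 9L)
})

test_that("iteration steps fill the deepest level of a fixed scaffold", {
  p <- test_params()
  steps <- steps_iteration(p)
  expect_identical(vapply(steps, function(s) count_nodes(s$root), integer(1)),
                   c(13L, 22L, 31L, 40L))
  # step 1 already has three hierarchical levels
  expect_identical(max(flatten_tree(steps[[1]]$root)$level), 3L)
  # step 4 is tree-identical to recursion step 4 over the same params
  expect_true(tree_equal(steps[[4]]$root, steps_recursion(p)[[4]]$root))
})

test_that("cross-rule identity: serialized step-4 note tables are byte-identical", {
  for (p in pool_params()) {
    ev_r <- schedule_events(steps_recursion(p)[[4]])
    ev_i <- schedule_events(steps_iteration(p)[[4]])
    expect_identical(ev_r, ev_i)
  }
})

test_that("repetition presents two unrelated hierarchies then an exact repeat", {
  ref <- test_params()
  d1 <- rule_params(40, 8, 4, -1)
  d2 <- rule_params(43, 4, 8, +1)
  steps <- steps_repetition(ref, list(d1, d2))
  expect_identical(vapply(steps, function(s) count_nodes(s$root), integer(1)),
                   rep(40L, 4))
  expect_true(tree_equal(steps[[4]]$root, steps[[3]]$root))
  expect_true(tree_equal(steps[[4]]$root, steps_recursion(ref)[[4]]$root))
  expect_false(identical(leaf_pitches(steps[[1]]), leaf_pitches(steps[[3]])))
  expect_false(identical(leaf_pitches(steps[[2]]), leaf_pitches(steps[[3]])))
  expect_error(steps_repetition(ref, list(d1, d1)), "distinct")
  expect_error(steps_repetition(ref, list(ref, d2)), "distinct")
})

test_that("JSON tree serialization round-trips", {
  tree <- build_fractal(test_params(), 3)
  js <- tree_to_json(tree)
  expect_true(tree_equal(tree, tree_from_json(js)))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, path)
  expect_true(tree_equal(tree, tree_from_json(path)))
})
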