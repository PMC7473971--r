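#' Generative parameters of one melodic fractal
#'
#' A melodic fractal is a tone hierarchy in which every dominant tone governs
#' a triplet of subordinate tones, with identical pitch relations at every
#' level. Four parameters fully determine a fractal:
#'
#' * `x0` — root pitch (MIDI note number, integer semitones),
#' * `l`  — inter-level interval: semitone distance from a dominant tone to
#'   the lowest-pitched tone of its subordinate triplet (4 or 8),
#' * `t`  — inter-tone interval: semitone distance between adjacent tones
#'   within a triplet (4 or 8),
#' * `c`  — melodic contour within a triplet, ascending (`+1`) or
#'   descending (`-1`).
#'
#' The derived quantity `phi = l + t` is the interval from a dominant tone to
#' the middle tone of its triplet; it is always computed, never stored.
#'
#' @param x0 Root pitch, integer MIDI note number within `root_set`.
#' @param l Inter-level interval in semitones, 4 or 8.
#' @param t Inter-tone interval in semitones, 4 or 8.
#' @param c Contour, `+1` (ascending) or `-1` (descending).
#' @param root_set Admissible root pitches; the default keeps every pitch of
#'   a depth-4 fractal (`x0 + 3*(l+t) + t <= x0 + 56`) inside MIDI range.
#' @return An object of class `rule_params`.
#' @examples
#' rule_params(64, 4, 4, +1)
#' @export
rule_params <- function(x0, l, t, c, root_set = default_root_set()) {
  if (!is.numeric(x0) || length(x0) != 1L || x0 != round(x0))
    stop("x0 must be a single integer MIDI note number")
  if (!l %in% c(4L, 8L)) stop("l must be 4 or 8 semitones")
  if (!t %in% c(4L, 8L)) stop("t must be 4 or 8 semitones")
  if (!c %in% c(-1L, 1L)) stop("c must be +1 (ascending) or -1 (descending)")
  if (!x0 %in% root_set)
    stop("x0 = ", x0, " is not in the configured root-pitch set (",
         paste(root_set, collapse = ", "), ")")
  structure(
    list(x0 = as.integer(x0), l = as.integer(l), t = as.integer(t),
         c = as.integer(c)),
    class = "rule_params"
  )
}

#' Default root-pitch set
#'
#' Four starting tones (E2, G2, A2, B2). Chosen so that the highest pitch of
#' any depth-4 fractal, `x0 + 3*(l + t) + t <= x0 + 56`, stays within MIDI
#' range 0-127.
#'
#' @return Integer vector of four MIDI note numbers.
#' @export
default_root_set <- function() c(40L, 43L, 45L, 47L)

#' @export
print.rule_params <- function(x, ...) {
  cat(sprintf("rule_params: x0=%d  l=%d  t=%d  c=%+d  (phi=%d)\n",
              x$x0, x$l, x$t, x$c, x$l + x$t))
  invisible(x)
}

#' Expand one tone into its subordinate triplet
#'
#' Applies the recursive hierarchical embedding rule to a single pitch:
#' a tone `x` at level n spawns the subordinate triplet
#' `[x - t*c + phi, x + phi, x + t*c + phi]` at level n+1, in temporal order,
#' with `phi = l + t`. For both contours the lowest returned pitch is
#' `x + l`: ascending contour plays low-to-high, descending high-to-low.
#'
#' @param x Integer pitch (MIDI note number) of the dominant tone.
#' @param params A [rule_params] object.
#' @return Integer vector of three pitches in temporal order.
#' @examples
#' p <- rule_params(64, 4, 4, +1)
#' expand_tone(64, p)  # 68 72 76
#' @export
expand_tone <- function(x, params) {
  stopifnot(inherits(params, "rule_params"))
  if (!is.numeric(x) || length(x) != 1L || x != round(x))
    stop("x must be a single integer pitch")
  phi <- params$l + params$t
  as.integer(x + phi + params$t * params$c * c(-1L, 0L, 1L))
}

#' Closed-form pitch of any node in a melodic fractal
#'
#' Independent of the recursive expansion: the node reached from the root by
#' the temporal position path `p_1, ..., p_m` (each `p_i` in 1..3) has pitch
#' `x0 + m*phi + t*c*sum(p_i - 2)`. Used as the algebraic oracle for
#' [build_fractal()].
#'
#' @param params A [rule_params] object.
#' @param position_path Integer vector of temporal positions in `{1,2,3}`
#'   from the root to the node; length 0 (the root) to 3.
#' @return Integer pitch.
#' @examples
#' p <- rule_params(64, 4, 4, +1)
#' node_pitch_closed_form(p, c(3, 3, 3))  # 100
#' @export
node_pitch_closed_form <- function(params, position_path) {
  stopifnot(inherits(params, "rule_params"))
  if (length(position_path) > 3L)
    stop("position_path longer than 3: no node deeper than level 4")
  if (length(position_path) && !all(position_path %in% 1:3))
    stop("position_path entries must be in {1, 2, 3}")
  m <- length(position_path)
  phi <- params$l + params$t
  as.integer(params$x0 + m * phi +
               params$t * params$c * sum(position_path - 2L))
}

## --- fractal tree -----------------------------------------------------------

new_node <- function(pitch, level, path) {
  list(pitch = as.integer(pitch), level = as.integer(level),
       position_path = as.integer(path), children = list())
}

expand_node <- function(node, params) {
  pitches <- expand_tone(node$pitch, params)
  node$children <- lapply(1:3, function(p) {
    new_node(pitches[p], node$level + 1L, c(node$position_path, p))
  })
  node
}

#' Build a complete melodic fractal tree
#'
#' Expands the root pitch recursively to the requested depth. Level k holds
#' `3^(k-1)` nodes; a depth-4 fractal has 40 nodes (1 + 3 + 9 + 27), whose 27
#' terminal tones form 3 clusters of 9.
#'
#' @param params A [rule_params] object.
#' @param depth Number of hierarchical levels, 1 to 4.
#' @return A `fractal_node` tree: nested lists with fields `pitch`, `level`,
#'   `position_path`, `children`.
#' @examples
#' tree <- build_fractal(rule_params(64, 4, 4, +1), 4)
#' count_nodes(tree)  # 40
#' @export
build_fractal <- function(params, depth) {
  stopifnot(inherits(params, "rule_params"))
  if (!depth %in% 1:4) stop("depth must be an integer 1-4")
  grow <- function(node) {
    if (node$level >= depth) return(node)
    node <- expand_node(node, params)
    node$children <- lapply(node$children, grow)
    node
  }
  root <- grow(new_node(params$x0, 1L, integer(0)))
  structure(root, class = "fractal_node")
}

#' Count nodes of a fractal tree
#' @param node A `fractal_node` (or plain nested-list node).
#' @return Integer node count of the subtree rooted at `node`.
#' @export
count_nodes <- function(node) {
  1L + sum(vapply(node$children, count_nodes, integer(1)))
}

#' Flatten a fractal tree to a node table
#'
#' Depth-first, children in temporal order. One row per node with its pitch,
#' level, and position path (as a "p1.p2.p3" string; empty for the root).
#'
#' @param node A `fractal_node`.
#' @return `data.frame` with columns `pitch`, `level`, `path`.
#' @export
flatten_tree <- function(node) {
  rows <- list()
  walk <- function(nd) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pitch = nd$pitch, level = nd$level,
      path = paste(nd$position_path, collapse = "."),
      stringsAsFactors = FALSE)
    for (ch in nd$children) walk(ch)
  }
  walk(node)
  do.call(rbind, rows)
}

#' Serialize a fractal tree to JSON
#'
#' Plain nested-object form (`pitch`, `level`, `children`), re-readable with
#' [tree_from_json()].
#'
#' @param node A `fractal_node`.
#' @param path Optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(node, path = NULL) {
  strip <- function(nd) {
    list(pitch = nd$pitch, level = nd$level,
         children = lapply(nd$children, strip))
  }
  js <- jsonlite::toJSON(strip(node), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a fractal tree from JSON
#' @param x JSON string or path to a JSON file written by [tree_to_json()].
#' @return A `fractal_node` tree (position paths recomputed).
#' @export
tree_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  rebuild <- function(o, level, path) {
    nd <- new_node(o$pitch, level, path)
    nd$children <- lapply(seq_along(o$children), function(i)
      rebuild(o$children[[i]], level + 1L, c(path, i)))
    nd
  }
  structure(rebuild(obj, 1L, integer(0)), class = "fractal_node")
}

# Recompute position paths from tree shape (children order = temporal order).
renumber_paths <- function(node, path = integer(0)) {
  node$position_path <- as.integer(path)
  node$children <- lapply(seq_along(node$children), function(i)
    renumber_paths(node$children[[i]], c(path, i)))
  node
}

#' Test two fractal trees for structural equality
#'
#' Trees are equal when they have the same shape and the same pitch at every
#' node (position paths are recomputed before comparison, so trees built by
#' different routes compare equal when they sound identical).
#'
#' @param a,b `fractal_node` trees.
#' @return Logical scalar.
#' @export
tree_equal <- function(a, b) {
  canon <- function(nd) {
    list(pitch = nd$pitch, children = lapply(nd$children, canon))
  }
  identical(canon(a), canon(b))
}

## --- rule step sequences ----------------------------------------------------

new_step <- function(rule, step, root, params) {
  structure(
    list(rule = rule, step = as.integer(step),
         root = structure(root, class = "fractal_node"), params = params),
    class = "step_structure"
  )
}

#' @export
print.step_structure <- function(x, ...) {
  cat(sprintf("step_structure: rule=%s step=%d nodes=%d (x0=%d l=%d t=%d c=%+d)\n",
              x$rule, x$step, count_nodes(x$root),
              x$params$x0, x$params$l, x$params$t, x$params$c))
  invisible(x)
}

#' Four steps of the recursive rule
#'
#' The recursive rule adds a new hierarchical level at each application step:
#' step k is the complete depth-k fractal, so node counts grow 1, 4, 13, 40.
#'
#' @param params A [rule_params] object.
#' @return List of four `step_structure` objects.
#' @export
steps_recursion <- function(params) {
  lapply(1:4, function(k)
    new_step("recursion", k, build_fractal(params, k), params))
}

#' Four steps of the iterative rule
#'
#' The iterative rule presents the full three-level scaffold from the start
#' and then adds elements within the fixed deepest level: step k consists of
#' levels 1-3 complete plus the first k-1 temporal children of every level-3
#' node (node counts 13, 22, 31, 40). Step 4 is identical, as a tree, to step
#' 4 of the recursive rule over the same parameters — the experiments' central
#' constraint that the final test sound is shared across rules.
#'
#' @param params A [rule_params] object.
#' @return List of four `step_structure` objects.
#' @export
steps_iteration <- function(params) {
  lapply(1:4, function(k) {
    root <- build_fractal(params, 3L)
    n_children <- k - 1L
    add_leaves <- function(node) {
      if (node$level == 3L && n_children > 0L) {
        pitches <- expand_tone(node$pitch, params)
        node$children <- lapply(seq_len(n_children), function(p)
          new_node(pitches[p], 4L, c(node$position_path, p)))
      } else {
        node$children <- lapply(node$children, add_leaves)
      }
      node
    }
    new_step("iteration", k, add_leaves(root), params)
  })
}

#' Four steps of the repetition rule
#'
#' In repetition, steps 1 and 2 are unrelated complete melodic hierarchies
#' (built from the two distractor parameter sets) and steps 3 and 4 are the
#' complete depth-4 fractal of the reference parameters: the correct fourth
#' step is an exact repetition of the third. All four sounds are complete
#' 40-node fractals, so repetition sounds are perceptually as rich as the
#' final stimuli of the other rules.
#'
#' @param reference A [rule_params] object; its fractal is steps 3 and 4.
#' @param distractors List of two [rule_params] objects, pairwise distinct
#'   from each other and from `reference`.
#' @return List of four `step_structure` objects.
#' @export
steps_repetition <- function(reference, distractors) {
  stopifnot(inherits(reference, "rule_params"), length(distractors) == 2L)
  all_p <- c(list(reference), distractors)
  key <- vapply(all_p, function(p)
    paste(p$x0, p$l, p$t, p$c), character(1))
  if (anyDuplicated(key))
    stop("reference and distractor parameter sets must be pairwise distinct")
  roots <- list(build_fractal(distractors[[1]], 4L),
                build_fractal(distractors[[2]], 4L),
                build_fractal(reference, 4L),
                build_fractal(reference, 4L))
  par_by_step <- list(distractors[[1]], distractors[[2]], reference, reference)
  lapply(1:4, function(k)
    new_step("repetition", k, roots[[k]], par_by_step[[k]]))
}

#' Build the four steps of any rule
#'
#' @param rule One of `"recursion"`, `"iteration"`, `"repetition"`.
#' @param params Reference [rule_params].
#' @param distractors For repetition only: list of two distractor
#'   [rule_params].
#' @return List of four `step_structure` objects.
#' @export
build_steps <- function(rule = c("recursion", "iteration", "repetition"),
                        params, distractors = NULL) {
  rule <- match.arg(rule)
  switch(rule,
         recursion  = steps_recursion(params),
         iteration  = steps_iteration(params),
         repetition = {
           if (is.null(distractors))
             stop("repetition requires two distractor parameter sets")
           steps_repetition(params, distractors)
         })
}
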