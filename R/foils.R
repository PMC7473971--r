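#' @title Foil construction
#' @description Foils are incorrect fourth-step sounds. Three categories are
#'   used: *positional* (the contour of every deepest-level triplet is
#'   flipped), *odd* (one tone per deepest-level triplet is misplaced), and
#'   *repeat* (the third step re-played instead of a fourth). Positional and
#'   odd foils permute tones within triplets and therefore never change the
#'   pitch content of the sound, only its temporal structure; in-scanner
#'   designs use positional foils only, so the identical test sounds can be
#'   presented under every rule.
#' @name foils
NULL

#' Foil types
#' @return Character vector of the closed foil-type enumeration.
#' @export
foil_types <- function() c("positional", "odd", "repeat")

assert_complete_step4 <- function(step) {
  stopifnot(inherits(step, "step_structure"))
  if (count_nodes(step$root) != 40L)
    stop("foil construction requires a complete depth-4 structure (40 nodes)")
  invisible(step)
}

map_level3 <- function(step, f) {
  walk <- function(node) {
    if (node$level == 3L) return(f(node))
    node$children <- lapply(node$children, walk)
    node
  }
  root <- renumber_paths(walk(step$root))
  new_step(step$rule, step$step, root, step$params)
}

#' Positional foil: flip the deepest-level contour
#'
#' Reverses the temporal order of every level-4 triplet, i.e. applies contour
#' `c -> -c` at the deepest (newly generated) level only. Levels 1-3 are
#' untouched and the pitch multiset is preserved: the foil differs from the
#' correct sound only in structure. The transformation is an involution.
#'
#' @param correct_step4 A complete depth-4 `step_structure`.
#' @return The foil `step_structure`.
#' @export
foil_positional <- function(correct_step4) {
  assert_complete_step4(correct_step4)
  map_level3(correct_step4, function(node) {
    node$children <- rev(node$children)
    node
  })
}

#' Odd foil: misplace one tone in every deepest-level triplet
#'
#' Swaps one configured pair of temporal positions (default 1 and 2) within
#' every level-4 triplet, breaking within-triplet pitch monotonicity while
#' preserving the pitch multiset.
#'
#' @param correct_step4 A complete depth-4 `step_structure`.
#' @param swap Integer pair of temporal positions to exchange.
#' @return The foil `step_structure`.
#' @export
foil_odd <- function(correct_step4, swap = c(1L, 2L)) {
  assert_complete_step4(correct_step4)
  swap <- as.integer(swap)
  if (length(swap) != 2L || !all(swap %in% 1:3) || swap[1] == swap[2])
    stop("swap must be two distinct positions in {1, 2, 3}")
  map_level3(correct_step4, function(node) {
    node$children[swap] <- node$children[rev(swap)]
    node
  })
}

#' Repeat foil: the third step re-played as the test sound
#'
#' For recursion and iteration, presenting step 3 again instead of a fourth
#' step is a rule violation (the foil's node count betrays it: 13 nodes under
#' recursion, 31 under iteration, vs 40 for the correct sound). Under the
#' repetition rule a re-play of step 3 *is* the correct continuation, so the
#' construction is rejected there.
#'
#' @param steps List of four `step_structure` objects from [build_steps()].
#' @return A `step_structure` carrying the step-3 tree, labelled as step 4.
#' @export
foil_repeat <- function(steps) {
  stopifnot(length(steps) == 4L, inherits(steps[[3]], "step_structure"))
  if (steps[[1]]$rule == "repetition")
    stop("repeat of step 3 is the correct continuation under the repetition rule, not a foil")
  s3 <- steps[[3]]
  new_step(s3$rule, 4L, s3$root, s3$params)
}

#' Build the foil of a given type for a rule's step set
#'
#' @param steps List of four `step_structure` objects.
#' @param type One of [foil_types()].
#' @param ... Passed to the specific constructor (e.g. `swap` for odd foils).
#' @return The foil `step_structure`.
#' @export
make_foil <- function(steps, type = c("positional", "odd", "repeat"), ...) {
  type <- match.arg(type)
  switch(type,
         positional = foil_positional(steps[[4]], ...),
         odd        = foil_odd(steps[[4]], ...),
         `repeat`   = foil_repeat(steps))
}

#' Classify a candidate test sound against a reference step set
#'
#' Round-trip validator: reconstructs the correct fourth step and each foil
#' from the reference steps and returns the unique label whose constructor
#' reproduces the candidate tree, or `"other"` when none matches.
#'
#' @param reference_steps List of four `step_structure` objects.
#' @param candidate A `step_structure` to classify.
#' @param swap Odd-foil position pair used when reconstructing the odd foil.
#' @return One of `"correct"`, `"positional"`, `"odd"`, `"repeat"`, `"other"`.
#' @export
classify_test_sound <- function(reference_steps, candidate, swap = c(1L, 2L)) {
  stopifnot(length(reference_steps) == 4L,
            inherits(candidate, "step_structure"))
  correct <- reference_steps[[4]]
  if (tree_equal(candidate$root, correct$root)) return("correct")
  if (tree_equal(candidate$root, foil_positional(correct)$root))
    return("positional")
  if (tree_equal(candidate$root, foil_odd(correct, swap)$root))
    return("odd")
  if (reference_steps[[1]]$rule != "repetition" &&
      tree_equal(candidate$root, reference_steps[[3]]$root))
    return("repeat")
  "other"
}
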