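---
title: "Melodic fractals: generative model, trial design, and the simulated responder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melodic fractals: generative model, trial design, and the simulated responder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melofractal)
```

## The generative model

melofractal builds auditory stimuli for experiments on hierarchical cognition
in the melodic domain. The core object is a *melodic fractal*: a rooted tree
of tones in which every dominant tone governs a triplet of higher-pitched,
shorter subordinate tones, with the same pitch relations at every level. A
single recursive hierarchical embedding rule generates the whole structure.
Writing $x$ for a tone's pitch (integer MIDI note number) and $\phi = l + t$,

$$(x)_n \rightarrow \big[(x)_n\; [(x - tc + \phi)_{n+1},\,
(x + \phi)_{n+1},\, (x + tc + \phi)_{n+1}]\big]$$

with three interval parameters:

* **inter-level interval** $l \in \{4, 8\}$ semitones — distance from a
  dominant tone to the lowest tone of its triplet (a major third or minor
  sixth, intervals chosen to avoid dissonance when levels sound together);
* **inter-tone interval** $t \in \{4, 8\}$ semitones — distance between
  adjacent tones within a triplet;
* **contour** $c \in \{-1, +1\}$ — whether a triplet plays low-to-high
  (ascending) or high-to-low (descending).

For either contour the lowest tone of a triplet sits exactly $l$ above its
parent ($x - t + \phi = x + l$), which is why $l$ and not $\phi$ is the
perceptually meaningful inter-level distance. The tree bottoms out at four
levels: 1 + 3 + 9 + 27 = 40 tones, whose 27 terminals group into 3 clusters
of 9.

Every node pitch also has a closed form. The node reached from the root by
temporal positions $p_1, \dots, p_m$ (each in $\{1,2,3\}$) has pitch

$$x_0 + m\phi + tc \sum_i (p_i - 2),$$

which the test suite uses as an algebraic oracle against the recursive
expansion, exhaustively over the whole stimulus pool. (A consequence worth
noting: the extreme pitch of a depth-4 tree is $x_0 + 3\phi + 3t$, reached
when all three positions pull in the same direction.)

Three **rules** present the same final structure through different histories:

* *Recursion*: step $k$ is the complete depth-$k$ fractal (1, 4, 13, 40
  nodes) — each step adds a new hierarchical level.
* *Iteration*: the full three-level scaffold is present from step 1; each
  step adds one more temporal child to every level-3 node (13, 22, 31, 40
  nodes) — elements accumulate within a fixed level.
* *Repetition*: steps 1 and 2 are unrelated complete fractals; steps 3 and 4
  are the reference fractal — the correct fourth step is an exact re-play.

The central design constraint is that **step 4 is tree-identical across
rules** for matched parameters, so any difference in how listeners process
the final sound reflects how it was generated, not what it sounds like. The
package asserts this by byte-comparing serialized note tables.

The stimulus **pool** crosses $l \times t \times c$ (8 combinations) with
four root pitches, default $x_0 \in \{40, 43, 45, 47\}$ (E2, G2, A2, B2):
32 distinct fractals. The roots are a package choice — the source design
names four starting tones without printing them — picked as distinct pitch
classes in a low register so that every derived pitch (max $47 + 48 + 24 =
119$) stays inside MIDI range.

The exact content of iterative steps 1–3 and of the two unrelated repetition
hierarchies is likewise underdetermined by the published description. The
defaults here (three-level scaffold filled one child per step; two distinct
pool members as distractors) satisfy the two constraints that are stated:
the shared step-4 sound, and early iteration/repetition steps carrying more
items and levels than recursion's. Both choices are configurable.

## Foils

A foil is an incorrect fourth step. Three categories:

* **positional** — every deepest-level triplet is reversed in time (contour
  $c \to -c$ at the new level only). Levels 1–3 are untouched; the pitch
  multiset is preserved; the transform is an involution.
* **odd** — one configured pair of temporal positions (default 1↔2) is
  swapped within every deepest-level triplet, misplacing exactly one tone per
  triplet and breaking within-triplet monotonicity. "Misplaced" is
  operationalized as a single swap because only the salience of the violation
  is described, not its permutation; the pair is a parameter.
* **repeat** — step 3 re-played in place of step 4. Under the repetition rule
  this is the correct continuation, so the constructor refuses it there.

Positional foils flip the *deepest* level only, uniformly across rules: the
violation is defined from the third to the fourth step, and already-heard
levels must stay intact. In-scanner designs use positional foils exclusively
(the repeat foil sounds different under recursion vs iteration, and the odd
foil is easy to detect), which is what keeps test sounds identical across
rules; `validate_plan()` enforces it. `classify_test_sound()` inverts the
constructors and is round-trip tested over the pool.

## Timing model

All sounds live on one fixed grid of 27 terminal slots (3 clusters × 3
triplets × 3 tones) with a pause hierarchy: `g1` within triplets < `g2`
between triplets ≤ `g3` between clusters. Every tone spans exactly the
temporal extent of its subtree (*subtree-span model*), so dominant tones
sound simultaneously with, and throughout, their subordinates — levels are
added cumulatively in the sound. A tone's slots derive from its position
path, so partial structures (early iteration steps) keep each tone where it
sits in the complete sound and every step occupies the same envelope;
recursion step 1 is a single tone spanning the whole grid.

The published description fixes three timing facts — total sound 7.4 s,
first cluster 2.4 s, between-cluster pauses longer than within — but not the
individual tone and pause values. The defaults solve those constraints
exactly:

| parameter | default | role |
|---|---|---|
| `leaf_tone_dur` | 0.22 s | terminal tone |
| `g1` | 0.04 s | pause within triplet |
| `g2` | 0.09 s | pause between triplets |
| `g3` | 0.10 s | pause between clusters |
| `cue_dur` | 0.84 s | visual rule cue |
| `inter_step_gap` | 1.00 s | silence after steps 1–3 |

giving triplet span $3(0.22) + 2(0.04) = 0.74$ s, cluster span $3(0.74) +
2(0.09) = 2.4$ s, total $3(2.4) + 2(0.10) = 7.4$ s, and a leaf/parent
duration ratio of $0.22/0.74 \approx 0.30$ — "approximately 1/3". The trial
prior phase (cue through end of step 3, including the gap after each step)
is $0.84 + 3(7.4 + 1.0) = 26.04$ s. `cue_dur` and `inter_step_gap` are
solved jointly from that total; they are not individually attested.

Rendering: format-1 MIDI, one track per level, 960 PPQ at 120 bpm (tick ≈
0.52 ms, so boundaries are exact to under 1 ms; the round trip is tested
against a matching reader). WAV is additive sine synthesis at equal
temperament (A4 = 440 Hz), per-level gains summing below 1 so a sustained
four-level stack cannot clip (clipping raises an error rather than being
silently limited), 10 ms raised-cosine ramps, 16-bit PCM or float32. Sample
counts are `ceiling(span × rate)` with a $10^{-6}$ guard against
floating-point noise in the span sum. A leaves-only render mode exists for
inspection; with sustained dominants the root tone fills the pauses, so
silent-gap checks apply to the leaves-only mode.

## Trial design

Each of 4 sessions holds 18 trials, 6 per rule. Per rule across the full
plan (24 trials): 12 correct / 12 positional foils, 12 ascending / 12
descending, 12 interval-8 / 12 interval-4 with 6 correct and 6 foils inside
each interval class. By default `t` and `l` are yoked (`t = l`), matching
the printed 12/12 interval split; a non-yoked mode balances `l` and `t`
marginally with all 8 parameter combinations appearing equally often.

The balancing works by dealing each rule × correctness group (4 contour ×
interval cells × 3 replicates) cyclically across sessions, with the foil
cycle offset by two cells from the correct cycle. A session's 3 correct and
3 foil trials per rule then cover complementary cells, which makes contour
come out exactly 3/3 per session × rule. An exact 3/3 contour split *within*
a session × rule × correctness cell is impossible (3 trials), so the stricter
reading of the balancing description is satisfied at the session × rule level
and exactly 6/6 within rule × correctness across sessions.

Generation-phase jitter is seeded uniform on a 0.5 s grid over [2, 4] s.
The original experiment optimized its trial sequence with Optseq2; sequence
optimization is deliberately out of scope here, and a seeded uniform draw
with pseudorandom trial order stands in its place. The decision phase is
response-terminated with a 5 s cap; event files carry the 5 s cap as its
scheduled duration. Between trials a fixed 2 s interval is inserted (a
package default; the source design's inter-trial timing was part of the
Optseq2 schedule).

`export_events_tsv()` writes one BIDS-style `events.tsv` per session with
the five modelled phases per trial — prior (26.04 s), generation (jitter),
test_part1 (2.4 s, the first cluster, where a violation is already
detectable), test_part2 (5.0 s), decision — 90 rows per session.

A pretesting variant, `make_2afc_block()`, builds two-alternative
forced-choice blocks (default 12 recursion + 12 iteration trials) pairing
the correct step 4 with one foil from a configurable mix of all three
categories, in seeded random presentation order.

All randomness flows from one global seed through `split_seed()`, a fixed
affine map to per-stage child seeds (plan, jitter, trial order, distractors,
responses), so stages are independently reproducible and two runs with the
same configuration produce byte-identical bundles (`run_pipeline()` writes
an MD5 manifest and the tests compare manifests).

## The simulated responder

`simulate_responses()` emulates button presses under equal-variance signal
detection: evidence $\sim N(d'_{\text{rule}}, 1)$ on correct trials and
$N(0, 1)$ on foils, with a "correct" judgement when evidence exceeds
$d'/2 + c$. The criterion $c$ is the standard bias measure: at $c = 0$ the
responder is unbiased, with hit rate $\Phi(d'/2)$, false-alarm rate
$\Phi(-d'/2)$, chance accuracy at $d' = 0$, and accuracy approaching 1 as
$d'$ grows. (A threshold fixed at 0 instead of the midpoint would pin the
false-alarm rate at 0.5 and cap accuracy at 0.75, which is why the midpoint
convention is the one implemented.) Response times are lognormal per rule
with a 5 s cap.

Default sensitivities ($d'$ = 1.06 recursion, 0.88 iteration, 1.31
repetition) and RT medians (0.78 / 0.74 / 0.58 s) sit where trained
non-musicians perform on this paradigm. They are descriptive defaults for
producing realistic synthetic data — the simulator makes no claim to
reproduce any particular observed sample, and observed human scores are not
test targets.

Analysis mirrors standard practice: `compute_dprime()` uses
$d' = z(H) - z(F)$ with a log-linear correction for extreme rates (add 0.5
to each count, 1 to each N; the published analysis does not state its
correction, so the common log-linear rule is the default and a $1/(2N)$
adjustment is available). `rm_anova_oneway()` is a one-way repeated-measures
ANOVA computed from sums of squares with subject blocking — with 15 subjects
and 3 rules, $F(2, 28)$ — cross-checked in the tests against
`stats::aov(y ~ cond + Error(subj))`. Post-hoc pairwise comparisons use
paired t tests with a configurable adjustment (default Holm); the published
pairwise procedure is not fully specified, so no particular p-values are
asserted for it.

## What the tests establish (and what they do not)

The suite verifies, among other properties: oracle equivalence of recursive
expansion and the closed form over all 32 × 40 nodes; byte-identity of
recursion and iteration step-4 note tables pool-wide; foil classification
round trips; plan invariants over 100 seeds; MIDI/WAV round trips; d′
recovery within ±0.1 of generative values (15 subjects × 24 trials per rule
× 200 replicates); and a type-I error of 0.05 ± 0.01 for the RM-ANOVA over
5,000 null simulations with 15 subjects. These sizes are the package's
verification scale — large enough that Monte-Carlo error is well inside the
asserted tolerances, small enough to run routinely.

The simulator produces idealized observers: independent trials, stationary
sensitivity, no lapses, fatigue, learning, or sequential effects, and RTs
independent of evidence strength. Passing recovery tests therefore shows the
estimation pipeline is correct, not that real participants behave this way.
Likewise the stimuli are exact sine-tone realizations; no claims are made
about timbre, loudness perception, or scanner acoustics.

## Known limitations

* Depth is fixed at 4 levels and branching at 3; the grammar does not extend
  to other arities or microtonal intervals.
* The balancing scheme is specific to 4 sessions (the cyclic dealing assumes
  a 4-cell cycle).
* No design-efficiency optimization of trial sequences or jitter.
* `read_midi()` parses the subset of SMF the package writes (plus running
  status); it is a verification tool, not a general MIDI importer.
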