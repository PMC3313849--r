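---
title: "CpG island search: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CpG island search: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CpGscout)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It covers the composition model, the
deterministic extractor, the stochastic searches and their complementary
restart, the synthetic-genome generator, and the numerical and design
choices that were genuinely open.

## Composition model

Every statistic reduces to four prefix-count arrays built in one pass over
the sequence (`buildIndex()`): counts of C, of G, of valid (unambiguous
A/C/G/T) bases, and of CpG dinucleotides. Any interval `[s, e)` then
yields, in constant time,

* GC content `100 (N_C + N_G) / L_valid`, and
* the CpG observed/expected ratio `N_CpG · L_valid / (N_C · N_G)` —
  observed CpG count over its expectation under base independence.

Three conventions matter and are applied everywhere:

* **Coordinates** are 0-based half-open internally; BED and bedGraph
  emit them unchanged, GFF3 converts to 1-based closed on write. A single
  internal convention is the cheapest insurance against off-by-one drift.
* **Ambiguity codes** are accepted on input but treated as N downstream:
  they are excluded from both numerator and denominator of GC% and from
  `L` in O/E, and a CpG spanning an ambiguous base is not counted. Masked
  assembly gaps therefore neither inflate island lengths nor dilute
  composition.
* **Degenerate denominators** return 0 rather than failing: an interval
  with no C or no G has O/E 0, which can never meet a threshold, and the
  stochastic searches must be free to score arbitrary candidates.

O/E is invariant under reverse complement (CpG is its own reverse
complement), so a single-strand scan is complete; the tests assert this
exactly.

## Island criteria

`IslandCriteria` bundles the three thresholds plus the merge gap. All
thresholds are inclusive (`>=`); the island-definition literature mixes
strict and inclusive wording, and the inclusive reading is taken as
operative, exposed as presets:

| preset | min length | min GC% | min O/E | merge gap |
|--------|-----------:|--------:|--------:|----------:|
| `ggf`  | 200 bp     | 50      | 0.6     | 100 bp    |
| `tj`   | 500 bp     | 55      | 0.65    | 100 bp    |

The stricter `tj` parameterization exists to exclude short interspersed
repeats (Alu) that satisfy the classical thresholds.

## The sliding-window extractor

`slidingWindowSearch()` scans a 200 bp window in 1 bp steps. When a window
meets the GC and O/E thresholds it extends rightward one whole window at a
time while each *added window* still meets them, then trims the extended
interval one base at a time — removing from whichever end most improves
the limiting margin `min(GC/minGC, OE/minOE)`, left first on ties — until
the whole interval meets both thresholds. The interval is kept if its
final length reaches the minimum; scanning resumes after it. Finally,
islands separated by less than the merge gap are fused when the spanning
interval still qualifies, iterating the left-to-right merge pass until
nothing changes so that merging is idempotent.

Two guard rules handle assembly gaps: an island containing a run of 50 or
more consecutive ambiguous bases is split at the run, and a merge is
refused when the gap between two islands contains such a run — otherwise
the merge would silently re-bridge exactly what the split separated. Both
rules are this package's choice; the window/step/trim granularities are
flags, not constants, because the classical extractor family varies on
these details.

## Fitness and the stochastic searches

`searchIslands()` treats island discovery as optimization of a candidate
`(start, length)` inside a segment. The encoding keeps the minimum-length
constraint a simple box bound. The fitness is:

* **feasible** candidate (meets all criteria): score = length, so the
  search prefers the longest valid island reachable — consistent with
  judging island callers by total predicted length and coverage;
* **infeasible** candidate: score =
  `min(length, minLength) · min(GC/minGC, 1)² · min(OE/minOE, 1)²`.

The cap on the infeasible length factor is essential and was adopted after
the uncapped form failed in an instructive way: on a realistic 10 kb
segment (CpG-depleted background plus two islands) the *whole segment* has
GC ≈ 47 % and O/E ≈ 0.55, so an uncapped infeasible score
`length · 0.89 · 0.83 ≈ 5800` beats every feasible island (≈ 2900) and the
search converges to an infeasible candidate. With the cap, every feasible
candidate strictly dominates every infeasible one, while the composition
ramp still pulls infeasible candidates toward CpG-rich ground.

A consequence worth knowing: because feasible fitness is length, the
optimum is the *longest* qualifying interval around an island, which
legitimately annexes background flank until GC or O/E hits its threshold
(the emitted islands often have GC exactly at 50 %). This raises
sensitivity and total predicted length at the cost of nucleotide-level
precision — the same trade the swarm/genetic approach exhibits against
window methods at chromosome scale.

**PSO** uses the standard update
`v ← w v + c1 r1 (pbest − x) + c2 r2 (gbest − x)`, `x ← x + v`, with
velocities clamped to ±`vMax` and positions to the box. **GA** applies
binary tournament selection (k = 2), single-point crossover on the
concatenated bit encoding of `(start, length)`, per-bit mutation, and
elitism; decoded positions re-clamp to the box. Defaults (population 40,
200 generations, inertia 0.9 → 0.4 linear, c1 = c2 = 2,
vMax = segment/10, crossover 0.8, mutation 0.01, 2 elites) are the
conventional mid-range settings for these operators; elitism ≥ 1
guarantees the best-so-far fitness is non-decreasing, which the tests
assert. A seed is required — there is no silent default, and identical
configuration plus input reproduces byte-identical output.

### Complementary restart

Stagnation is counted as consecutive generations with no improvement of
the best fitness (exact comparison; feasible fitness is integral). After
five stagnant generations — the limit is configurable — the complementary
variants replace the worse half of the population, never the current best
members, by each member's reflection across the box,
`x′ = lo + hi − x` per coordinate. The reflection maps the box onto
itself, so it is an exact involution; keeping the best members preserves
the monotonicity guarantee, and replaced particles restart with zero
velocity and a reset personal best. The box is deliberately kept a pure
box (candidates may overhang the segment end and are clipped only at
evaluation) precisely so the reflection needs no clamping.

Which members to replace, and whether personal bests reset, are genuinely
open choices; replacing the worse half and resetting were chosen because
they leave the incumbent solution intact while relocating the stagnant
mass to the unexplored side — on a constructed two-peak landscape (a small
qualifying block near the start, a larger one far away, swarm initialized
near the small one) plain PSO reaches the larger peak in 0 of 20 seeded
runs, CPSO in 20 of 20.

### Segment driver

Long sequences are tiled into 10 kb segments with 1 kb overlap. Per
segment the search runs, records the best candidate when feasible, masks
its bases by rewriting them to `A` in the segment-local copy (they then
score as CpG-free ground; the whole-sequence index is never touched) and
repeats, up to 10 islands per segment. Because candidates are scored on
fully contained dinucleotides only, a candidate that does not overlap a
mask has identical statistics on the masked and true sequence. Pooled
islands are de-duplicated across segment overlaps (longer wins, leftmost
on ties), split at ambiguity runs, re-checked against the criteria on the
unmasked index, and gap-merged. The 1 kb overlap means any island up to
1 kb lies wholly inside at least one segment; longer islands straddling a
boundary may be recovered piecewise and merged.

## Synthetic genomes

`generateGenome()` emulates the contrast the criteria detect: a
CpG-depleted background (defaults GC 40 %, O/E 0.2 — bulk vertebrate DNA
is CpG-poor from methyl-CpG deamination) with planted islands (GC 60 %,
O/E 0.8, 300–1500 bp, ≥ 500 bp apart). Sequences come from a first-order
Markov chain with stationary base probabilities
`p_C = p_G = gc/200` and `P(G|C) = oe · p_G` — under this model
`O/E = P(G|C)/p_G`, so both targets are controlled independently. The
remaining C-row mass is spread over A/C/T proportionally to their
stationary probabilities; the A/G/T rows are the unique shared row that
makes the stationary distribution *exactly* the target composition
(i.i.d. rows would drag realized GC% about two points below target at the
background settings). At `oe = 1` the chain reduces to the i.i.d. model;
at `oe = 0` the sequence contains no CpG at all. Realized statistics at
100 kb land within ±1 GC point and ±0.05 O/E of target, which the
acceptance tests assert.

The chain restarts at every island/background boundary, so the planted
truth coordinates are exact by construction; one junction dinucleotide per
boundary is left to chance. Placement is uniform rejection sampling under
the minimum-gap constraint (up to 1000 attempts before refusing).

What the generator does *not* emulate: isochore-scale GC structure, repeat
families (Alu), methylation state, and real chromosomal island-length
distributions. Tests passing on these genomes show that the machinery
finds the programmed contrast; they do not certify performance on real
chromosomes, where the benchmark-table arithmetic in
`inst/extdata/` is the only contact with real data.

## Problem sizes used by the test and acceptance suites

Deliberate choices, recorded here as the package's own: the planted-island
recovery runs use the generator's default 50 kb genome with ten islands
(seed 42); the extractor-vs-oracle sweep uses 200 seeded 2 kb genomes with
one island each (the oracle is O(n²)); generator calibration uses 100 kb;
the two-peak landscape is 5.5 kb with 20 seeds per algorithm. At these
sizes the whole suite runs in minutes on one core.

## Known limitations

* **The exhaustive oracle is not the extractor's fixpoint.** The oracle
  reports, at the leftmost qualifying start, the *longest* interval
  meeting all criteria. At the default synthetic contrast a qualifying
  interval may annex diluting background flank of roughly the island's own
  length before GC% crosses below 50 (O/E binds even later), so oracle
  intervals systematically overhang true islands on the left, while the
  window extractor by design stops within about one window of the island
  edge. Measured nucleotide recall of the extractor against the oracle is
  therefore ≈ 0.55 at default contrast — both algorithms behaving exactly
  as specified — and the corresponding acceptance check documents this gap
  rather than papering over it. Against *planted truth*, where the
  question is "did we find the island", the extractor's sensitivity is
  ≈ 0.97.
* The length-maximizing fitness overpredicts island boundaries (high SN,
  lower PPV), as discussed above.
* The GA bit encoding clamps decoded values to the box, which slightly
  biases mutation toward the upper bound; harmless in practice but visible
  in the operator's stationary distribution.
* The evaluation module is annotation-agnostic: it compares any two
  interval sets at nucleotide resolution and does not ship a reference
  island annotation.

## Session info

```{r}
sessionInfo()
```
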