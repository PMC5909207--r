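---
title: "Segment overlap scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment overlap scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sovscore)
```

## The problem

Two equal-length strings over a single-character state alphabet — a
reference segmentation and a predicted one — must be compared in a way
that values *contiguity*. Per-position accuracy (`q_score`; Q3/Q8 in the
secondary-structure literature) treats every position independently, so a
prediction that scatters isolated correct positions can outscore one that
recovers a whole segment with slightly misplaced edges. Segment overlap
(SOV) scores instead decompose both sequences into maximal runs and score
overlapping same-state run pairs, granting each pair a bounded boundary
*allowance* δ.

## The scoring model

For each state $i$ present in the reference, with $S(i)$ the set of
overlapping reference/predicted segment pairs of that state and $S'(i)$
the reference segments of state $i$ overlapped by nothing,

$$SOV(i) = \frac{1}{N(i)} \sum_{S(i)}
  \frac{minov(s_1,s_2) + \delta(s_1,s_2)}{maxov(s_1,s_2)}\, len(s_1),
\qquad
N(i) = \sum_{S(i)} len(s_1) + \sum_{S'(i)} len(s_1),$$

and the overall score is $\sum_i SOV(i) N(i) / \sum_i N(i)$. $minov$ and
$maxov$ are the intersection and union sizes of the two segments'
position sets. A reference segment overlapped by $k$ predicted segments
contributes $len(s_1)$ to both the numerator-side terms and $N(i)$ $k$
times; this multiplicity is what penalizes fragmented predictions, and it
also means $\sum_i N(i)$ can exceed the sequence length (equality holds
exactly when no reference segment is split across several predictions —
the tiling-conservation property in the test suite).

The two variants differ only in δ:

* **SOV'99**: $\delta = \min(maxov-minov,\; minov,\;
  \lfloor len(s_1)/2 \rfloor,\; \lfloor len(s_2)/2 \rfloor)$ —
  an integer local to the pair. Because the $minov$ term caps it, the
  allowance can stall as a predicted segment grows, so a strictly better
  prediction does not always earn a larger bonus.
* **SOV_refine**: the reference sequence as a whole carries a budget
  $$\delta(all) = \lambda\,\frac{N_C}{\sum_{j=1}^{N_S}
    \left(len(s_j)/len(s_r)\right)^2},$$
  with $N_C$ the number of distinct states *occurring in the reference*
  and the sum over all its segments: more states and more fragmentation
  (many boundaries) mean a harder prediction task and a larger budget.
  Each pair draws
  $\delta = \delta(all)\cdot \frac{len(s_1)}{len(s_r)}\cdot
  \frac{minov}{maxov}$, clamped to $maxov - minov$. The $minov/maxov$
  factor makes the allowance grow with every additional correct
  position, which is the defining behaviour: on the graded benchmark
  series in `worked_examples()` the refined score's increments are
  strictly increasing while SOV'99's are erratic.

Both scores are in $[0,1]$, equal 1 exactly on identity, and are
deliberately asymmetric in (reference, prediction) — the reference owns
the normalization and the budget.

### Reading of $N_C$

The budget formula's "number of states" could mean the nominal alphabet
size (e.g. always 3 for H/E/C). This package counts the distinct states
actually occurring in the reference: a reference without strands is a
two-state problem regardless of notation. This reading reproduces every
published benchmark cell for the two-state-occupancy reference
`CHHHHHHHHHHC`; the nominal reading does not.

## Tunable parameters

* **`lambda`** (SOV_refine, default 1, any positive real): linear scale
  on the budget, hence a stringency dial — smaller is stricter, and the
  score is non-decreasing in λ (clamping only flattens the growth). The
  default 1 is the conventional operating point for secondary-structure
  assessment; λ = 0.1–0.5 separates near-perfect predictions that
  saturate at λ = 1.
* **`step`** (`sliding_best_score`, default 1): offset increment when a
  shorter sequence is scanned along a longer one. Step 1 (gapless) is
  exact; coarser steps (e.g. 20 residues) are a speed/resolution
  trade-off for large all-vs-all screens. Windows that would overrun the
  end are skipped; ties report the first maximizing offset. The shorter
  sequence plays the reference role in every window comparison.
* **`bin_size`** (`intervals_to_states`): resolution at which interval
  calls (e.g. TADs, in bp) are discretized into state strings. Bin
  membership is decided by the bin midpoint — with half-open intervals a
  midpoint can never sit ambiguously on an edge, making the conversion
  deterministic; fractional-overlap thresholds would add a parameter
  without changing any well-separated call.

## Numerical and degenerate-input choices

* The clamp is applied per pair, before the $SOV(i)$ sum; a pair with
  $minov = maxov$ (exact match) gets δ = 0, so no term exceeds
  $len(s_1)$ and scores cannot exceed 1.
* Library functions return full doubles. Display (CLI TSV, `print`)
  rounds half-away-from-zero at 3 decimals by default (`--precision`
  changes display only); base `round()` rounds half to even, which would
  misreport values like 0.9375 against 3-decimal published tables.
* States present only in the prediction are never scored directly (a
  pair needs a reference segment); they act by truncating overlaps.
  States in the reference but missing from the prediction contribute
  $SOV(i) = 0$ at full $N(i)$ weight. A state with no reference
  occurrence is skipped entirely — no 0/0.
* Equal-length input is enforced with a hard error naming both lengths;
  `sliding_best_score` is the sanctioned unequal-length path. Empty
  sequences and non-single-character labels are rejected; whitespace is
  stripped; labels are case-sensitive and unrestricted.
* A reference with more than 10 distinct states triggers a warning (on
  the message channel, not the result stream): with many states,
  segment-overlap scores lose discriminative value and per-position
  accuracy is the better tool.
* Coordinates are 0-based half-open throughout, including BED input and
  reported sliding offsets.

## The random-pair generator

`random_state_sequence` draws segment lengths geometrically (the
memoryless run-length model — the simplest generator whose mean run
length is a single parameter) and forbids consecutive equal states so
runs are maximal by construction. Defaults (3 states, mean run 6) mimic
the gross statistics of three-state secondary structure; 2 states with
long runs mimic TAD body/boundary strings. `random_pair` perturbs a
reference by boundary shifts (edge disagreement), segment splits
(spurious short calls) or segment relabelling (misclassification), with
one intensity knob; intensity 0 is the identity and one integer seed
fully determines a pair without touching the caller's RNG state.

What the generator does *not* emulate: real secondary-structure
transition statistics (no state-dependent run lengths, no H/E/C
grammar), correlated errors from actual predictors, or Hi-C-derived TAD
calls. Passing property tests on this corpus therefore demonstrates the
*mathematical* invariants (range, identity, λ-monotonicity, tiling
conservation, oracle agreement) across segmentation regimes, not
performance claims about any real predictor.

## Verification strategy and problem sizes

The test suite recomputes all 44 published benchmark cells (eight
three-state predictions × 3 scores; four four-state predictions × 5
scores, λ ∈ {1, 0.5, 0.1}) at 3 decimals, and checks the implementation
against an independent brute-force oracle — a literal transcription of
the definitions using explicit position-set intersections and unions,
sharing no code with the segment-table implementation — to 10⁻¹² on
1000 seeded random pairs spanning alphabets of 2–8 states and lengths
5–200, with mixed run-length regimes, perturbation kinds and λ drawn
from [0.1, 2.4]. Property checks (identity, range, monotonicity, tiling)
run on a further 300-pair corpus; distributional checks on the generator
use 200 replicates per intensity level. The whole suite completes in
about a minute on one CPU.

## Known limitations

* Scores compare two already-called segmentations; the package neither
  assigns secondary structure (DSSP/STRIDE) nor calls TADs, and performs
  no 8→3-state reduction.
* The sliding-window reduction takes a maximum over ungapped windows; it
  is not an alignment, and for very different lengths the best window
  can be optimistic.
* SOV scores on alphabets larger than ~10 states are discouraged (see
  the warning above); the math still works but the per-state
  decomposition becomes sparse and noisy.
* One invocation scores one pair; batch screens are left to shell loops
  or R scripting around `score_pair`.
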