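---
title: "Detecting internal repeats in protein embeddings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internal repeats in protein embeddings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embrep)
```

# The problem

Tandem repeats — adjacent copies of a duplicated segment — are pervasive in
proteins, but the copies diverge over evolutionary time until sequence-level
similarity is hard to detect. Self-sequence alignment (SSA) addresses this by
aligning a protein against itself: off-diagonal suboptimal alignments reveal
internal duplication. `embrep` performs SSA in *embedding space*: every
residue is represented by a fixed-width numeric vector (from a protein
language model, or any residue-wise embedder), and the cosine similarity
between residue vectors serves as a context-dependent substitution score.
This captures similarity that has drifted beyond recognisability in the
amino-acid alphabet.

# The detection pipeline

For an embedding $E \in \mathbb{R}^{L \times D}$ the pipeline is:

1. **Self-similarity.** $S_{ij} = \cos(E_i, E_j)$. Cosine is scale-invariant,
   so row normalisation of the embedder is irrelevant; no centering is
   applied.
2. **Suboptimal self-alignment.** A local alignment landscape is computed
   over $S$ (details below) and all significant suboptimal traces are
   collected. A trace is an ordered set of aligned index pairs with a score.
3. **Transitivity.** If $i$ aligns to $j$ in one trace and $j$ to $k$ in
   another, $(i,k)$ is inferred in a composed trace; composites are scored
   from $S$ like any trace, must pass the same filters, and are never
   composed again (one round).
4. **Score matrix.** $M_s[i,j]$ accumulates the scores of all traces whose
   alignment contains the pair $(i,j)$ (mirrored into both triangles).
5. **Length estimation.** For each distance $d \in [1, \lfloor L/2 \rfloor]$
   the upper-triangle cells at $|i-j| = d$ are summed; positive-sum
   distances are candidate unit lengths, ranked by their sums. Periodic
   signal concentrates at multiples of the unit length, so the fundamental
   dominates.
6. **Representative localisation.** An $l$-column sliding window is scored
   as $\sum_i \sum_p w(p)\, M_s[i, c+p-1]$ with the symmetric triangle
   weights $w(p) = \min(p, l-p+1) - \tfrac12$, reflecting that repeat
   middles are better conserved than their indel-prone boundaries. The
   maximising window start (leftmost on ties) is the representative repeat.
7. **Weighted embedding.** The representative's profile embedding is
   $E_{\mathrm{rep}} = M_{sw}^{\top} E$, the score-matrix columns under the
   window weighting the full-length rows — the embedding analogue of
   building a profile from an MSA column. Zero-weight columns fall back to
   the raw embedding row (cosine scoring makes overall scale irrelevant).
8. **Instance extraction.** The profile is locally aligned against the
   full-length embedding; candidate spans are resolved greedily by
   descending score with pairwise overlap at most half of the shorter span,
   and each accepted span is globally aligned (Needleman–Wunsch on cosine)
   to the representative for its alignment, score and coverage. Pairwise
   alignments are stitched into an A2M multiple alignment (uppercase match,
   lowercase insert, `-` deletion).
9. **Hypothesis selection and masking.** Each candidate length yields a
   hypothesis; the best one is reported as a repeat family, its residues are
   masked out of $M_s$ (rows and columns zeroed), and steps 5–8 repeat until
   nothing remains, no hypothesis has two instances, or `max_iterations`
   (default 5) is reached.

# The alignment landscape: why the gap model matters

The committed local aligner is Smith–Waterman with a *bounded affine* gap
model: a gap run of $g$ steps costs `gap_open` $+ (g-1)\cdot$
`gap_extension` and may be at most `window_length %/% 2` steps long.
Defaults: `gap_open = 1.0` (about one strong aligned pair), `gap_extension
= 0.0`.

This combination is load-bearing, and we document the failure modes that
motivate it because they are instructive:

* With *free unbounded* gaps the landscape is monotone non-decreasing, so
  the single best alignment band's prefix dominates everywhere: no other
  suboptimal band can be traced back at all, and 3×3 local maxima of the
  landscape degenerate into global plateaus. Suboptimal alignments — the
  whole point of SSA — become unreachable.
* With a positive opening cost but *unbounded free extension*, a one-residue
  indel costs exactly as much as a hop across the entire matrix, so the
  optimal path switches to a parallel band instead of bridging an indel,
  fragmenting true-period instances.
* Bounding the gap length by the smoothing half-window closes the loop: a
  jump wider than the scoring window is not an alignment gap but a change of
  alignment band, which is exactly where traceback paths are split during
  segmentation.

**Trace extraction.** Every positive cell is assigned a deterministic
predecessor (tie order: diagonal move realising an aligned pair with
positive similarity, then gap over rows, then gap over columns, then a
zero-contribution diagonal). Tracebacks are started at the end of every
maximal diagonal run — a tractable realisation of "trace back from all
positions", since every other traceback is a prefix of one of these. Each
path is split into jump-free pieces; within a piece the per-pair
similarities are smoothed with a centered moving average of `window_length`
(default 15, truncated at the ends) and maximal runs with smoothed value at
least `score_cutoff` (default 0.3) become candidate traces. Run ends are
anchored on three consecutive raw above-cutoff pairs, so isolated chance
similarities at region boundaries cannot smear the alignment edges.

**Filters.** A reported trace must have at least `min_span` aligned pairs
(default 15; relaxed to $\max(5, \lfloor 0.8\,l \rfloor)$ when searching
with a representative shorter than 15, otherwise short units could never be
recovered), a windowed score at least `score_cutoff`, and a mean per-pair
similarity at least $\mu + 2\sigma$ of the off-diagonal similarity
distribution (`sigma_factor = 2`). The diagonal band $|i-j| \le 2$ is
excluded — the self-identity alignment is not a repeat signal — and mirror
traces are reported once (upper triangle). Reported traces are maximal (no
strict sub-paths) and deduplicated: two traces are redundant when at least
70% of either one's pairs lie within Chebyshev distance 2 of the other's;
the higher-scoring one is kept.

# Representative phase and hypothesis selection

Two design points were genuinely open and deserve their rationale:

**Lattice re-anchoring.** The off-diagonal band of $M_s$ is
translation-invariant: the window-score argmax fixes the representative
relative to the repeat *region*, not to unit boundaries. For even copy
numbers the centred window sits mid-unit for the true period while the
doubled length happens to align, which silently inverts length selection.
The phase is only visible at the band endpoints, so after `locate_representative()`
the window is shifted to the nearest lattice position of the $d$-band's
first supported row (kept only if the re-anchored window still carries
positive score).

**Selection metric.** Every harmonic of the true period explains almost the
same residues, and on clean signal the per-instance coverage saturates at
1.0 for *any* candidate length (a short window inside the unit matches every
copy perfectly). The package therefore ranks hypotheses by
`covered_residues` — the number of distinct sequence positions covered by
the family's instances — treats hypotheses within 10% of the best (or
within one smoothing window of residues, whichever is larger: edge smear is
an absolute effect, so a purely relative slack is too tight on short repeat
regions) as tied, and breaks ties towards the fundamental: more instances,
then smaller length, then smaller representative start. `mean_coverage` (average fraction
of representative columns matched per instance) and
`total_aligned_residues` are available as alternatives; candidates carrying
less than 5% of the strongest candidate's diagonal mass are not evaluated
at all, since a sliver of noise cannot be a real period yet its profile
still leaks perfect-looking instances.

# The synthetic generator

`generate_synthetic()` plants controllable repeat structure: a base unit of
`unit_length` random unit vectors is drawn, each copy's row $r$ is
$\mathrm{normalize}(\sqrt{\rho}\,\mathrm{base}_r + \sqrt{1-\rho}\,\mathrm{noise})$
with $\rho$ = `within_unit_cosine`, flanks are independent random unit
vectors, and each indel event inserts or deletes one position at a random
interior offset of a copy (ground truth adjusted). The expected cosine
between corresponding positions of distinct copies is $\approx \rho$; at
dimension $D$ unrelated rows have cosine $0 \pm 1/\sqrt{D}$.

The study conditions of the package's own benchmarks (and of
`scripts/acceptance.R`) are: units of 10–40 residues, 3–8 copies,
$\rho = 0.9$, at most one indel per copy, flanks of 10–30 residues,
$D = 64$, 200 positive and 200 background proteins. $D = 64$ rather than a
language model's 1024 keeps tests fast; the cosine pipeline is
dimension-agnostic. What the generator does *not* emulate: real embeddings
are not isotropic or zero-mean, neighbouring residues are correlated,
repeat families share cross-protein signatures, and divergence is not
i.i.d. noise. Passing these benchmarks therefore demonstrates the
correctness and calibration of the machinery on controlled signal, not
field performance on real proteins.

# The pre-filter classifier

The light-attention classifier takes the same per-residue embedding: two 1D
convolutions over the length axis (filter size 9, `channels` outputs each)
produce attention logits and feature maps; per-channel softmax over the
length axis turns the logits into attention distributions; the
attention-weighted sum of the (dropout-regularised) features is concatenated
with the per-channel global maximum into a fixed-size vector of length
`2 * channels`, and a linear head with a sigmoid yields the repeat
probability. Training minimises binary cross-entropy with Adam; early
stopping restores the best-held-out-loss weights after `patience` (20)
epochs without improvement. Production-scale defaults are 1024 channels and
learning rate $10^{-6}$; the test scale (32 channels, $10^{-3}$, $D = 64$)
trains in about a minute. Dropout probability (0.25), the global max pool
and the epoch cap are configurable implementation choices.

**Why the classifier dataset has motifs.** A per-protein duplication signal
has no cross-protein feature a conv+attention network can learn: trained on
positives whose base units are independent random vectors, the model
memorises the training set and generalises at chance. The pre-filter's real
task is knowledge-based — recognising patterns shared with known repeat
families — so `make_classifier_dataset()` draws each positive's base unit
around one of a small dictionary of shared motifs (8 motifs, motif share
$\tau = 0.5$), while keeping within-unit fidelity and background exactly at
the benchmark conditions ($\rho = 0.95$ vs background 0.1). With that
structure the model separates held-out proteins essentially perfectly.

**Attention profiles.** `forward_classifier()` returns both `profile` (the
channel mean of the raw attention logits, the conventional attention score)
and `attention` (the channel mean of the softmax attention weights — the
share of pooling weight each residue receives). On sign-symmetric synthetic
embeddings, trained channels split arbitrarily into positive- and
negative-sign motif detectors, so the *signed* logit mean cancels across
channels even though every channel is attending to the repeat region; the
softmax mass does not cancel and localises the repeats in essentially all
held-out positives. On real embeddings, with their strong common
components, the raw-logit profile is meaningful as well.

# Benchmark harness

Correctness of a predicted repeat is judged by reciprocal span overlap with
an annotated unit: the overlap divided by the prediction length and by the
unit length must both exceed `min_coverage` (0.5) — strict inequalities,
matching the "greater than 50%" convention of structural benchmarks, so a
prediction blanketing two whole equal units fails. This is a sequence-level
surrogate for a structural-superposition criterion, chosen because the
package operates on embeddings only. At the protein level, two predictions
"align correctly" when their embedding slices globally align with score at
least `score_cutoff` and mutual coverage above `min_mutual_fraction` (0.5)
on both sides; a protein is called repeat-containing when strictly more
than half of its predictions align with at least one other. All predictions
on truth-negative proteins count as false-positive repeats.

# Numerical and degenerate-input choices

* All comparisons driving tracebacks use an absolute tolerance of $10^{-12}$
  on DP-cell equalities; ties are broken by the fixed move priority and, for
  gap runs, by the shortest realising run.
* Zero-norm embedding rows are rejected with the offending row index.
* Sequences shorter than `min_span` yield an empty trace set, not an error.
* A probability exactly at the classification threshold is called positive.
* Masking is idempotent; the masking loop terminates because each reported
  family strictly removes score mass.
* Coordinates are 1-based inclusive in every user-facing table and in
  memory; the ground-truth TSV on disk is 0-based half-open (BED
  convention), converted only in the IO layer.

# Problem sizes used by the test-suite and acceptance script

Unit and property tests run on embeddings of 50–200 residues at $D \le 64$;
the recovery, specificity and multi-region benchmarks use 200 + 200
synthetic proteins and 50 two-region constructions; the classifier
benchmarks use 400 labelled embeddings at 32 channels. These sizes give
stable rates (binomial standard errors of ~2 percentage points) while a
full run of the suite stays within a few minutes on one core.

# Known limitations

* No statistical significance is attached to reported repeats — scores and
  the $\mu + 2\sigma$ gate are heuristic; shuffling-based null models would
  destroy the context dependence of real embeddings.
* The MSA is a stitch of pairwise alignments to the representative and is
  not globally optimised.
* Nested or interleaved repeat regions are resolved only as well as masking
  allows; families from different iterations are forced to be disjoint.
* Units shorter than 5 residues are not recoverable (minimum relaxed span),
  and units longer than half the sequence are outside the candidate range
  by construction.
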