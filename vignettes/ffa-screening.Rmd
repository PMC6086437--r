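---
title: "Proteome-based screening of strains for free-fatty-acid production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-based screening of strains for free-fatty-acid production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The screening problem

Selecting a chassis strain for a microbial cell factory is usually done one
strain at a time, experimentally, and is slow and expensive. For
free-fatty-acid (FFA) production in cyanobacteria, however, the genetic
prerequisites are reasonably well understood: a curated set of criterion
proteins is known to impact production positively (targets for insertion or
overexpression), negatively (targets for deletion or underexpression), or to
be outright required for fatty-acid synthesis. `ffascreen` scores, ranks and
categorizes candidate strains from their predicted proteomes against such a
panel, so experimental effort can be focused on the most promising
candidates.

The engine runs in two phases.

**Phase 1 — feature generation.** Each panel criterion is matched against
the strain proteome using homology evidence (BLAST tabular) and domain
evidence (HMMER per-domain tables). Evidence passes a stringent
*domain-completeness* filter: a hit counts only if its e-value is at or
below the threshold **and** the subject protein carries *every* domain
family of the query criterion protein. Domain comparison is set inclusion on
accessions — multiplicity and order are deliberately ignored, because
completeness, not architecture order, is the stated condition. Criteria with
no known domain composition pass the domain test vacuously. The retained
hits are collapsed into a per-strain profile: hit counts (distinct subject
proteins per criterion — robust to alignment fragmentation into multiple
HSPs), presence indicators, and per-orthologous-group (OG) satisfaction. An
OG is satisfied when *any* member is present; this is what lets a backup
enzyme catalyzing the same metabolic step (e.g. pyruvate, phosphate dikinase
EC 2.7.9.1 standing in for pyruvate, water dikinase EC 2.7.9.2) satisfy a
required group.

**Phase 2 — scoring.** The raw strain score is a signed weighted sum over
panel criteria,

$$ s(\text{strain}) = \sum_{c \in \text{panel}} w_c\, x_c, \qquad
   w_c > 0 \text{ for positive/required}, \; w_c < 0 \text{ for negative}, $$

with features $x_c$ either presence indicators (default) or hit counts. Raw
scores are min-max normalized over the evaluated cohort to $[0, 1]$, ranked
descending (ties broken by ascending strain id, so ranks are deterministic
and gapless), and categorized:

* **Top-ranked** — normalized score strictly above the upper boundary
  strain (by default the highest-scoring positive reference);
* **Positive** — above the lower boundary strain but not above the upper;
* **Negative** — everything else. "Higher than" is read strictly, so a
  score exactly equal to a boundary falls below it.

The lower boundary strain is found by clustering the cohort's
one-dimensional scores into two groups (K-means with $k = 2$) and taking the
lowest-scoring strain of the cluster that contains all positive references.

## Numerical and design choices

**Exact 1-D 2-means.** For $k = 2$ in one dimension the optimal partition
minimizing within-cluster sum of squares is a contiguous split of the sorted
scores, so `find_boundary()` scans all $n-1$ splits with prefix sums and
returns the global optimum. This is deterministic and exact, unlike Lloyd
iterations from random starts; the `seed` argument is retained only for API
stability. If the positive references straddle the optimal split, the
boundary is reported as undefined rather than guessed.

**Score form and weights.** The minimal model consistent with
presence/absence feature generation and a normalized score scale is a signed
weighted sum with unit default magnitudes. `unit_weights()` is therefore the
default everywhere; calibrated or user-supplied weights are drop-in
replacements constrained to the same sign pattern.

**Weight calibration.** `calibrate_weights()` asks only that every positive
reference strain out-score every negative reference, with the largest
possible margin. A raw hinge margin over unbounded weights is degenerate —
it grows without limit by inflating any weight on which the references
differ, distorting the mid-cohort ranking — so the objective is the
SVM-style *normalized* margin: the minimum pairwise raw-score difference
divided by the Euclidean norm of the weight vector. It is maximized by
coordinate ascent over log-magnitudes (multiplicative steps 2, 1.5, 1/1.5,
1/2; magnitudes clamped to $[0.01, 100]$), starting from unit magnitudes,
with a fixed pass budget — fully deterministic. If no weights achieve a
positive margin (e.g. a positive and a negative reference with identical
profiles) the result is flagged non-separable rather than silently returned.

**Evidence thresholds.** Defaults `max_evalue = 1e-5` and
`max_ievalue = 1e-5` are conventional homology-search cutoffs; both are
arguments everywhere they apply. Coordinates are 1-based inclusive
throughout, matching both evidence formats.

**Fallback aligner.** `internal_search()` makes the pipeline runnable with
no external binaries: a Smith–Waterman local aligner (match/mismatch, linear
gap; compiled) scores each criterion against each proteome protein. A hit
requires at least 30% of the query's self-alignment score, mirroring the
fixture generator's guarantee that decoys stay below 30% identity; the
nominal e-value $\mathrm{len}_q \cdot \mathrm{len}_s \cdot 2^{-S}$ keeps
genuine homolog copies far below the 1e-5 threshold. This aligner generates
usable evidence for testing and small screens; it does not reproduce BLAST
statistics and is not intended to replace a real search at scale. When no
domain evidence accompanies internally generated hits, the
domain-completeness test is skipped with a warning instead of silently
failing every criterion that has domains.

**Recommendations.** One suggestion per absent positive criterion and per
present negative criterion. For an unsatisfied required OG, only one
representative member (the first in panel order) is suggested: one enzyme
suffices to satisfy a group, so listing every backup co-member would be
redundant.

## What the synthetic generator emulates

The fixtures module generates panels, proteomes, evidence files and cohorts
with known ground truth. Its defaults *are* the study conditions used by the
tests:

* a 64-criterion panel (40 positive, 12 negative, 12 required) whose
  required criteria span 12 OGs, emulating the curated panel's shape; the
  first required groups carry the classical gene labels (pps/ppdK, odhB,
  pyk), everything else is explicitly synthetic (reserved `SYND…` domain
  namespace, so no accidental claims about real Pfam families);
* cohorts of 140 strains, with presence probabilities 0.5 / 0.5 / 0.9 for
  positive / negative / required criteria — required steps are present in
  most strains, as in real screens, where over 70% of strains carry the
  complete synthesis route;
* homolog copies mutated at 5% per residue (within-clade ortholog
  divergence), 5 random decoy proteins per strain held below 30% identity to
  any panel sequence by rejection sampling;
* four injected reference-like strains: two high-presence positive
  references, one intermediate boundary-like strain, one very low negative
  reference;
* for simulation studies, ground-truth weight magnitudes drawn from
  Uniform(0.5, 2) — criterion impacts of the same order of magnitude.

What it does **not** emulate: real domain architectures, gene order,
paralogy, annotation noise, incomplete genomes, or compositional biases of
real proteomes. Passing tests on these fixtures demonstrates that the
engine's logic is correct — filters filter, scores sum, ranks rank,
categories partition — not that any particular real strain will produce
FFAs.

## Problem sizes used by the test suite

The suite verifies scoring against a brute-force dot product on 1,000
random profiles and boundary detection against exhaustive minimum-SSE
enumeration on 200 random cohorts of up to 15 strains; categorization on a
simulated 140-strain cohort; the domain filter against a set-inclusion
oracle on 500 random architectures; end-to-end ground-truth recovery on a
noise-free 20-strain × 64-criterion cohort through the fallback aligner; and
weight-recovery on 20 replicate cohorts of 50 strains × 30 criteria, where
rankings under calibrated weights track rankings under the true generating
weights (mean Spearman ρ ≥ 0.9) and positive references always outrank
negative ones when separable.

## Known limitations

* The engine evaluates native biosynthetic capability only; robustness,
  growth rate, photosynthetic efficiency, expression levels and metabolic
  flux are outside its scope, as is FFA chain-length specificity.
* Real curated panels and pre-evaluated cohorts are user-supplied inputs;
  the shipped generator produces synthetic stand-ins only.
* The normalized score is cohort-relative: adding a strain can shift every
  normalized value (ranks of stored strains may change in the returned
  view; stored cohort data is never modified).
* Category boundaries compare normalized scores within one cohort; under
  min-max scaling this is order-equivalent to comparing raw scores.
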