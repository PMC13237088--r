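---
title: "Methods: the LCR complexity space, reference annotation and boundary estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LCR complexity space, reference annotation and boundary estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrbench)
```

# The two-axis complexity space

Protein low-complexity regions (LCRs) span a continuum from perfect
homorepeats (polyQ, polyA) through degenerate tandem repeats to mildly
biased stretches. `lcrbench` characterises any segment by two
percentages:

* **Dominance (y).** The share of the most frequent amino acid,
  `100 * max_a c(a) / L`. Ties between equally frequent residues are
  broken lexicographically so results are deterministic.
* **Mutational distance to a perfect repeat (x).** For each candidate
  period `p` in `1..floor(L/2)`, positions are grouped by
  `(position - 1) mod p`; the consensus of a phase class is its most
  frequent symbol (ties again lexicographic) and the period's cost is the
  number of positions differing from their phase consensus. `x` is
  100 times the minimum cost over periods, divided by `L`, and
  `best_period` is the smallest period attaining it. A partial terminal
  unit is allowed, and the upper bound `floor(L/2)` guarantees at least
  two (possibly partial) unit copies, so "repeat" always means something
  observable in the segment.

Because period 1 is always admitted, `x <= 100 - y`: every sequence lies
in a triangle. Degenerate inputs are handled explicitly: a single-residue
sequence has `x = 0` at period 1; empty sequences are an error everywhere
rather than a silent zero.

Two distances are deliberately exposed side by side. The period-1
distance to the homorepeat of the dominant residue
(`mutation_to_homorepeat`, identically `100 - y`) is what the intuitive
worked example ACDEFEGEIE → 60 % computes; the minimum over all periods
(`min_mutation_over_periods`) is what "minimal mutation to achieve perfect
periodicity" means, and is strictly smaller whenever some longer period
fits better (40 % at period 4 for the same segment). The diagram x-axis
is selectable (`x_metric = "minperiod"` or `"homorepeat"`) with
min-over-periods as the default, since the diagram is about
repetitiveness, not just composition. Both conventions are defensible;
keeping both avoids baking one reading into every downstream number.

The triangle is cut at 50/50 into LCR (`x < 50 & y > 50`), LTR
(`x < 50 & y < 50`) and HCR (`x > 50 & y < 50`) zones. The inequalities
are strict: boundary values of exactly 50 are classified `UNDEFINED`
rather than being silently assigned to a side, as is the (unreachable
when period 1 is admitted) `x > 50 & y > 50` corner.

One consequence worth knowing: under the min-over-periods metric a
*random* 20-residue segment rarely lands in HCR, because with ten
candidate periods some period always fits partially by chance and pulls
`x` below 50. Under the homorepeat metric random segments sit where one
expects them, at high x and low y. The package's tests assert the HCR
expectation under the homorepeat metric for this reason.

Shannon entropy `H = -sum(f log2 f)` is computed in bits from the
segment's own frequencies, no pseudocounts, so the ceiling for the
20-letter alphabet is `log2(20) ≈ 4.32`. Purity is `y / 100`. Ambiguity
codes (X, B, Z, ...) are retained as ordinary symbols so that length
arithmetic never changes; they are rare enough in practice not to distort
compositional statistics, and dropping them would silently shift
coordinates.

# Reference annotation

The operational reference LCR set is produced by a sliding window of 20
residues advancing in steps of 10 (both configurable; the defaults are
the classical scheme for this diagram). Windows never extend past the
sequence: if the final residue would be uncovered, one extra window
anchored at `(L - window + 1, L)` is appended, so C-terminal LCRs are not
systematically missed; proteins shorter than the window are scanned as a
single whole-protein window rather than skipped, which keeps true-negative
counts honest. Windows passing `mutation % < 50 AND dominance % > 50`
(strict inequalities, so exactly-50 windows are excluded) are merged into
maximal regions. Merging matters only for region-level counts — residue
level labels are identical either way — and the merged union is the
natural reference for residue-level evaluation because it never counts a
residue twice.

This reference is an *internal, reproducible definition*, not biological
truth; all TPR/FPR numbers downstream measure agreement with it.

# Interval algebra and consensus

All coordinates are 1-based inclusive residue positions. The
standard BED convention (0-based half-open) exists only as an I/O dialect
(`read_regions(..., dialect = "bed0")`) and converts on the boundary, so
no off-by-one reasoning ever happens inside the package. IRanges supplies
the interval arithmetic; the public surface is plain tibbles.

* **Merging** unites overlapping *and bookended* intervals
  (`end + 1 == next start`), the residue-level equivalent of half-open
  abutment.
* **Multi-method intersection** partitions covered residues into maximal
  runs of constant method-membership; each run carries its consensus
  level `k`. `k` counts method+mode configurations, not base tools.
* **Jaccard** is intersection over union of residue sets pooled across
  proteins, with the empty-union case defined as 0.
* **Histograms** use the conventional bin labels (lengths 0–10, 10–20,
  20–50, 50–100, 100–200, >200; coverage 0–20 … 80–100 %; counts 0, 1–5,
  5–10, 10–15, 15+). Labels like "0–10, 10–20" overlap at their edges, so
  ownership must be decided: bins are left-open/right-closed — a
  length-10 region is "0–10", a protein with 5 regions is "1–5". This is
  a documented convention, not a discovery; edge counts change if you
  choose differently.

Consensus tiers are characterised by dominant-motif class (Monopeptide /
Dipeptide / Tripeptide when a primitive tandem unit of length 1/2/3
covers at least half the segment, Other otherwise), and by entropy and
purity quartiles. Requiring the unit to be *primitive* ("AA" reduces to
"A", "ABAB" to "AB") prevents every homorepeat from also counting as a
di- and tripeptide repeat. The 0.5 coverage floor is the package's
choice of threshold; it makes "dominant" mean "covers at least half".
Outliers are retained in all computed summaries — excluding them is a
plotting decision, not a statistical one.

# Evaluation

Residue-level confusion counts (TP/FP/FN/TN against the reference) pool
over the evaluated proteins and always sum to the residue total. Rates
with zero denominators are reported as missing (`NA`), never as 0 — a
method with no reference positives in a stratum has an *undefined* TPR,
not a zero one.

Four stratifications mirror common practice: gene-length deciles
(proteins sorted by length, stable tie order by id, bin sizes differing
by at most one with the larger bins first — the remainder rule is a
determinism choice the data do not dictate), reference-LCR count per
protein (1–6+, proteins with no reference LCR excluded from count
strata), reference coverage (5/10/15/20/>20 %, right-closed), and the
LCR:gene entropy ratio (0.2–1.0 bins, right-closed, first bin including
0; proteins with zero whole-sequence entropy are excluded because the
ratio is undefined). Within a stratum residues are pooled by default;
per-protein averaging is available behind a flag because both appear in
the literature and they answer different questions (pooling weighs long
proteins more).

Per-method summaries are *unweighted* means of per-stratum rates — a
deliberate reading of "grouped means": each stratum counts equally,
regardless of its residue mass.

# Boundary estimation

Given labelled points (x, y, LC/BG), the binned estimator discretises
the plane into Δ = 2 % bins (`bin index = floor(v / Δ)`, the top edge
v = 100 closed into the last bin so no one-point bin row exists) and
computes a smoothed posterior `P(LC | i,j) = (n⁺ + a)/(n⁺ + n⁻ + 2a)`
with pseudocount `a = 1`. The pseudocount keeps every probability
strictly inside (0, 1) and sets empty bins at the indifferent 0.5; with
`a = 0` the estimator reduces to the empirical frequency wherever
defined, and growing `a` pulls every bin monotonically toward 0.5.

Because the split into training and held-out halves is not dictated by
the data, it is configurable: the default is a stratified 50/50 split
under a caller-supplied seed. Held-out points are scored by their bin's
posterior, the ROC is swept over the sorted unique scores plus {0, 1}
under the `LC if P >= t` rule, and t* maximises Youden's J = TPR − FPR
with ties broken toward the smallest threshold (the most permissive
optimal operating point). The `P(LC) = t*` contour is extracted by
marching squares on bin centers with linear interpolation
(`grDevices::contourLines`); it may be empty or consist of several
polylines, and it is a *confidence* boundary, not a biological one.

The smooth alternative fits a tensor-product penalised-spline logistic
surface (`mgcv::gam`, binomial family, REML smoothness selection,
basis dimension k = 10 per margin by default). The logit link guarantees
probabilities strictly inside (0, 1); with heavy penalisation the surface
degenerates toward an ordinary logistic plane, which is the correct
limiting behaviour for a smooth logistic model. Non-convergence is an
error with the deviance reported, not a silent result.

# The synthetic-data generator

The generator exists so that every analytic module can be exercised
against known ground truth with no downloads. It emulates exactly the
features the methods measure: background sequences are iid draws
(uniform over the 20 standard residues by default; any composition
vector can be supplied), and planted features are homorepeats or tandem
repeats degraded by iid substitutions at a per-residue rate, placed
uniformly at random without overlap (placement failure after bounded
retries is an error, never a silent skip). Pseudo-methods emit each truth
region with a planted sensitivity, jitter endpoints uniformly within a
bounded radius, and add decoy regions in background at a planted
false-discovery rate. Everything is deterministic per seed, and seeded
helpers save and restore the caller's RNG state.

What the generator does *not* emulate — and therefore what passing tests
do not show — includes: realistic amino-acid composition and its
covariation with disorder, length and domain structure of real proteomes,
correlated errors between real detectors (real tools disagree
systematically, not independently), and the residue-mapping noise of real
disorder annotations. Synthetic results validate the *machinery*
(coordinates, counting, rates, thresholds), not biological conclusions.

For boundary-recovery experiments, `separable_boundary_points()` plants a
linear boundary `x + y = 100`: each class is sampled uniformly over the
union of whole grid cells lying entirely on its side of the line (with an
optional extra margin). Building classes from whole cells is what makes
"separable" survive discretisation — any cell-straddling construction
leaves boundary bins with mixed or sparse counts, and exact separability
after binning would then hold only asymptotically. With cell-aligned
classes the planted line is recoverable: the held-out Youden J reaches 1
and the extracted contour lies within one bin width of the line.

# Problem sizes and numerical choices

The test-suite and the acceptance script use sizes chosen to make the
checks sharp but quick on a single CPU: the exhaustive minimum-mutation
oracle enumerates all 3⁸ = 6561 length-8 sequences over a three-letter
alphabet (with every consensus assignment tried explicitly); the interval
algebra is checked against explicit residue sets on 1,000 random
fixtures; the triangle invariant on 10,000 random sequences of lengths
4–30; sensitivity recovery uses 500 planted homorepeats of 25 residues
(binomial 3σ ≈ 0.054 at sensitivity 0.8); boundary recovery uses 60,000
points per class at Δ = 2 (roughly 25 training points per supporting
bin, which makes an empty supporting bin — the only way held-out
separation can fail — vanishingly unlikely), and the area-contraction
sweep 30,000 per class at margins 0/20/40. Floating-point comparisons of
exact quantities (probabilities, percentages) use equality at 1e-9 to
1e-12 tolerances; everything stochastic is seeded.

# Known limitations

* The min-over-periods metric is O(L · max_period) per segment; profiling
  very long consensus segments (thousands of residues) is noticeably
  slower than windows of 20–50.
* The dominant-motif rule (primitive unit, tandem coverage ≥ 0.5) is one
  reasonable operationalisation of "dominant motif"; other regex-style
  definitions would classify borderline segments differently.
* TPR/FPR measure agreement with the operational reference definition;
  they are not estimates of biological detection accuracy.
* The smooth surface is a generic penalised-spline logistic fit; it is
  an analog of GAM-based boundary mapping, with its contract (continuity,
  probabilities in (0, 1), planar limiting behaviour) stated rather than
  any specific basis/penalty configuration reproduced.
* The smooth logistic surface is slow (and its smoothness selection may
  hit iteration limits) on *perfectly separated* point clouds — complete
  separation is pathological for any logistic likelihood. The binned
  estimator is the right tool for separable synthetic data; the smooth
  surface is meant for noisy, overlapping classes.
* Tool outputs reporting regions past the sequence end are an error, not
  clamped; upstream coordinate bugs should fail loudly.
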