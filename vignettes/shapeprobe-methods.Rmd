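---
title: "Methods: multi-condition SHAPE analysis with shapeprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-condition SHAPE analysis with shapeprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeprobe)
library(dplyr)
```

`shapeprobe` analyses SHAPE chemical-probing experiments performed under
several conditions — with and without Mg²⁺, and along a thermal
denaturation series — to locate the nucleotides that hold an RNA's tertiary
structure together, and to encode them into constraint files that let
secondary-structure prediction software recover pseudoknots it would
otherwise miss. This vignette explains each method, its assumptions, the
parameters that matter, and the design decisions taken where conventions
differ between labs.

## Replicate handling

A reactivity table carries, per position, one normalized SHAPE reactivity
per replicate (typically three). Values may be negative: SHAPE
normalization subtracts a background, so weakly reactive positions scatter
around zero.

**Outlier rule.** Within each position's replicate set, a value is
discarded when its absolute distance to *every* other measurement exceeds
`window = 0.4` reactivity units. With a triplicate this keeps the agreeing
pair and drops the stray value; if all values are mutually more than 0.4
apart there is no agreeing majority and the position becomes undetermined.
The rule is a single pass over the original values and is provably
idempotent: a kept value owes its survival to a neighbour within 0.4 units,
and that neighbour cannot itself have been discarded (discarded values are
far from *all* others). With fewer than three usable values no outlier is
identifiable and everything is kept. The test is applied to the values as
read; whether it should precede or follow renormalization is not
standardized, so the pipeline takes the table at face value.

**Classes.** Aggregated mean reactivities bin into the conventional display
classes: low below 0.4, moderate from 0.4 to 0.7 inclusive, high strictly
above 0.7. Negative means clamp to low. The boundary convention (0.4 and
0.7 both moderate) follows from "high" being defined as *over* 0.7.

## Differential reactivity calling

For each position determined in both conditions, with mean reactivities
$R_1, R_2$:

$$\Delta R = |R_1 - R_2|, \qquad \text{rel} = \frac{\Delta R}{R_1 + R_2}.$$

A position is significant only when **all three** hold strictly:
$\Delta R > 0.2$, $\text{rel} > 0.2$, and a two-sided t-test on the
per-replicate values gives $p < 0.05$. The pair of thresholds filters out
both small absolute changes between weakly reactive nucleotides and large
but meaningless changes between highly reactive ones; the relative change
presumes a positive mean sum, so non-positive sums are flagged and never
called.

Design decisions:

* **Welch, not pooled.** With n = 3 per side, equality of variances cannot
  be assessed, so the unequal-variance (Welch) t-test is used throughout.
  The hand-coded Welch statistic (Welch–Satterthwaite degrees of freedom)
  serves as an independent oracle in the test suite.
* **Degenerate variance.** If both sides are exactly constant the t
  statistic is undefined; the pipeline sets p = 0 when the means differ and
  p = 1 otherwise, flags the record, and lets the ΔR/rel thresholds decide.
  This keeps the strict-threshold semantics testable at exact boundary
  values.
* **No multiple-testing correction by default**, matching common practice
  for per-position probing comparisons; `p_adjust = "BH"` is available.

## Thermal-unfolding clustering

Each nucleotide's reactivities across the probing temperatures (37, 53, 65,
74, 85 °C by default) form a 5-vector. Positions undetermined at any
temperature are removed. Vectors are floored at 0.01 (log₂ cannot take the
non-positive values normalization produces; the floor is configurable),
log₂-transformed, then standardized row-wise (per nucleotide) and
column-wise (per temperature), in that order. The double standardization
makes clustering respond to the *shape* of the thermal response, not the
absolute reactivity — it is exactly invariant to uniform positive rescaling
of the input — at the cost of amplifying noise for nucleotides whose
response is genuinely flat. Zero-variance rows or columns are centered but
not scaled, and flagged.

k-means uses `stats::kmeans` (Hartigan–Wong) with 50 random restarts under
a fixed seed, keeping the lowest-distortion solution; distortion is the
within-cluster sum of squared errors. When k reaches the number of distinct
profiles the assignment is constructed directly (one cluster per distinct
vector, distortion zero). The restart protocol, not the seeding scheme, is
what buys reproducibility and objective quality here, which is why the
standard R implementation is used rather than a bespoke k-means++.

**Choosing k.** The distortion curve for k = 1…10 is summarized by the
maximum-distance-to-chord rule: the chosen k maximizes the perpendicular
distance to the straight line joining (1, d₁) and (10, d₁₀). This
automates the visual elbow judgement deterministically; the full curve is
always returned (and written by the pipeline) so the choice can be
overridden with an explicit `k`.

**Archetypes.** With k = 4 the clusters are labelled from their *raw* mean
profiles: a cluster already above 0.7 at the lowest temperature is
`always_reactive` (single strands; their apparent reactivity then drifts
down because profile normalization rescales as everything else becomes
reactive); otherwise the temperature interval with the largest centroid
increase decides — first interval (37→53 °C) `tertiary_37_53`, last
interval (74→85 °C) `stable_85`, any middle interval `secondary_65`. The
0.7 threshold is the high-reactivity bin edge and is configurable; ties or
k ≠ 4 label `unassigned`.

## Melt-curve analysis

Dye-based melt curves (temperature vs relative fluorescence) are analysed
per replicate: min–max normalization to [0, 1] (so prominence thresholds
are comparable across instruments), −dRFU/dT by central differences
(one-sided at the grid ends), replicate averaging on the common grid, and a
centered moving average whose window is given in degrees (default 1.5 °C)
rather than points, making smoothing grid-independent. Melting transitions
are the local maxima of the smoothed derivative whose topographic
prominence is at least `min_prominence = 0.05` of the curve's dynamic
range; each Tm is reported at the grid point of its maximum (no sub-grid
refinement by default).

The sign convention deserves a note: the analysis takes maxima of −dRFU/dT
as transitions, the standard convention of derivative melt analysis, which
corresponds to fluorescence *dropping* fastest at Tm. The synthetic melt
model is built to match: a linearly decaying dye baseline minus one
sigmoidal fluorescence drop per transition. Narrative descriptions of
dye-binding experiments sometimes describe fluorescence rising as single
strands become available; under that reading the transitions would be
derivative minima. The package follows the analytic convention
consistently, and `compare_titration()` tracks Tm shifts and peak growth
across a Mg titration by peak rank regardless of sign.

## Sugar pucker analysis

The five ring dihedrals v₁ (C1′-C2′-C3′-C4′) … v₅ (O4′-C1′-C2′-C3′) are
condensed into pseudorotation coordinates via the Fourier components

$$a = \tfrac{2}{5}\sum_{i=1}^{5} v_i \cos(0.8\pi(i-1)), \qquad
  b = -\tfrac{2}{5}\sum_{i=1}^{5} v_i \sin(0.8\pi(i-1)),$$

with amplitude $\sqrt{a^2+b^2}$ (degrees) and phase $\mathrm{atan2}(b, a)$
mapped to [0°, 360°). This treats all five dihedrals symmetrically. The
sign of $b$ was fixed by a round-trip requirement: dihedrals constructed as
$v_i = A\cos(P + 0.8\pi(i-1))$ must return amplitude $A$ and phase $P$,
which places the canonical C3′-endo pucker near P = 18°. The cosine
projection $a/\mathrm{amp}$ (often printed as "Pha") is also reported, but
classification uses the full angle: a cosine cannot distinguish the two
half-wheels, and ten families require the full circle.

Phases classify into the ten standard 36°-wide families in wheel order
starting at 0°: C3′-endo, C4′-exo, O4′-endo, C1′-exo, C2′-endo, C3′-exo,
C4′-endo, O4′-exo, C1′-endo, C2′-exo. The A-like group is {C1′-endo,
C2′-exo, C3′-endo, C4′-exo}; the B-like group is {C1′-exo, C2′-endo,
C3′-exo, C4′-endo}; the two O4′ families belong to neither. Rings with
amplitude below `planar_tol = 1e-6°` are planar — phase undefined — and
count in an `undefined` occupancy bucket rather than a family. Occupancy
percentages per nucleotide always sum to 100.

Dihedral ingestion is from a per-frame CSV (`frame`, `residue`, `v1`…`v5`);
extracting dihedrals from MD trajectory formats is left to external
tooling.

## Constraint-file strategies

Two encodings turn differential results into input for prediction
software, both written in the two-column `.shape` dialect with −999 for
undetermined positions and six significant digits:

* **boost10** (temperature differential): significant positions get
  reactivity 10 — prohibitively costly to pair under pseudo-energy models —
  while every other nucleotide keeps its 37 °C value. This discourages
  spurious secondary pairings through pseudoknot strands while leaving the
  rest of the profile intact.
* **pk_mask**: significant positions get −0.2 (pairing-favourable), all
  other determined positions get 5 (pairing-adverse). This inverts the
  usual reading of reactivity: the only pairings the software can still
  form are among the differential positions, so any predicted helix is a
  pseudoknot-candidate pairing. Undetermined positions get the −999
  sentinel; assigning them 5 would fabricate evidence of being unpaired.

`find_complementary_helices()` provides an in-package sanity check of a
mask: it enumerates every maximal antiparallel helix of ≥ `min_len` base
pairs (default 3 — two-base-pair interactions are below the reliable
detection limit of this screen) formed entirely within the candidate set,
with GU wobble pairs allowed by default since pseudoknot helices commonly
contain them. The choice of condition pair that defines "significant" (37
vs 53 °C, or ±Mg) is the caller's; the pipeline computes both comparisons.

## The synthetic-data generator

The generator exists so that every stage has data with known truth. It
emulates, per structural class, the statistical structure of multi-condition
probing data — not any particular RNA's sequence-specific behaviour.

`make_structure()` lays out a pseudoknotted RNA (default 188 nt, minimum
60) with three regular helices, one stable helix, tertiary-contact
stretches, an H-type pseudoknot whose 5′ strand sits in a hairpin loop and
pairs with a complementary downstream 3′ strand, and a complementary
kissing-loop pair between two hairpin loops. Extra length beyond the
60-nt minimal layout is distributed round-robin over segments so all
classes scale together; at 188 nt the layout has 60 HELIX, 43 SS, 22 KL,
22 PK, 21 TERT and 20 STABLE_HELIX nucleotides.

`simulate_reactivities()` draws replicates as class mean + logistic
temperature response + Mg term + Gaussian noise:

* 37 °C class means align with the display bins: single strands 0.90,
  helices 0.10, stable helix 0.08, tertiary contacts 0.50, kissing loop
  0.45, pseudoknot strands 0.15 — paired positions low, tertiary contacts
  moderate, loops high.
* Logistic midpoints place the melting of each class where the thermal
  series resolves it: tertiary/pseudoknot/kissing-loop at 45 °C (opening
  between 37 and 53 °C), regular helices at 66 °C (the onset of
  secondary-structure melting that the melt curves put at ~65 °C), the
  stable helix at 90 °C (reactive only at the top of the range); widths are
  4 °C, wide enough that clustering is non-trivial but the four archetypes
  remain resolvable, which is the regime the thermal series is designed to
  probe. Single strands have no transition; they drift down by 0.2 units
  across the range, mimicking the normalization artefact that makes
  everything look less reactive as the average rises.
* Removing Mg adds +0.4 to tertiary contacts, the kissing loop and the
  pseudoknot 3′ strand — but not the 5′ strand, which is modelled as
  finding an alternative pairing partner without Mg. This plants the
  one-sided pseudoknot signature the ±Mg comparison is known to produce.
* Replicate noise is 0.04 SHAPE units (clean triplicate agreement after
  normalization), and 0.6 % of positions per condition lose their signal
  entirely, which across five temperatures removes about 6 of 188
  positions from the clustering matrix.

`simulate_melt()` produces triplicate curves on a 37–95 °C grid at 0.5 °C
steps (a 0.04 °C/s ramp sampled every ~10 s) as a linearly decaying
baseline (900 RFU, −3 RFU/°C) minus sigmoidal drops at the planted Tms
(defaults 57 and 80 °C, widths 1.5 °C) plus 0.5 RFU of Gaussian noise.
A "tertiary-mutant" configuration is obtained by planting only the 80 °C
transition. `simulate_dihedrals()` draws pucker families per frame from
per-nucleotide mixture weights and reconstructs dihedrals by inverse
pseudorotation with Gaussian jitter (amplitude 38.6 ± 3°, phase ± 5°).

Everything derives deterministically from the configuration seed; each
condition folds its temperature, Mg and probe into a derived 32-bit seed so
conditions are independent but reproducible, and planted truth (class
labels, true means, transition tables, mixtures) is attached to every
simulated object.

**What passing tests do and do not show.** The generator's classes respond
homogeneously, noise is Gaussian and position-independent, and undetermined
positions are missing at random. Real probing data have position-specific
variance, correlated replicate errors, sequence-dependent reagent biases,
and nucleotides that genuinely defy their structural class (edge base
pairs, dynamic regions). Recovery of planted truth therefore validates the
pipeline's logic and numerics, not its error rates on any real RNA.

## Numerical choices and degenerate inputs

* Strict inequalities at every significance threshold; boundary cases
  (ΔR or rel exactly 0.2) are never called.
* Reactivity floor 0.01 before log₂; floor scales with any uniform
  rescaling of the data to preserve the transform's scale invariance.
* k-means: 50 restarts, `iter.max` 100, fixed default seed 42; distortion
  curves are checked for monotonicity and a warning suggests more restarts
  if violated.
* Peak prominence uses the full topographic definition (drop to the higher
  of the two flanking saddles), so shoulders on a large peak do not count
  as transitions; plateaus of exactly equal values count once, at their
  midpoint.
* Pseudorotation treats amplitudes below 1e-6° as planar rather than
  returning a numerically meaningless phase.
* SHAPE files print six significant digits; re-exporting a parsed file is
  byte-identical, so round-trips are lossless at the printed precision.

## Scale of the shipped analyses

The test suite and the acceptance script run the full pipeline at the
study's natural scale: 188-nt structures, five temperatures, triplicates,
1000-position differential comparisons, 20 generator seeds for clustering
recovery, 1000-draw pseudorotation round-trips, and ~120-point melt curves.
A complete run of the test suite plus the acceptance script takes on the
order of a minute on a single CPU.

## Known limitations

* The pipeline starts from normalized reactivity tables; raw
  electropherogram or mutational-profiling processing is out of scope.
* It writes constraint files for prediction software but never invokes
  that software; the complementarity screen is a necessary-condition check,
  not a folding prediction.
* Archetype labels are defined for k = 4; other k values return the
  clustering unlabelled rather than guessing.
* Thermodynamic model fitting (two-state ΔH/ΔS from melt curves) is not
  attempted; only transition temperatures and peak shapes are reported.
* Welch-vs-pooled is fixed at Welch; with n = 3 the choice can flip
  borderline p-values, which is one reason the two ΔR thresholds, not the
  t-test, carry most of the specificity.
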