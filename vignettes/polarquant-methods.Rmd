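---
title: "polarquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polarquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarquant)
```

polarquant quantifies front–rear polarity in rod-shaped bacteria at four
levels: polar protein localization in snapshots, motility and reversals in
time-lapses, GTPase activities in bulk assays, and gene co-occurrence across
genomes. This vignette explains the model behind each stage, the parameters
that matter, and the design choices made where the underlying conventions
are genuinely open. Every number shown here is computed by the code in this
document or by the package's test suite; the vignette states no result the
tests do not themselves reproduce.

## Snapshot localization

### Model

A segmented cell (an integer label mask plus a fluorescence image) is
reduced to a pixel set, and its two pole anchors are the extremal pixels of
the principal axis of the pixel coordinates. Each pole region is the set of
cell pixels whose axis projection lies within a fraction (default 0.2) of
the cell length from that pole; the remaining pixels are the cytoplasmic
reference.

A polar cluster is called per pole when the largest 4-connected component of
pixels above `mu_cyto + 2 * sd_cyto` has mean intensity above that threshold
and spans at least 3 pixels. In time-lapse mode a second rule is added: the
component mean must also exceed twice the cytoplasmic mean. Both rules
operate on differences and ratios of intensities measured within one cell,
which makes the accept/reject decision invariant under affine intensity
transforms of the whole image (the property suite checks this).

Pole fluorescence is the summed intensity of the detected cluster; pole 1
is by definition the brighter pole. The asymmetry index is

$$\omega = \frac{F_{pole1} - F_{pole2}}{F_{pole1} + F_{pole2}} \in [0, 1],$$

defined only when at least one cluster exists; cells without polar signal
are diffuse. Classes: unipolar ($\omega > 0.9$), bipolar asymmetric
($0.2 < \omega \le 0.9$), bipolar symmetric ($\omega \le 0.2$), diffuse.

### Design choices

* **Pole region fraction 0.2.** The cluster-calling rules do not define the
  spatial domain searched; polar clusters in this biology sit at the cell
  tips, and 20% of the axis length keeps the two regions disjoint with a
  clear cytoplasmic segment between them. Configurable via `pole_fraction`;
  at 0.5 the two regions exactly partition the cell (ties split at the
  midpoint).
* **Cytoplasmic statistics** are the mean and SD of the cell pixels outside
  both pole regions, computed once per cell with no iteration. This is
  deterministic and unbiased by cluster brightness; a per-image alternative
  would couple cells to their neighbours' expression levels. Cells with
  fewer than 10 cytoplasmic pixels are flagged unquantifiable and dropped
  with a message.
* **Candidate = largest supra-threshold component** (ties broken by total
  intensity), at most one cluster per pole.
* **Boundary ties.** $\omega$ exactly 0.9 bins as bipolar asymmetric and
  exactly 0.2 as bipolar symmetric: boundaries go to the less extreme class,
  making the four classes a total partition.
* **Coordinates** are R-native 1-based (row, col) matrix indices throughout,
  including output tables; introducing a 0-based convention inside an R
  package invites off-by-one defects at every boundary.

## Motility tracking

### Model

Tracks link per-frame cell observations by greedy nearest-centroid matching
with a displacement gate (default: half a cell length per frame); ambiguous
matches terminate the tracks involved rather than guessing, and tracks are
never merged across gaps. Pole identities "a"/"b" are propagated by
nearest-pole matching between consecutive frames, so they are persistent
anatomical labels that do not relabel at reversals.

Reversal detection projects each per-interval centroid displacement onto
the cell's long axis and decomposes the sequence into runs of constant
sign. A reversal is a sign change where both adjacent runs travel at least
`min_displacement` cumulatively (default: one cell width); runs below the
gate are treated as positional jitter and absorbed into whichever neighbour
travelled further. The reported event frame is the first frame moving in
the new direction. This gate makes the detector robust to single-frame
jitter at the cost of missing direction changes shorter than the gate —
an unavoidable trade-off for any finite-displacement detector, and the
reason the ground-truth equality tests condition on events separated by
enough frames to be resolvable.

The leading pole of a run is the persistent pole pointing in the direction
of motion; roles swap exactly at detected reversals. The dynamic asymmetry
index per frame is

$$\omega_{dyn} = \frac{F_{leading} - F_{lagging}}{F_{leading} + F_{lagging}} \in [-1, +1],$$

so $-1$ is unipolar localization at the lagging pole and $+1$ at the
leading pole. Frames are included only when the cell moved for three or
more successive frames without reversing, excluding the first frame after
and the last frame before each reversal, and frames with zero total polar
fluorescence are dropped.

Reporting conventions: speeds are per-interval centroid displacements
(20 s intervals over 10 min are the usual convention for pili-driven
movies, 30 s over 15 min for gliding); `reversal_frequency()` counts events
in the first full reporting window; a cell counts as moving when its median
per-interval speed exceeds 0.5 px/interval (no published threshold exists;
this sits well below real gliding speeds and above segmentation jitter).
Strain comparisons use `welch_t_test()`, the two-tailed unequal-variance
t statistic with Welch–Satterthwaite degrees of freedom, implemented from
the defining formulas and cross-checked against `stats::t.test()` to
1e-10 in the suite.

## GTPase assay kinetics

In the regenerative coupled assay, GDP release is coupled through pyruvate
kinase and lactate dehydrogenase to NADH oxidation, read as a linear A340
decrease with exactly one NADH per GTP hydrolyzed (the coupling enzymes are
in excess, so regeneration is not limiting). The estimator is an ordinary
least-squares slope over the fitting window — by default the full 60-min
trace, since published activities from this assay are endpoint-style 1-h
numbers; traces that exhaust NADH (A340 ≤ 0.05) are truncated before
saturation. Conversion to specific activity:

$$\text{rate} = \frac{|m - m_{bg}|}{\varepsilon_{340}\, l} \cdot
  \frac{3600}{[E]} \quad \left[\frac{\text{GTP}}{\text{enzyme} \cdot h}\right],$$

with slope $m$ in absorbance/s, $\varepsilon_{340} = 6220\,$M⁻¹cm⁻¹ for
NADH, effective path length $l$ (default 0.5 cm — plate-reader paths depend
on well volume and must match the instrument), and enzyme concentration
$[E]$ in molar. Replicates are averaged with a standard error; a background
steeper than the sample clamps the rate at 0 and flags it.

The malachite-green branch fits an OLS standard curve A590 vs [Pi] (at
least 3 standards including the 0 blank), reads samples off the curve, and
divides by enzyme concentration and incubation time (default 1 h). Readings
above the top standard are flagged as extrapolated.

`titration_analysis()` fits $A(x) = A_0 + A_{max}\, x / (K + x)$ by
Levenberg–Marquardt least squares and reports the saturation concentration
as the smallest *tested* concentration whose fitted activity reaches 95% of
the fitted plateau $A_0 + A_{max}$. This is a deliberately strict
operationalization: a hyperbola with $K$ comparable to the tested range
correctly reports "saturation not reached" (the 95% point of a hyperbola
lies at $19K$). Monotone-decreasing series are rejected as violating the
model.

## Gene co-occurrence

Presence/absence matrices (genomes × genes, with phylum/class/order
metadata) are compared by the Jaccard index of profile pairs:
`both_present / (both_present + only_reference + only_gene)`. Jaccard
ignores genomes lacking both genes, which is the right behaviour when most
of a broad genome panel (the emulated surveys span > 1600 prokaryotic
genomes) lacks the module of interest entirely — a correlation-style
metric would reward shared absence. The phi coefficient is available as an
option for panels where absence is informative. Ranking is by descending
score with alphabetical tie-breaks, reference excluded. No phylogenetic
correction for lineage non-independence is applied; closely related
genomes count as independent observations, which inflates apparent
co-occurrence within clades.

## The synthetic-data module

The generators are pure functions of their spec objects (seed included):
identical specs give bit-identical output, and their ground-truth tables
are sufficient to score every downstream stage without re-inspecting
pixels.

* **Snapshot scenes.** Cells are axis-aligned rods (rectangles with
  semicircular caps) on a non-overlapping grid, so pole anchors are exact;
  what the analysis consumes is pole geometry, not cell curvature. Defaults
  — 40 × 9 px cells, cytoplasm 100 ± 8, cluster pixels at 3× the
  cytoplasmic mean, 6-px clusters, additive Gaussian noise — are typical of
  background-subtracted epifluorescence of these bacteria at ~0.06 µm/px.
  The pattern mixture is realized as exact stratified class counts
  (largest-remainder rounding, shuffled placement): the emulated object is
  a published population table of exactly *n* cells with stated class
  percentages, so ground-truth prevalence is controlled and any deviation
  measured downstream is classification error, not multinomial sampling
  noise. Per-class asymmetry targets default to the interior of the class
  intervals (asymmetric 0.3–0.8, symmetric 0–0.15; unipolar cells carry a
  single cluster, $\omega = 1$) so the intended class is unambiguous;
  bipolar cells realize their target $\omega$ exactly by scaling cluster
  intensities with the dimmer cluster held at the guaranteed-detectable
  base intensity.
* **Time-lapses.** Cells glide along their long axis in separate lanes
  (spaced beyond the linker's gate, so ground-truth identity is
  unambiguous), with Gaussian per-interval speeds (default 8 px/interval ≈
  1 µm per 30 s, a typical gliding speed) and Poisson reversals; at a true
  reversal the direction flips instantaneously and pole fluorescence
  identities swap with zero lag. The default pole rule paints a bright
  cluster at the lagging pole and none at the leading pole, emulating a
  lagging-pole protein.
* **Assays.** Coupled traces follow the closed-form generator equation
  (linear NADH consumption plus optional drift and Gaussian noise; specs
  that would drive A340 below zero are rejected). Malachite plates are
  linear in [Pi]. The kinetics round trip — generate at turnover $r$,
  estimate back — recovers $r$ to 1e-6 relative error for $r$ from 0.1 to
  100 GTP/enzyme/hr at zero noise (tested).
* **Presence/absence.** The reference profile is Bernoulli; each other gene
  matches the reference per genome with its co-occurrence probability, so
  expected similarity is controlled.

What the generators do **not** emulate: point-spread blur and diffraction,
shot noise (noise is Gaussian, not Poisson), cell curvature and segmentation
errors, photobleaching, cell division or track occlusion, coupled-assay lag
phases and NADH-depletion nonlinearity, and phylogenetic structure among
genomes. Passing the recovery tests therefore demonstrates correctness of
the quantification logic under the stated statistical model — not
robustness to every artifact of real microscopy.

## Problem sizes and test design

The suite runs in well under a minute on one CPU: population-level checks
use 30–200 cells per scene, time-lapses use 4–60 cells at 21–31 frames,
kinetic traces 121 points, and co-occurrence panels 100–400 genomes. The
population prevalence-recovery checks use n = 200 cells with a ±6-point
band (the binomial 95% envelope at that n); deterministic assay recoveries
use a 1% band. Hand-built single-cell fixtures with exactly known
cytoplasmic mean and SD (alternating ±x values) pin the cluster-calling
arithmetic to its defining inequalities without any generator in the loop.

## Known limitations

* The reversal detector cannot resolve direction changes whose runs are
  shorter than the displacement gate; with the default gate of one cell
  width and default speeds this means events closer than ~2 frames are
  merged. The ground-truth comparisons condition on resolvable spacing.
* Cluster detection assumes one cluster per pole and no mid-cell clusters;
  mid-cell signal is counted as cytoplasm and raises the detection
  threshold.
* Specific-activity conversion assumes the effective optical path is known;
  plate-reader paths vary with well volume, and a mismatched `path_length`
  scales all rates by a constant factor.
* `fraction_moving()`'s 0.5 px/interval threshold is a convention, not a
  measurement; report it alongside results.
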