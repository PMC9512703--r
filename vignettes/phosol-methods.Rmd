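---
title: "Models and methods behind phosol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

`phosol` analyzes differential-detergent solubility proteomics aimed at
biomolecular condensates. Cells are lysed under a mild detergent (NP-40),
which leaves higher-order assemblies such as condensates intact and
pelletable, and in parallel under a strong denaturing detergent (SDS),
which solubilizes essentially everything. For every protein (or
phosphopeptide) and replicate, the log-ratio

S = log2(NP-40 intensity) - log2(SDS intensity)

measures how much of that feature is in a soluble state: S near 0 means
predominantly soluble, strongly negative S means a substantial insoluble
subpool. Running the same pair of extractions on RNase-treated lysate and
taking

RBF = S_preserved - S_digested

isolates the RNA-dependent part of that insolubility: a negative RBF
means the feature became more soluble once RNA was digested, i.e. its
insoluble pool was RNA-bound.

Phosphorylation is substoichiometric, so the total protein measurement is
dominated by the unmodified proteoforms and serves as their proxy.
Enriched phosphopeptides are compared against their parent protein: a
phosphopeptide with S significantly above its parent marks a
phosphorylation event enriched in the soluble subpool, and vice versa;
the same comparison on RBF separates events that facilitate or repress
RNA association.

# Normalization on a calibration subset

Technical variation is removed before any test. Crucially, the
normalization parameters are fitted only on a calibration subset of
features whose raw mean NP-40/SDS ratio lies in [0.8, 1.2] — the
predominantly soluble population, for which NP-40 and SDS signals should
agree. Fitting on all features would absorb genuine insolubility into the
per-sample scale factors; `tests/test-normalization.R` demonstrates the
induced bias on a half-insoluble simulated proteome.

The model is the contract of a variance-stabilizing normalization, not a
re-implementation of any specific package's estimator: a per-sample scale
(the per-sample median of calibration intensities, centred to geometric
mean one, which makes calibration medians exactly equal across samples
after normalization) followed by a shared generalized-log transform
`glog2(x, c) = log2((x + sqrt(x^2 + c^2)) / 2)`. The parameter `c` is
chosen from a small candidate grid to flatten the variance-versus-mean
trend of the calibration features (|Spearman correlation| of row means
vs row standard deviations), taking the smallest `c` within 0.02 of the
optimal trend statistic. On clean data the objective is flat and `c`
resolves to 0, so the transform reduces to an exact `log2` and planted
effects pass through the entire pipeline to machine precision — the basis
of all zero-noise exactness tests. A pure median-scaling mode
(`method = "median"`) is provided for exactness and idempotence checks;
glog with `c > 0` is intentionally not idempotent on its own output.
Whether one transform per sample or per detergent group is fitted was an
open design point; per-sample is implemented, matching the factual
observation that reporter channels differ individually.

# Moderated differential testing

With three replicates, per-feature variance estimates are unstable. The
moderated t shrinks each feature's residual variance s_g^2 toward a
common prior: assuming s^2 ~ s0^2 F(d, d0), the hyperparameters (d0,
s0^2) are estimated by the method of moments on log s^2 (digamma /
trigamma moment equations, trigamma inverted by Newton iteration), and
the posterior variance (d0 s0^2 + d s^2) / (d0 + d) feeds a t statistic
with d + d0 degrees of freedom. If the spread of log-variances does not
exceed its sampling expectation, d0 is infinite and all features share
s0^2. Forcing `prior_df = 0` recovers the ordinary t exactly (tested to
1e-9), and the whole fit reproduces the reference empirical-Bayes
implementation to 1e-6 on shared data (tested against limma as an
independent oracle; limma is a test-time dependency only).

Peptide-versus-protein comparisons are paired by replicate index: the
same TMT plex measures both, so the per-replicate difference removes the
replicate effect. Calls use |log2 FC| > 0.5 and Benjamini-Hochberg
adjusted p < 0.01. Two source-text discrepancies are resolved in favour
of the Methods-section values and exposed as configuration: the
phosphopeptide call threshold (0.01, not the 0.1 that appears once in the
running text) and the insolubility effect gate (0.5 log2 units; "at
least 30% lower" corresponds to log2 ≈ -0.514 and is treated as the same
rule at printed precision).

# Protein classes and phosphosite categories

A protein maintains an insoluble subpool iff its preserved-lysate S is
significantly below zero at the thresholds above; it is RNase-sensitive
iff it additionally gains solubility significantly upon digestion
(negative RBF effect), and RNase-insensitive otherwise. The simulator's
default class mixture (0.815 / 0.055 / 0.135, renormalized from the
published rounded percentages, which sum to 100.5%) plants exactly this
world.

Phosphosites inherit calls from every peptide covering them, and the
rules are deliberately conservative: an axis label (`soluble` /
`insoluble`, `facilitates_RNA` / `represses_RNA`) is assigned only when
at least one supporting peptide is significant and all significant
peptides agree in direction; any conflict among significant calls yields
`ambiguous`; `not_changing` requires no significant peptide on either
axis. A peptide that is non-significant but opposite in sign does not
create a conflict — "similar trends" is read as agreement among
significant calls, flagged here as an interpretation. On the RNA axis,
`facilitates_RNA` means significantly more RNA-bound, i.e. a negative
RBF log2 FC; the sign convention is pinned by planted-effect simulations.
Peptides whose site localization probability is below 0.75 contribute an
ambiguous-location site group (e.g. `S218|T219`) instead of a single
residue.

# Sequence physicochemistry

Site neighborhoods are 31-residue windows (±15 around the site). Windows
at a terminus are clipped, never padded — properties are computed over
the actual residues; a terminal-anchored mode slides the window inward
instead, reproducing "the last 31 residues" usage for C-terminal
clusters. Charged residues are D/E (−) and K/R (+); histidine is treated
as uncharged (configurable), following the charge-patterning literature.
A phosphoresidue counts as one charged residue for FCR and contributes
−2 charge units to the net-charge sum for NCPR (two negative charges per
phosphogroup at physiological pH), so six phosphoserines in a 31-mer with
four basic residues move FCR from 4/31 ≈ 0.129 to 10/31 ≈ 0.323 and NCPR
to (4 − 12)/31 ≈ −0.26 — the package's worked example.

Kappa measures charge-patterning: for blob sizes 5 and 6, the squared
deviation of blob charge asymmetry sigma = (f+ − f−)²/(f+ + f−) from the
sequence-global value is averaged (delta), normalized by the maximal
delta over rearrangements of the same composition, and the two blob
sizes are averaged. delta_max is computed by exhaustive enumeration when
the composition admits at most 20,000 distinct arrangements (this covers
every sequence the short-sequence oracle checks) and otherwise by the
best padded-block construction — the two charge blocks with the neutral
residues split around and between them in all ways — refined by
pairwise-swap hill climbing. Even refined constructions can slightly
underestimate the true extremum for neutral-rich compositions (a known
property of this parameter; reference implementations can report values
above 1), so kappa is clipped to [0, 1]. Kappa is undefined (NA, never
0) when the window has no charges or when its composition admits no
patterning variation.

Disorder is called by the charge-hydropathy criterion: mean absolute net
charge above `2.785 * <H> - 1.151`, where `<H>` is Kyte-Doolittle
hydropathy rescaled to [0, 1] and smoothed over a 5-residue sliding
window; points exactly on the line are ordered. Whether the mean net
charge enters as an absolute value was unstated in the source; the
absolute value of the mean is used.

# Enrichment and activity

Over-representation is the upper-tail hypergeometric probability of the
observed overlap, sets intersected with the user-supplied background
first, BH-corrected across sets; annotation content (GO, kinase-substrate
compendia) is user-supplied — only the engine is in scope. Phosphosite
activity per perturbation condition is a Z-test of the subgroup mean
against the overall fold-change distribution,
`z = (mean_sub - mean_all) / (sd_all / sqrt(n_sub))`, reported as signed
−log10 p with a significance threshold of 2. The standard-error form was
chosen over `sd_all` alone because that is how Z-tests are used in the
kinase-activity literature the procedure mirrors; a permutation null is
provided as a sensitivity check. Conditions with fewer than 5 mapped
subgroup sites are untestable (NA), never zero.

# Imaging

Nucleolus partitioning uses a label mask (segmentation itself is out of
scope; a clearly non-faithful Otsu fallback is bundled as plumbing). The
nucleoplasmic reference for each nucleolus is a rim of pixels whose
Euclidean distance to the labelled region lies in (inner − 1, outer]
(defaults 1 and 6 px); rims exclude all labelled pixels and overlapping
rims go to the nearer label — the distance semantics are anchored by a
brute-force per-pixel oracle in the tests, since the original ring tool
is unspecified. Background is the mean of a user-placed ROI outside the
cell and is subtracted from both means before K = (nucleolus − bg) /
(rim − bg). Nucleoli pass filters only above 1,000 px² and with mean
intensity above 20x background (the published absolute intensity gates
are instrument-specific and not reproduced); K is still reported whenever
its arithmetic is defined, with `passed_filters`/`reason` carrying the
gates, because the source's own worked arithmetic computes K for a
background of 50 that would fail a literal 20x gate. The nuclear
coefficient of variation is sd/mean of background-subtracted pixels,
sample (n − 1) standard deviation by default.

# The synthetic world

The generator states one world and the tests live in it: lognormal
multiplicative noise on intensities (additive Gaussian on log2, default
sd 0.15 — the source gives no noise magnitude, so this is a calibration
choice held fixed), class fractions 0.815/0.055/0.135, insoluble effect
−1 log2, RNase rescue +1, three replicates, baselines log-uniform over
2^14..2^22, substoichiometric peptide occupancy 1-20%, QC failures
planted by drawing signal-to-interference below 0.5 for a configured
fraction. One global seed expands into per-stage child seeds by a fixed
multiplicative-hash derivation, so stages reproduce independently.

What the generator does not emulate — and therefore what a green test
does not establish: isotopic interference and ratio compression,
chromatographic missingness beyond missing-at-random, correlated noise
across peptides of one protein, real phosphosite localization ambiguity
structure, and cellular image texture (nucleoli are noiseless or
Gaussian-noised disks). Recovery rates measured here are upper bounds on
real-data performance; the published dataset-level counts depend on the
deposited MS data and are deliberately never asserted.

# Known limitations

- The normalization is a contract-level stand-in for the published
  variance-stabilization estimator; on low-intensity-dominated data the
  two can differ more than on TMT reporter data.
- kappa beyond the enumeration limit relies on a refined construction
  (see above); values are exact for all enumerable compositions.
- The pulldown comparison takes per-replicate medians over interactors
  before the two-sample t-test; the alternative per-protein reading of
  the source is available as `mode = "per_protein"`.
- Images are plain matrices serialized as TSV; no binary image formats
  are read or written.
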