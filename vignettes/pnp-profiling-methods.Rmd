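---
title: "Methods: chemical diversity and cell-painting profile analysis of pseudo-natural product collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical diversity and cell-painting profile analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpcpa)
```

## Scope

Pseudo-natural products (PNPs) are synthetic compounds that fuse fragments
of biosynthetically unrelated natural products. Characterizing such a
collection asks two questions: is it *chemically* diverse (different
fragment combinations give structurally distinct classes while each
subclass stays homogeneous), and is it *biologically* diverse (the classes
induce distinct morphological phenotypes in a cell painting assay, CPA)?
`pnpcpa` implements both tracks: fingerprint similarity, 3D shape, QED and
NP-likeness scoring, and a descriptor PCA on the chemistry side; robust-z
normalization, induction, biosimilarity, median biosimilarity percentages
(MBP), profile PCA with a cluster-separation score, and phenotypic
fragment-dominance classification on the biology side. A seeded plate
simulator with planted ground truth makes every stage testable without
external data.

## Chemical track

### Circular fingerprints and count-Tanimoto

Subclass homogeneity and inter-subclass diversity are summarized with
Tanimoto similarities of circular fingerprints: count fingerprints at
radius 2 (ECFC4-style) as the primary measure and 1024-bit fingerprints at
radius 3 (ECFP6-style) as the cross-check of a different design. No
installed R package provides Morgan-style fingerprints, so the hashing
scheme is authored here and fixed for reproducibility: each heavy atom
starts from the invariant tuple (atomic number, heavy degree, total bond
order, implicit hydrogen count, ring flag) hashed with a polynomial hash
modulo $2^{31}-1$; each iteration rehashes an atom's identifier together
with the *sorted* list of (bond order, neighbor identifier) pairs, which
makes the result independent of input atom ordering. Atoms stop emitting
identifiers once their environment no longer grows. The scheme is
deterministic across sessions; it is *not* bit-compatible with other
toolkits, so absolute similarity values differ from those other software
would print, while the intra/inter contrast structure is preserved.

Count-Tanimoto uses the standard generalization
$\sum_k \min(a_k, b_k) / \sum_k \max(a_k, b_k)$ over the key union.

The pooled intra-subclass median is the median of the *union* of
within-subclass pairs (subclasses of size one are excluded with a
warning); per-subclass medians are also returned so the alternative
median-of-medians reading stays recoverable. Both summaries are invariant
to compound order and label renaming, which the test suite asserts.

### Shape, QED, NP-likeness, descriptors

**PMI/NPR.** Conformers come from OpenBabel's rule-based 3D builder with
force-field cleanup. That builder is deterministic, so a single embedding
is used; `n_conformers` and `seed` are recorded as provenance rather than
driving a stochastic search (no installed R route exposes a seeded
multi-conformer generator, and a deterministic embedding keeps the shape
coordinates exactly reproducible). The inertia tensor is mass-weighted
with standard atomic weights by default; unit weighting is available via
`mass_weighted = FALSE` since both conventions appear in shape analyses.
Normalized ratios `npr1 = I1/I3`, `npr2 = I2/I3` place each molecule in
the rod-disk-sphere triangle; `npr1 + npr2 >= 1` is asserted for every
processed molecule.

**QED.** The eight properties (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM,
ALERTS) pass through the published asymmetric-double-sigmoid desirability
functions (`qed_params()`) and are aggregated as the exponential of the
mean log desirability — the unweighted geometric mean; desirabilities are
floored at $10^{-6}$ before logs. Property calculators are OpenBabel's
(logP, TPSA, HBA, HBD, MW); rotatable bonds use the simple rotor
definition (acyclic single bonds between non-terminal heavy atoms, amides
not excluded); ALERTS counts matches against a compact curated alert
SMARTS list (16 classic reactive/promiscuous motifs) and is
user-extensible. Because the property calculators and the alert list
differ from other implementations, absolute QED values are comparable
within a run, not across toolkits.

**NP-likeness.** A trainable fragment-frequency scorer: fragments are the
same atom-centered circular environments as the count fingerprint;
contributions are add-one-smoothed log-ratios of occurrence frequencies in
a natural-product versus a synthetic reference collection; a molecule's
score is the occurrence-weighted sum normalized by heavy-atom count,
clipped to $[-5, 5]$. Reference sets are user-supplied; the package ships
only toy stand-ins, so shipped scores characterize relative, not absolute,
NP-likeness.

**Descriptors.** The 17-descriptor vector (heavy atoms, MW, rings,
aromatic rings, aliphatic rings, HBD, HBA, SLogP, TPSA, rotatable bonds,
O, N, halogens, bridgehead atoms, fraction sp3, Lipinski violations, Veber
violations) feeds a standardized PCA (`prcomp`, constant columns dropped
with a warning). Ring counts use the cyclomatic number with a
GF(2)-greedy smallest-ring basis; bridgeheads are shared-path endpoints of
ring pairs sharing at least two bonds (so fused systems like decalin count
zero and bridged systems like norbornane count two). Formal charges are
not modelled by the implicit-hydrogen valence rules — a documented
limitation acceptable for the neutral molecules this package targets.

## Biological track

### Normalization, induction, biosimilarity

Each plate is normalized per feature against its own DMSO control wells:
$z = (x - \mathrm{median}_{DMSO}) / (1.4826\,\mathrm{MAD}_{DMSO})$.
Features with zero control MAD carry no spread information; their z-scores
are set to 0 and the feature is flagged. Replicates (default 3, shifted
layouts) are aggregated by the per-feature median before any comparison —
chosen for robustness over correlating replicate-level vectors, and
configurable by operating on un-aggregated wells.

*Induction* is the percentage of features with $|z| \ge z^*$; the
significance threshold $z^* = 3$ on robust z-scores is a declared default,
not asserted to be the only reasonable reading of "significantly changed".
*Biosimilarity* is derived from the correlation distance $d = 1 - r$
between two full profiles: $100\,(1 - d) = 100\,r$, Pearson, clipped at 0
so percentages live in $[0, 100]$. *MBP* is the median of a
cross-similarity comparison: over off-diagonal cells for a
self-comparison ("within"), over all cells for a two-set comparison
("between").

### Profile selection and the PC1-induction artifact

Profiles spanning a wide induction range make the first principal
component track overall activity strength rather than phenotype.
`select_profiles()` therefore picks, per compound, the concentration whose
induction falls in a window (default 20-40%); among qualifying
concentrations the one closest to the window midpoint wins, with exact
ties going to the *lower* concentration (prefer the weaker perturbation at
equal information). `profile_pca()` reports $|r(\mathrm{PC1},
\mathrm{induction})|$ as the diagnostic; the `wide_induction` scenario
demonstrates both the artifact (high $|r|$ over a 5-70% spread) and its
suppression after windowing.

### Cluster separation and the dominance rule

Published analyses judge "the classes form clusters in PCA" visually; the
package operationalizes it as the mean silhouette width of the subclass
labels on the 3-component scores, with `clustered = silhouette >= 0.25`.
The cutoff is a declared default, logged with every call; singleton labels
are excluded with a warning.

A shared fragment is classified from two signals: the cross-subclass MBP
(median of per-subclass-pair MBPs, so large subclasses do not dominate;
the pooled-cells aggregation is also emitted) and the clustered flag.
Low MBP (< 75%) and/or clustering mean the combinations set the phenotype:
**non-dominating**. High MBP without clustering means the shared fragment
dictates the phenotype: **dominating**. When the MBP lies within one point
of the threshold and the two signals conflict, the call is
**maybe_non_dominating** — a codified reading of comparisons that sit at
the cutoff; real analyses resolve such conflicts case by case, so the
conflict is flagged in the output rather than hidden. The 75% threshold,
the one-point band and the silhouette cutoff are all configurable.

`evaluate_predicted_class()` closes the design loop: a new class built
from non-dominating fragments is expected to be "unique" (all average
MBPs against fragment-sharing reference groups below threshold), one
reusing a dominating fragment "redundant" with that fragment's group.

## The synthetic generator

`simulate_assay()` draws, from one seed: a per-feature baseline, one
signature vector per fragment ($\mathcal{N}(0,1)$ scaled, optionally
sparsified), one pair-interaction signature per subclass, and shared
low-rank jitter directions. A compound's true mean profile is

$$\mu = \mathrm{potency}\,\big(\textstyle\sum_f w_f s_f + \gamma\, s_{pair}\big) + \sum_{k=1}^{K} a_k v_k,$$

and wells are $\mu \cdot c_{mult} + \mathcal{N}(0, \sigma)$, DMSO wells
noise only. All unassigned wells of each plate are DMSO controls; layouts
rotate between replicates. Two modelling choices matter:

* **Homoscedastic Gaussian noise** makes the DMSO null approximately
  standard normal after robust-z normalization, so the induction null rate
  has the analytic reference $2\Phi(-3) = 0.27\%$ per feature.
* **Low-rank jitter** (shared directions $v_k$, per-compound coefficients
  $a_k$) reproduces the *correlated* biological variability of real
  profiles. With i.i.d. per-feature jitter, within-class variability would
  be invisible in a 3-component PCA and any between-class contrast would
  cluster perfectly; low-rank jitter puts within-class spread into the
  same low-dimensional space the PCA sees, which is what lets a dominating
  fragment show high MBP *without* clustering, as observed in real
  collections.

### Null calibration and control-well counts

Estimating the control median and MAD from finitely many wells inflates
the $|z| \ge 3$ null rate (Jensen's inequality applied to the convex tail
function of the estimated scale): at 16-96 controls per plate the mean
null induction computes to roughly 0.5-3%, far from the analytic 0.27%.
The `pure_null` calibration scenario therefore dedicates most of each
384-well plate to controls (284 DMSO wells, 100 treatments per plate) and
uses single-replicate plates, since median-of-3 aggregation collapses the
single-well null tail by three orders of magnitude and would make the
analytic reference meaningless. The acceptance script recomputes the
resulting mean null induction (about 0.35% at these settings) at run time.

### Preset calibration

The planted-dominance presets were fixed from the variance model before
freezing, not tuned against test outcomes. With dominant weight
$w_{dom} = 4$, partner weights 0.3, interaction 0.3, jitter rank 8 with
coefficient SD 0.5 and unit noise, the expected profile correlation shared
across subclasses is $16 / (16 + 0.18 + 2 + 0.45) \approx 0.86$ (MBP
$\approx 86\%$, comfortably above 75) while the between-subclass contrast
variance ($\approx 0.09 F$) stays below each jitter eigenvalue
($\approx 0.25 F$), so PCA shows no class clusters: a dominating
fragment. Swapping the weights (fragment weights 0.5, interaction
$\gamma = 4$) moves the shared variance to the pair term: cross-subclass
correlations collapse and the interaction contrast dominates the PCA —
a non-dominating shared fragment. The `wide_induction` series uses 250
compounds with a potency gradient so that the 20-40% window retains
enough profiles (~50) for the windowed PC1 diagnostic to be statistically
stable.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 579 features throughout;
96-well plates with 16-19 treatments for the dominance scenarios (50
seeded runs each); two 384-well plates with 284 controls each for null
calibration (200 compounds); 250 compounds for the induction-window
diagnostic; a 21-molecule deterministic toy collection for the chemistry
modules. All randomness flows from explicit seeds; `simulate_assay()`
restores the caller's RNG state. These sizes were chosen so each
statistical check has adequate power while the full suite stays fast on a
single CPU.

## What passing tests do and do not show

The generator emulates the *structure* the analysis assumes: signatures,
interactions, correlated within-class variability, plate noise,
replicates, shifted layouts. It does not emulate image-derived feature
distributions (skewness, heavy tails, feature redundancy), cell-count
artifacts, toxicity-induced signal loss, or batch effects beyond the
plate level. Recovery of planted dominance therefore validates the
statistical machinery and decision rule, not the biology of any real
collection; absolute fingerprint similarities, QED and NP-likeness values
depend on the documented in-package calculators and are not interchangeable
with other toolkits' numbers. Analyses of real collections additionally
depend on the unpublished details of feature selection and normalization
used when the data were acquired.
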