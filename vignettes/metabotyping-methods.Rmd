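---
title: "Methods: plasma 1H-NMR quantification and inflammatory metabotyping"
author: "nmrMetabotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma 1H-NMR quantification and inflammatory metabotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrMetabotyping)
```

# Overview

`nmrMetabotyping` implements an analysis chain for one-dimensional
^1^H-NMR plasma profiles of prostate-cancer patients: quantification of a
41-signal panel (metabolites, lipid envelope groups, the glycoprotein
inflammation markers GlycA and GlycB, and total protein amides),
unsupervised *metabotype* discovery by accuracy-maximising proximity
learning, rank-based group statistics under Benjamini–Hochberg control,
and double cross-validated PLS-DA.  Because patient-level spectra of this
kind are rarely shareable, the package includes a first-class synthetic
generator that renders full plasma-like spectra with known ground truth;
every downstream stage is validated against that truth.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does
and does not demonstrate about real data.

# Spectral model

## Lineshape

Every narrow resonance is a **Voigt profile**, the convolution of a
Gaussian (standard deviation $\sigma$, in ppm) and a Lorentzian
(half-width at half-maximum $\gamma$):
$$V(x;\sigma,\gamma) \;=\; \frac{\mathrm{Re}\,w(z)}{\sigma\sqrt{2\pi}},
\qquad z = \frac{x + i\gamma}{\sigma\sqrt 2},$$
where $w$ is the Faddeeva function, evaluated with Weideman's rational
approximation (64 terms; relative error far below every fitting
tolerance used here).  The limits $\gamma = 0$ (pure Gaussian) and
$\sigma = 0$ (pure Lorentzian) are special-cased exactly.  The `area`
parameter is the integral over infinite support; note that a Lorentzian
component puts ~1.3% of its mass beyond ±50 half-widths, so finite-window
integrals of strongly Lorentzian lines recover the area only to that
level — a property of the mathematics, not of the implementation.

A **multiplet** is a sum of Voigt components with binomial amplitude
ratios (1:1, 1:2:1, 1:3:3:1) spaced by $J/\nu_0$ ppm, with
$\nu_0 = 600.13$ MHz, the proton Larmor frequency of the emulated
spectrometer.

## The 41-signal panel

`defaultSignalLibrary()` ships 41 uniquely named signals: 33 fit-mode
metabolites with common plasma chemical shifts (including the
$\alpha$-glucose anomeric doublet at 5.24 ppm, histidine, mannose and the
unidentified aromatic singlet at 7.14 ppm), five broad lipid(protein)
envelope groups modelled as wide Lorentzians at 0.87, 1.28, 2.02, 2.76
and 5.30 ppm, and three integration-mode signals: GlycA
(2.005–2.054 ppm), GlycB (2.054–2.086 ppm) and the protein amide region
(6.000–10.000 ppm).  The panel *identities* are a documented stand-in —
the published analysis names only a handful of its 41 features — but the
panel *mechanics* (count, uniqueness, fixed Glyc/amide regions, fit vs
integrate dispatch) are the tested contract, and any `SignalLibrary` can
be substituted.

The envelope component under the Glyc region is given a half-width of
0.20 ppm: the N-acetyl glycoprotein signals ride on a lipoprotein
background that cannot be separated from them by fitting, which is
precisely why the markers are quantified by region integration above a
local baseline; a background this broad is removable by a chord to within
a few percent, which matches that description of the measurement problem.

## Generator

`generateSpectrum()` renders each signal at a requested area with
class-specific linewidths (narrow mixed Gauss/Lorentz metabolite lines,
broader Gaussian-dominated Glyc composites, a very broad two-Gaussian
amide hump), applies one global chemical-shift offset to *all* positions
(emulating miscalibration; the glucose doublet then sits at
5.24 + offset), and adds optional smooth baseline and i.i.d. Gaussian
noise.  The default grid spacing, 2.5×10^-4^ ppm, mirrors the digital
resolution of a ~128k-point processed spectrum over a ~30 ppm sweep.
The default noise SD is 0.5% of the tallest metabolite peak of a
noiseless base-area render.

`generateCohort()` draws per-sample true areas as
$\mathcal N\!\big(b_s(1 + c\,\delta_{gs}),\; (c\,b_s)^2\big)$ truncated at
zero, where $b_s$ is the signal's base area, $c = 0.15$ the within-group
coefficient of variation, and $\delta_{gs}$ the group shift in SD units
from the effect template.

## Effect template

The planted metabotypes mirror the published portraits: IV (the
inflammatory metabotype) has GlycA and GlycB at +3 SD, mannose and the
7.14 ppm signal elevated, histidine and protein amides reduced, and a
broad −1.5 SD reduction across the amino-acid panel with mild
ketone-body/creatinine elevations of a catabolic state; III couples
elevated GlycB with a strong reduction of the lipid envelope and
lipid-associated metabolites; II is the opposite lipid phenotype (high
VLDL-like envelope, BCAA/aromatic amino-acid and lactate elevations of an
insulin-resistant, higher-adiposity state, mildly reduced GlycB); I
carries mild opposite shifts of the least-inflamed state.

A design point worth stating explicitly: the clustering input is
autoscaled, and autoscaling absorbs between-group variance, so *no single
feature can contribute more than about 2 SD* of standardized group
separation no matter how large its raw shift.  Separability therefore
comes from signature *breadth*.  With the shipped defaults all pairwise
group-mean separations in the prepared feature space are ≈5–8 pooled SD
units — comfortably separable, as a four-group metabotype structure that
is visible in a score plot must be, yet far from trivial in a ~35
dimensional noise background.

The generator also emits clinical covariates drawn consistently with
metabotype severity (group IV almost entirely very-high-risk or
metastatic), a synthetic lipoprotein subclass panel (VLDL/HDL particle
numbers, Apo-A1/A2, LDL-1/LDL-2 triglycerides with the IV-direction
effects), and CRP values positively associated with GlycA.  These tables
are synthetic stand-ins: their marginal distributions are plausible but
not calibrated to any real assay.

# Preprocessing

**Calibration.**  The chemical-shift axis is referenced to the
$\alpha$-glucose anomeric doublet: within a 5.10–5.40 ppm search window,
local maxima are refined by parabolic interpolation and must exceed the
window median by 5 noise MADs (noise estimated from the 9.5–10 ppm
region, which is essentially signal-free).  If the two tallest maxima are
separated by 0.004–0.010 ppm — the ~3.8 Hz doublet at 600.13 MHz spans
0.0063 ppm — their intensity-weighted centroid is the reference,
otherwise the single tallest peak.  The axis is shifted so the reference
sits at exactly 5.240 ppm and intensities are linearly re-interpolated
onto the original grid; at the default grid density the interpolation
error is negligible against all quantification tolerances.  The centroid
(rather than one doublet arm) is used because it is first-order
insensitive to differential arm heights.

**Baseline.**  Residual slowly varying baseline is removed by asymmetric
least squares: minimise
$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$ with
$w_i = p$ above the current baseline and $1-p$ below, defaults
$\lambda = 10^7$ (for the default grid), $p = 0.01$, 10 reweighting
iterations.  Isolated peak areas survive to within a few percent; the
correction is nearly idempotent and commutes with intensity scaling.

# Quantification

**Fit-mode signals** are fitted in a window of ±`searchWindow`
(default 0.015 ppm) around the outermost multiplet components by bounded
Levenberg–Marquardt least squares of: local linear baseline + multiplets
with one shared centre shift (bounded to ±0.01 ppm of the library
position) and shared $\sigma, \gamma \in [10^{-5}, 0.02]$ ppm.
Initialisation comes from the tallest local maximum in the window; up to
five deterministic multi-start perturbations are tried on
non-convergence, and a non-converged fit is reported with
`converged = FALSE` and masked `NA` downstream — never an exception.

Weak narrow lines sit on a flat likelihood ridge: the free baseline can
absorb Lorentzian tail mass while $\gamma$ collapses, biasing areas low
by 15–25% at realistic noise.  The package breaks the ridge the way the
physics suggests: the magnet shim fixes one effective lineshape for all
small-molecule signals, so `estimateLineWidths()` fits a few strong
reference peaks (glucose anomeric doublets, lactate, alanine) with free
widths and `buildFeatureTable()` then constrains every metabolite fit to
±30% of those shared widths.  This removes the bias without fixing the
lineshape outright.

**GlycA and GlycB** are quantified by trapezoid integration above one
shared local-baseline chord fitted across their combined region
(2.005–2.086 ppm), with 0.010 ppm anchor windows at 1.990–2.000 and
2.091–2.101 ppm (20%-trimmed mean intensity in each anchor).  Sharing the
chord keeps GlycA + GlycB additive.  **Protein amides** are a plain
integral of 6–10 ppm, with no local baseline, matching the stated
measurement definition of that feature; the region is configurable.
Negative integrals are reported as-is so noise-only values remain
unbiased for the statistics.

# Metabotype discovery

The feature matrix is median-imputed, transformed by
$\log(1 + x/\mathrm{median})$, autoscaled, and the three inflammation
markers (GlycA, GlycB, protein amides) are excluded from the clustering
input by default, so that the metabotypes are discovered from the
metabolome and the markers can be read out afterwards as independent
characterisations.

**Proximity learning** follows the knowledge-discovery-by-accuracy-
maximisation idea: over 100 random restarts, a label assignment is
refined by repeated 10-fold cross-validated self-prediction with a
k-nearest-neighbour classifier (k = 10) — fit on 90%, predict the held
10%, adopt the predictions — and the final labels of each restart are
accumulated into co-classification frequencies.  Four implementation
choices matter and were each adopted after the obvious alternative
failed a measurable contract:

* *Initial labels are a permutation* (one distinct class per sample).
  Random labels over a small class pool let far-apart clusters coalesce
  onto one label by chance, which inflates between-cluster proximity.
* *Votes are discounted linearly by neighbour rank* (triangular kernel).
  Plain majority lets a couple of far, potentially cross-cluster
  neighbours win early ties; inverse-distance weights degenerate into
  1-NN label propagation, which fragments clusters into stable pockets.
* *Folds are re-randomised every refinement cycle.*  With fixed folds the
  label-propagation basins are deterministic and metastable sub-cluster
  pockets survive; refolding anneals them out (measured within-cluster
  proximity rises from ~0.87 to 1.0 on 10+10 two-blob data).
* *The best-accuracy label snapshot is kept* and refinement runs until
  labels are stable, letting the dynamics pass through transient
  accuracy dips while coarsening.

**Embedding, tree, k.**  The dissimilarity $1-P$ is embedded by
classical metric MDS.  The familiar 2-D score plot is retained as the
reported representation, but clustering and model selection run in a
fuller embedding (up to `kmax + 1` dimensions): $k$ mutually equidistant
clusters need $k-1$ dimensions, and a learned proximity that saturates
towards a binary block matrix produces exactly that geometry — in 2-D,
two of four equidistant clusters land on top of each other.  A Ward
(D2) dendrogram is cut at each $k \in [2, 10]$ and the median silhouette
width (Euclidean distances in the clustering embedding) scores each
partition.  The chosen $k$ is the *smallest* k whose median silhouette is
within 0.01 of the maximum: sub-0.01 differences in median silhouette are
not meaningful evidence for extra clusters, and without this parsimony
rule float-level jitter inside degenerate-tight clusters can promote a
spurious larger k.

**Severity ordering.**  Clusters are renumbered I..k by ascending
proportion of very-high-risk plus metastatic members, ties broken by
ascending median PSA, then by descending size, so the most aggressive
metabotype always carries the largest numeral.

# Statistics

Numeric contrasts use the two-sided Wilcoxon rank-sum test (exact
enumeration when the pooled size is ≤12 without ties, otherwise the
normal approximation with tie and continuity correction) and the
Kruskal–Wallis test; categorical rows use Fisher's exact test (exact
hypergeometric for 2×2; seeded Monte-Carlo with 100,000 draws for larger
tables — the network algorithm is out of scope); correlations are
Spearman's $\rho$ on mid-ranks with the t approximation.  Multiple
testing across features is controlled by Benjamini–Hochberg with the
shipped significance threshold FDR < 10%.

Median confidence intervals use binomial order statistics — the smallest
symmetric rank pair with ≥95% coverage — which at small n widens towards
the sample range, matching the wide printed intervals of small clinical
subgroups; a sample too small for nominal coverage returns the full range
with a flag.  Censored PSA entries (">5000") are parsed as the cap value
with a censoring flag; rank-based tests are unaffected by any cap at or
above the largest uncensored value.  Percentages are rounded to one
decimal, half away from zero, matching the printed table convention.

# PLS-DA

`plsFit()` is NIPALS PLS2 on autoscaled X against centred one-hot class
indicators; class prediction is the argmax of the predicted indicators
(ties resolved to the first class and flagged).  `doubleCV()` nests
model selection inside validation: outer 10-fold CV yields held-out
predictions; within each outer training set an inner 10-fold CV selects
the number of components (grid 1–5, ties to fewer) by accuracy.
Accuracy is pooled over outer folds; its 95% interval is the 2.5/97.5
percentile over repeated double-CV runs with reshuffled folds (default
20 repeats) — a reproducible, assumption-free reading of a
"95% interval" on a cross-validated accuracy.  $R^2 = 1 -
SS_{res}/SS_{tot}$ on the training fit at the modal selected component
number; $Q^2 = 1 - PRESS/SS_{tot}$ from the held-out predictions.  Folds
shrink with a warning when the smallest class is smaller than the fold
count; singleton classes are an error.

# Clinical data model

Records carry PSA (with ">"-censoring), Gleason primary/secondary,
clinical T stage tokens (T1c..T4, "T3/T4" accepted and treated as
T3-or-worse), metastasis, ancestry, dates, and derived follow-up days
(collection to last visit, or to death when recorded; exact proleptic
Gregorian day counts).  The NCCN-style risk mapper is deliberately
simplified — full NCCN v2.2020 needs biopsy-core counts and PSA density
that patient-level tables of this kind do not print: metastasis
dominates; Gleason ≥9 or any T3/T4 gives very-high; Gleason 8 or
PSA > 20 gives high; Gleason 3+4/4+3, PSA 10–20 or T2b/T2c gives
intermediate; else low.  A bare "T3" is treated as very-high-qualifying,
which reproduces every printed label of the shipped 14-patient fixture.
The mapper is documented as a simplification, not as NCCN-faithful.

# Problem sizes and what the validation shows

The shipped tests validate, among others: area recovery of isolated and
overlapping fits at zero and realistic noise; GlycA/GlycB recovery within
3% over the lipoprotein envelope across 50 rendered spectra; calibration
recovery of ±0.05 ppm offsets within 0.001 ppm; four-metabotype recovery
(k = 4, adjusted Rand ≥ 0.9) in ≥90% of 50 independent cohorts of
15/group; FDR false-flag control on 200 null cohorts of 100 features;
chance-level double-CV accuracy under permuted labels and ≥85% accuracy
on the planted inflammatory-vs-rest contrast.  These sizes were chosen so
the whole suite runs comfortably on a single CPU.

What passing these tests does **not** show: that real plasma spectra —
with pH-dependent shift drift, water suppression artefacts, protein
binding effects on linewidths, and peak identities beyond the default
panel — would be quantified with the same accuracy; that real patient
metabotypes are as cleanly separated as the planted ones (the published
cohort's headline statistics on real samples are not reproducible without
the underlying data); or that the simplified risk mapper generalises
beyond the printed fixture.  The synthetic validation demonstrates the
*correctness of the machinery* under a known truth, not field
performance.

# Known limitations

* The fitter models each signal independently; heavily overlapped
  neighbours are handled by the local baseline, not by joint fitting.
* The Bruker reader is a best-effort convenience for processed 1D data
  (`1r` + `procs`); the two-column TSV format is the contract.
* Fisher's exact test above 2×2 is Monte-Carlo, not the network
  algorithm.
* The KODAMA-style proximity is this package's own implementation of the
  published idea; it is validated against its contracts (block structure,
  duplicate co-classification, cluster recovery), not against any
  external implementation.
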