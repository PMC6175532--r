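---
title: "Quantifying the value of gene-regulation experiments with model ensembles"
author: "infoGEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the value of gene-regulation experiments with model ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

infoGEM formalizes "what do we currently know about this enhancer's
regulatory logic?" as a probability distribution over thermodynamic
sequence-to-expression models, and "how informative was this experiment?" as
the entropy reduction of that distribution after discarding models
inconsistent with the experiment's outcome. This vignette documents the
model, every numerical choice that the construction leaves open, what the
synthetic scenarios do and do not emulate, and the package's known
limitations.

## The thermodynamic readout model

The model maps (enhancer sequence, TF motifs, TF concentration profiles,
parameters) to a predicted expression value per spatial bin.

**Site annotation.** Every window of the enhancer, on both strands, is
scored against each TF's position weight matrix by log-likelihood ratio
(natural log) relative to a declared background composition. Windows scoring
at least a configurable fraction of the maximal attainable score (default
0.5; the synthetic scenarios use 0.7 to keep their site complements small
and interpretable) become annotated sites; a site's relative affinity is
`exp(llr − llr_max) ∈ (0, 1]`. Coordinates are 1-based closed intervals on
the forward strand, the Bioconductor convention; user-facing bins are
likewise 1-based (bin 1 = ventral end).

**Configuration sum.** In bin `b` a site `i` of TF `t` has weight
`q_i(b) = K_t · c_t(b) · rel_affinity_i · atten_t(b)`, where `K_t` is the
TF's binding constant, `c_t(b)` its [0,1]-scaled concentration, and
`atten_t(b)` an optional attenuation factor (below). A configuration is any
subset of sites whose footprints do not overlap — overlapping sites are
sterically exclusive, the standard convention. Its weight is the product of
its site weights times a cooperativity weight `w` for every *adjacent* pair
of bound sites whose TFs form a declared pair and whose footprint gap is at
most 50 bp (configurable). Restricting cooperativity to adjacent bound
pairs keeps the partition function computable by a single dynamic program
over sites sorted by position; the DP is verified against brute-force
subset enumeration in the tests (maximum absolute difference below 1e-10 on
random instances with up to 12 sites). With basal-machinery weight `q_btm`
and per-TF potency `α_t` (activators > 1, repressors ≤ 1), the prediction
is `Z_on / (Z_on + Z_off)` with `Z_off = Σ_c W(c)` and
`Z_on = q_btm Σ_c W(c) Π_{i∈c} α_i`. The empty configuration (weight 1) is
always present, so the prediction is well-defined and equals
`q_btm / (1 + q_btm)` — the basal level — when no site is active.

**Attenuation.** A repressor whose activity is regionally relieved (the
CIC/ERK situation in the neuroectoderm) carries a per-bin mask; in masked
bins its site weights are multiplied by a free parameter `atten ∈ (0, 1]`,
modeling reduced DNA binding rather than reduced potency.

**Goodness of fit.** `sseScore` is the *mean* of squared per-bin
differences between [0,1]-scaled profiles. This normalization makes
threshold percentages scale-free: "error below 10% / 5%" reads directly as
0.10 / 0.05 regardless of the number of bins. The raw-sum alternative would
tie thresholds to bin count; the mean is the package's convention and both
thresholds are configurable.

## Ensemble construction

Free parameters and their default ranges (all strictly positive):

| group | scale | default range | meaning |
|---|---|---|---|
| `K_tf` | log | 0.01–100 | TF–DNA binding constant (dimensionless, relative to reference concentration 1) |
| `alpha_tf` (activator) | linear | 1–50 | activating potency |
| `alpha_tf` (repressor) | log | 0.001–1 | repressive potency |
| `coop_a_b` | linear | 1–20 | pairwise cooperativity weight |
| `q_btm` | log | 1e-4–1 | basal machinery weight |
| `atten_tf` | linear | 0.01–1 | regional attenuation factor |

Log/linear assignments follow the convention that multiplicative
(binding-type) parameters are explored on a log scale and bounded
interaction strengths linearly. The construction pipeline is:

1. **Stratified sampling** — each dimension's range is split into two halves
   on its declared scale and the same number of points is drawn uniformly in
   each of the `2^D` cells, so every corner region of the space is probed.
   For the 13-parameter five-TF configuration at 1000 samples per cell this
   is 8,192,000 models; a budget guard (default 2e6) refuses plans that
   would not fit in memory, and scoring streams in chunks.
2. **Coarse filter** at mean-squared error < 0.10.
3. **Local optimization** — bounded Nelder–Mead (Brent for one-dimensional
   spaces) on unit-cube coordinates
   (log dimensions optimized in log space), out-of-box proposals clamped
   with a smooth quadratic penalty, one restart from the incumbent,
   relative tolerance 1e-10, iteration cap 400 per start. The returned
   model never scores worse than its seed. A `maxOptimize` cap (used at
   desk scale) optimizes only the best-scoring coarse survivors.
4. **Strict filter** at < 0.05.
5. **De-duplication** — two models are duplicates when their
   min–max-scaled vectors differ by less than 1e-3 in max-norm; the
   better-scoring one is kept. This defines "distinct parameter settings".

Identical seed and configuration reproduce the ensemble exactly.

## The distribution over models and its entropy

Parameters are min–max scaled to [0,1] per dimension (degenerate dimensions
map to 0), and the scaled vectors are clustered with `mclust::Mclust`,
which selects the number of mixture components (search range 1–20, wide
enough to bracket plausible cluster counts for desk-scale ensembles) and
the covariance structure by BIC. Each model joins its
maximum-responsibility component; the component covariance, regularized by
adding `1e-6 · I` on the scaled space (small clusters yield singular
estimates otherwise), becomes the cluster covariance `Σ_C`.

The distribution over models is deliberately *not* a kernel density
estimate — ensemble members are local optima grown from uniform seeds, not
i.i.d. draws — and deliberately discounts over-represented regions: every
cluster (read: mechanistic hypothesis) receives equal weight `1/N`, and
within a cluster the `n_C` member-centered Gaussians with shared `Σ_C`
receive equal weight. Gaussians are evaluated on the scaled coordinates,
the same space in which clustering was performed. Discrete model
probabilities are proportional to the full mixture density at each model's
location (all Gaussians contribute, not only the model's own cluster),
normalized per cluster to mass `1/N`.

**Entropy** is `H = −Σ p log10 p`. The base is a package convention;
base 10 makes the single-cluster uniform case read as `log10(n)` and keeps
the maximum-entropy bound `log10(N) + (1/N) Σ log10(n_C)` on a convenient
scale. Entropies are only comparable within one study (one scenario and
ensemble), never across studies.

## Filtering and information gain

An experiment is a perturbation operator plus a machine-checkable
consistency criterion. Perturbations: knockout (zeroes the protein's
concentration profile — both derived profiles for a factor modeled with
split roles, since they represent one protein), site mutagenesis (removes
the strongest-k sites by relative affinity, or explicit positions), and
variant enhancer (replaces the sequence, re-annotates sites). Criteria map
verbal outcomes to numeric windows, all configurable:

- *unchanged*: error to the wild-type profile below the strict threshold;
- *profile match*: error to a given profile below a threshold;
- *peak fraction*: predicted/wild-type peak ratio inside a window (e.g.
  [0.35, 0.65] encodes "reduced to about half", [0, 0.5] "greatly
  diminished");
- *boundary shift*: the outermost crossing of half the profile's maximum on
  the stated side, linearly interpolated between bins, moves by at least a
  given number of bins (default 2) in the stated direction;
- *abolished*: peak at or below a ceiling.

Filtering keeps the consistent models and rebuilds the distribution in
strict order: (a) original cluster labels and covariances retained, (b)
emptied clusters removed and surviving cluster weights re-equalized to
`1/N'`, (c) each surviving cluster's mixture re-centered on its survivors.
The experiment's value is the signed difference `H_parent − H_filtered`;
nothing in the construction forbids a negative value, and clamping would
hide it, so it is reported as computed. Filtering with a deterministic
criterion is idempotent, which makes sequential-gain matrices have zero
diagonals and exposes redundant experiment pairs (both informative alone,
neither informative after the other).

A filtered ensemble that would be empty is an explicit error ("experiment
refutes the entire ensemble") rather than a silent degenerate distribution;
sequential-gain entries whose intermediate ensemble is empty are `NA`.

## What the synthetic scenarios emulate

The generators reproduce *structure*, not sequence identity: bin counts,
regulator roles, parameter dimensionality, and profile shapes. Real
enhancer sequences and curated motifs are not bundled; motifs are synthetic
8-mers (consensus base frequency 0.7, designated second base 0.15) whose
consensus strings are flavored after the cognate factors' known binding
preferences, and enhancers are i.i.d. background with planted site
instances (strong = consensus, medium/weak = one/two second-best
substitutions, so the planted "strong" site always carries its TF's maximal
relative affinity).

- `makeIndLikeScenario`: 50 bins; a ventrally graded activator, a uniform
  activator cooperating with it, a mesodermal repressor, a
  ventral-neuroectoderm repressor, and a uniform repressor attenuated over
  bins 20–28; 13 planted parameters; the target is the planted truth's own
  prediction, peaked at bin 25 with support confined to bins 22–28
  (everything outside below 10% of peak).
- `makeSimLikeScenario`: 25 bins (the ventral half of the axis); DL- and
  TWI-like activators, a SNA-like repressor falling from high to low at bin
  12, and a uniformly expressed factor split into complementary activator
  (mesoderm + mesectoderm) and repressor profiles because the readout model
  does not allow one TF to switch roles along the axis. The target is a
  Gaussian peaked at bin 12 with standard deviation 1.5 bins, chosen so the
  full width at half maximum (≈3.5 bins) matches a domain a few cells wide;
  no printed value for this width exists, so the choice is the generator's.
- `makeToyScenario` (2 TFs, 5 parameters): identifiable; used for
  parameter-recovery tests.
- `makeTwoRepressorScenario` (3 TFs, 7 parameters): the planted truth uses
  two repressors with *nested* expression domains (boundaries at bins 18.5
  and 21), so models using either repressor alone also fit the wild-type
  target within the strict threshold. This is the smallest setting in which
  the ensemble genuinely splits into mechanistic hypotheses and knockout
  experiments carry nonzero information gain — including the signature
  situation where an experiment whose true outcome is "no visible change"
  is still informative.

What passing tests on these scenarios do *not* show: performance on real
enhancers with overlapping, clustered, low-affinity sites; motif quality
effects; measurement noise in expression profiles (targets are exact model
outputs or exact Gaussians); or the behavior of the full 8-million-sample
construction, which the desk-scale runs only down-scale.

## Numerical choices and degenerate inputs

- Ground-truth recovery in tests is asserted at max-norm distance 0.05 on
  unit-cube (declared-scale) coordinates; the identifiable toy recovers the
  truth to within the 1e-3 dedup radius, while ridge-degenerate scenarios
  are only required to contain the truth's functional neighborhood.
- Problem sizes used by the tests and the acceptance script: 2-TF toy at
  250 samples/cell (8,000 models), two-repressor scenario at 100
  samples/cell (12,800 models) with optimization capped at the best 300
  coarse survivors; Monte-Carlo unit-integral check of the mixture density
  with 500,000 points on a 2-D ensemble.
- Site scans skip windows containing N; sequences shorter than the motif
  yield an empty site list, not an error.
- A single-model or zero-spread ensemble clusters to one point-mass cluster
  with covariance `ε·I` rather than invoking the mixture machinery.
- Ties in strongest-site selection resolve to the first annotated site;
  cluster ids follow mclust's component order.
- Peak-fraction criteria on a flat wild-type profile are an error (the peak
  is undefined), as is a cluster whose member densities all underflow.

## Limitations

- The readout implements the direct-interaction configuration-sum model
  only; quenching-range repression modes, occupancy output, and
  multi-enhancer joint fits are out of scope.
- Cooperativity is adjacent-pair only; longer-range chains interact through
  overlapping adjacency, not explicit triples.
- The ensemble is built by uniform sampling plus local optimization, not by
  posterior sampling; cluster-balanced weighting is a modeling choice, not
  a Bayesian posterior.
- Prospective experiment design (expected information gain before running
  an experiment) is not implemented; the package evaluates experiments
  retrospectively.
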