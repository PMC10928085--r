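---
title: "Methods: joint turnover and localization analysis of dual-encoded proteomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint turnover and localization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnloc)
```

## The measurement this package models

A single experiment encodes two orthogonal pieces of information in each
peptide spectrum. At the MS1 level, dynamic SILAC labeling (heavy lysine
+8.0142 Da, heavy arginine +10.0083 Da, started at the same time as any
perturbation) separates the pre-existing ("light", old) and
post-labeling ("heavy", new) pools of every protein, and the relative
intensity of the isotopomer peaks measures how much of the pool was
synthesized since labeling began. At the MS2 level, TMT reporter
channels quantify each peptide across the ten sequential pellets of a
differential-ultracentrifugation fractionation, so that the channel
profile of a protein is a sedimentation fingerprint of its subcellular
compartment. Because light and heavy peptide species are isolated and
fragmented separately, the old and new pools of the same protein get
*independent* spatial profiles — which is what makes it possible to ask
whether newly synthesized protein is trafficked differently from the
pre-existing pool.

## Turnover kinetics

For a peptide with one lysine, the fraction of the pool synthesized
after labeling onset is estimated from integrated MS1 isotopomer areas
as

$$\mathrm{fs} = 1 - \frac{m_0}{m_0 + m_8},$$

and analogously for other K/R compositions (`applicable_offsets()`
enumerates the admissible isotopomers; mixed partial-label peaks such as
m8 on a two-lysine peptide count in the denominator, since any heavy
residue is evidence of post-labeling synthesis). Note the complementary
convention: the quantity `m0 / sum` *decays* from 1; we standardize on
its complement, which *rises* from 0 to the plateau, because both
parameterizations give the identical rate constant and a rise-to-plateau
form matches the fitted model.

Under first-order replacement with complete precursor labeling,
$\mathrm{fs}(t) = 1 - e^{-kt}$. `fit_turnover_rate()` minimizes the
intensity-weighted squared error over $k \ge 0$ with the plateau fixed
at 1. Numerical notes:

* Each observation has a closed-form inversion
  $k_i = -\log(1-\mathrm{fs}_i)/t_i$; because every residual is monotone
  in $k$, the weighted optimum lies between the smallest and largest
  $k_i$. The solver therefore brackets on that interval. An unbracketed
  search is unreliable here: the objective is numerically flat once
  $e^{-kt}$ underflows.
* fs observations are clipped to $[0, 1-10^{-9}]$ before inversion
  (with a warning), and $k$ is capped (default 10 per hour) so fs near 1
  cannot produce unbounded rates.
* The standard error comes from the Gauss–Newton curvature at the
  optimum; single-observation fits report `NA`.

Protein rates are summarized as the median of peptide rates with raw
median absolute deviation (no 1.4826 consistency factor — the MAD is
used descriptively, not as a normal-scale estimator). Half-life is
$\ln 2 / k$. Between-condition comparisons average each peptide's rate
over replicates, keep the ten most intense peptides per protein, report
the median and MAD/median of per-peptide rate ratios, test with a
two-sided Wilcoxon rank-sum on the peptide-rate samples, and adjust
p-values by Benjamini–Hochberg across the comparison set. Whether
charge states are merged before fitting is not standardized in the
field; here envelopes are merged per modified sequence.

## Reporter quantification and rollup

Vendor lot sheets state, per reagent, the percentage of signal observed
at −2/−1/+1/+2 channel positions. `impurity_matrix()` fixes a single
orientation — column $j$ spills into row $i$, observed $= M\,x_{true}$ —
to prevent silent transposition; spill past the plex edge is lost mass.
`correct_impurities()` solves $\min_{x \ge 0} \lVert Mx - b\rVert^2$
(non-negative least squares, delegated to `pracma::lsqnonneg`, with an
exact fast path when the unconstrained solve is already feasible). NNLS
matters because fraction profiles are later row-normalized: negative
"corrected" intensities would corrupt the simplex geometry.

Peptide-to-protein rollup is deliberately conservative, because razor
peptides can blend the spatial profiles of differently localized
proteins: PSMs matching two or more top-level accessions are discarded
outright; isoforms enter only through isoform-unique peptides; peptides
shared between a canonical and an unevidenced isoform go to the
canonical. Light and heavy species are rolled up separately (the heavy
species gets an `_H` accession suffix) and each species needs two
distinct peptides per experiment to enter spatial analysis.

Channel intensities are mapped to fractions through the per-experiment
randomized design, column-normalized (removing per-fraction loading
differences; the output is provably invariant to any per-column scaling
of the input) and then row-normalized onto the simplex. Replicates are
normalized independently and concatenated, so a three-replicate,
ten-fraction experiment yields a 30-dimensional profile per protein
species. Rows with a missing replicate are excluded from
classification.

## Compartment classification

The classifier is a T-augmented Gaussian mixture fitted on organelle
marker proteins: one Gaussian per compartment (empirical mean,
regularized covariance), plus a single heavy-tailed outlier component —
a multivariate t (df 4) centered on the global marker mean with scale
four times the pooled covariance and prior mass $\varepsilon = 10^{-6}$.
Class priors are proportional to marker counts. Allocation is maximum a
posteriori; a call is confident when the top compartment posterior
exceeds 0.95, and the expected false discovery rate of a confident set
is the mean of (1 − probability) over passing calls.

The covariance regularization deserves a note. Marker counts per
compartment (order 10) are far below the profile dimension (order 30),
so empirical covariances are rank-deficient; a vanishing ridge leaves
near-null directions in which any query protein looks astronomically
unlikely, and everything drains to the outlier component. The default
therefore adds `lambda * tr(S)` — one percent of the *total* class
variance — to the diagonal, which keeps densities finite and calibrated
while preserving the dominant covariance structure. Both the shrinkage
and the outlier settings are exposed as parameters.

Markers are pruned before fitting by a seeded stochastic search that
proposes removing one marker at a time and accepts the removal when the
separation score (mean between-class centroid distance over mean
within-class distance to centroid) strictly increases, never shrinking
a class below the floor (default 6) and stopping after 100 consecutive
rejections or 500 proposals. The exact pruning algorithm is an open
design point in the field; accept-if-improving search against this
objective is the package's documented choice.

Full Bayesian differential-localization machinery (MCMC over mixture
allocations across conditions) is deliberately **not** reimplemented.
Differential localization is instead called by a bootstrap: peptides
are resampled with replacement within each condition (the peptide, not
the replicate, is the resampling unit — two or three replicates are too
few to bootstrap), the protein profile is re-derived and re-normalized,
and allocated under each condition's model. The DL probability is the
fraction of resamples whose top compartments differ between conditions;
calls above 0.95 in both the light and heavy species of one protein
form the paired set. This is a simplification with known consequences:
it captures sampling variability of the profile but not posterior
uncertainty of the mixture itself.

## Heavy–light partition statistics

The spatial distance between two profiles is the Euclidean norm of the
concatenated replicate vectors divided by the replicate count. The
scale of heavy–light distances is calibrated against a null of randomly
paired light proteins. For condition comparisons, the change in a
protein's heavy–light distance is adjusted by the mean change in
distance between its light profile and 250 sampled light partner
proteins (removing condition-wide drift), and the adjusted changes are
standardized into Z scores — by construction mean 0, SD 1 — so
heavy-only relocalization events surface as the top-ranked Z.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` generates the full evidence chain under a known
truth ledger: Dirichlet-drawn compartment profiles (concentration 0.5
over 10 fractions, minimum pairwise Euclidean separation 0.3 — peaked,
sedimentation-like fingerprints), log-uniform true rates on
[0.005, 0.2] per hour (half-lives ≈ 3.5–140 h, matching the dynamic
range seen in cultured human cells), a single 16 h chase by default,
first-order light/heavy partitioning that is exact at zero noise,
reporter spillover through a synthetic lot sheet pushed with
`observed = M x`, randomized channel-to-fraction designs per
experiment, three replicates, and mean-one multiplicative lognormal
noise (CV 0.05) on every area and channel intensity. Planted events
move both species (full relocalization) or only the heavy species
(partition); 12 markers per compartment are emitted as ordinary
quantified proteins. Replicate-level variance components are not
reported in the literature this design follows; the noise level is
chosen for testability, not as a claim about any instrument.

Not emulated: realistic peak shapes or chromatography (a minimal scan
stream exists only to exercise the integrator), co-isolation
interference (purity values are simulated covariates, not computed from
spectra), missing-value mechanisms beyond a small fraction of
identification failures, correlated noise across channels, and
compartment profiles with biologically adjacent structure. Passing
recovery tests on these fixtures therefore demonstrates correctness of
the computation, not performance on real instrument data.

## Problem sizes used by the test suite

The default validation fixture uses 200 unknown proteins plus 144
markers across 12 compartments, 2 conditions × 3 replicates, 200
bootstrap resamples per DL call; distance-statistics properties use a
500-protein single-condition fixture and a 100-protein fixture with
exactly one planted partition event. These sizes give stable recovery
statistics (rate errors, allocation rates, DL probabilities) while
keeping the whole suite fast enough to run routinely.

## Known limitations

* Plateau fixed at 1 assumes complete precursor labeling; precursor
  pool dilution would bias rates low. The plateau is a single
  configurable constant, not a fitted parameter.
* The two-peptide and complete-replicate requirements trade coverage
  for profile quality, as in the conservative end of spatial
  proteomics practice.
* Bootstrap DL probabilities are not posterior probabilities; they are
  resampling frequencies and should be compared against thresholds, not
  interpreted as calibrated posteriors.
* Expected FDR is the mean posterior complement of passing calls and
  inherits any miscalibration of the mixture posteriors.

## A worked miniature

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(n_compartments = 6, n_proteins = 40,
                                   markers_per_compartment = 8,
                                   dl_fraction = 0.1,
                                   partition_fraction = 0.05, seed = 3))
res <- analyse_dataset(sim$psm, sim$design, sim$impurity, sim$markers,
                       pipeline_params(n_boot = 50, n_ref = 20, seed = 2))
res$kinetics$protein_rates[1:3, ]
res$classification$ctl$expected_fdr
res$dl$paired
```
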