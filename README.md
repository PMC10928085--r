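# turnloc

Joint analysis of protein **turnover kinetics** and **subcellular
localization** from dual isotope-encoded mass spectrometry experiments,
for proteomics groups studying how cells re-route and re-synthesize
their proteome under stress.

The experimental design this package analyzes encodes two signals in
every peptide: dynamic SILAC labels (heavy Lys +8.0142 Da / Arg
+10.0083 Da, pulsed at perturbation onset) separate pre-existing
("light") from newly synthesized ("heavy") protein at the MS1 level,
while TMT reporter channels over ten differential-ultracentrifugation
fractions give each protein species a sedimentation profile at the MS2
level. Because light and heavy peptides are fragmented separately, the
old and new pools of the same protein get independent spatial profiles.

## What it computes

* **Turnover rates.** Fractional synthesis per peptide from MS1
  isotopomer envelopes, `fs = 1 − m0 / Σ(applicable isotopomers)`,
  fitted to the first-order rise `fs(t) = 1 − exp(−k t)` by
  intensity-weighted least squares (`fit_turnover_rate()`); protein
  rates as median ± raw MAD of peptide rates; half-life `ln 2 / k`;
  between-condition rate ratios with Wilcoxon rank-sum tests and
  Benjamini–Hochberg correction.
* **Reporter quantification.** TMT isotope-impurity correction by
  non-negative least squares (`observed = M · true`), conservative
  isoform-aware peptide→protein rollup split by SILAC species (`_H`
  suffix), channel→fraction design mapping, column- then
  row-normalization onto simplex fraction profiles.
* **Localization.** A T-augmented Gaussian mixture (per-compartment
  Gaussians plus a multivariate-t outlier component) trained on pruned
  organelle markers; maximum-a-posteriori allocation with posterior
  probabilities, outlier probabilities and expected FDR.
* **Localization dynamics.** Bootstrap differential-localization
  probabilities between conditions (peptide-level resampling), paired
  light/heavy DL calls, and drift-normalized heavy–light spatial
  distance Z scores that flag proteins whose *new* copies go somewhere
  the old ones did not.
* **Synthetic data.** A generator (`simulate_dataset()`) producing PSM
  tables, designs, impurity sheets, markers and a ground-truth ledger,
  so the whole pipeline is testable end to end without raw data.

## Worked example

```r
library(turnloc)

sim <- simulate_dataset(sim_config(n_compartments = 6, n_proteins = 40,
                                   markers_per_compartment = 8,
                                   dl_fraction = 0.1,
                                   partition_fraction = 0.05, seed = 3))
sim
#> Synthetic spatiotemporal proteomics dataset
#>   7260 PSM rows; 40 proteins + 48 markers; 6 compartments
#>   planted events: 4 DL, 2 partition

res <- analyse_dataset(sim$psm, sim$design, sim$impurity, sim$markers,
                       pipeline_params(n_boot = 50, n_ref = 20, seed = 2))

head(res$kinetics$protein_rates, 3)
#>   condition accession   median_k        mad_k half_life_h peptide_count
#> 1       ctl    MK0001 0.04863336 9.146373e-05   14.252505             6
#> 2       ctl    MK0002 0.04397474 4.265775e-04   15.762394             4
#> 3       ctl    MK0003 0.13671742 1.121429e-03    5.069926             6
```

`median_k` is the protein's replacement rate in per hour — MK0001 turns
over at 0.049/h, a half-life of about 14 h — and `mad_k` the spread
across its peptides. A single-protein fit prints the same quantities:

```r
fit_turnover_rate(16, 1 - exp(-0.048 * 16))
#> First-order turnover fit (plateau = 1)
#>   k         = 0.048 /h
#>   half-life = 14.44 h
#>   n = 1, R^2 = NA
```

The four planted full relocalizations are recovered as paired
(light + heavy) differential-localization calls, and the two planted
heavy-only partition events top the normalized distance-change ranking:

```r
res$dl$paired
#> [1] "SP0001" "SP0002" "SP0007" "SP0016"

ch <- res$pairdist$change
head(ch[order(-ch$z), c("accession", "d_a", "d_b", "delta_norm", "z")], 3)
#>    accession     d_a     d_b delta_norm    z
#> 67    SP0019 0.00971 0.32321     0.3056 7.28
#> 79    SP0031 0.00613 0.17866     0.1654 3.94
#> 55    SP0007 0.00686 0.00907     0.0465 1.11
```

`d_a`/`d_b` are the replicate-scaled Euclidean distances between a
protein's light and heavy profiles in each condition; SP0019's new
protein ends up in a different compartment than its old pool only in
the second condition, so its heavy–light distance jumps by an order of
magnitude and its Z score dominates.

File-based runs (`run_pipeline()`) read PSM/design/impurity/marker
tables, write per-stage TSVs plus a JSON manifest of parameters, seeds
and row counts, and can also be driven from the shell via
`inst/cli/turnloc.R` (`simulate` and `pipeline` subcommands). See the
methods vignette (`vignettes/spatiotemporal-proteomics.Rmd`) for the
statistical model, parameter defaults and design rationale.

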