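# socchrono

Soil organic carbon (SOC) stock change analysis for paired land-use
chronosequences.

## What it is for

Quantifying SOC change after land-use conversion — here, secondary forest
to rubber (*Hevea brasiliensis*) plantation — from a space-for-time
design: spatial clusters, each containing one reference forest plot and
one to three converted plots of different ages on matched terrain. The
package is aimed at soil scientists and biogeochemists running (or
re-analysing) such clustered paired-plot studies.

The analysis chain it implements:

1. **Stock accounting.** Per depth interval,
   `stock = %C/100 × BD × D × 10⁴` Mg C ha⁻¹ (BD in g cm⁻³, thickness D in
   m), summed over the canonical intervals 0–0.15, 0.15–0.3, 0.3–0.6,
   0.6–0.9, 0.9–1.2 m. Converted plots are evaluated at the cluster
   forest's bulk density (*equal-bulk-density correction*) so the same
   soil mass is compared across land uses; litter stocks and tree/bamboo
   basal areas are computed alongside.
2. **Cluster-paired changes.** Within each cluster, rubber plots are
   averaged, the forest subtracted, and relative differences taken against
   the forest stock; summaries report mean ± SE with n = clusters.
3. **Mixed-model inference.** `stock ~ land_use × depth` with a cluster
   random intercept (REML), per-depth rubber−forest Wald contrasts, Holm
   correction, optional per-land-use residual variances.
4. **Covariate screen.** Spearman rank correlations of carbon
   concentrations and relative stock differences against litter, basal
   area, texture, age, slope and altitude.
5. **Decay kinetics.** Rubber stocks as a proportion of the paired forest,
   `y(t) = Xe + (100 − Xe)·exp(−k·t)` (one pool, X₀ fixed at 100%) and the
   two-pool alternative `X₁·exp(−k₁t) + (100 − X₁)·exp(−k₂t)`, fitted by
   bounded Levenberg–Marquardt least squares with seeded multi-start;
   parsimony-based model selection; steady state at the first time the
   curve is within 1% of Xe: `t* = ln((100 − Xe)/(0.01·Xe))/k`.
6. **Synthetic studies.** A generator that emulates the full design
   (7 clusters, 11 plantations aged 5–46 yr, depth-specific decay truth,
   measurement noise) so every stage is testable and parameter recovery
   can be scored against known truth.

## Worked example

```r
library(socchrono)

gs <- generate_study(synthetic_config(), seed = 42)  # or read_study(dir)
st <- compute_stocks(gs$study)                       # BD-corrected stocks

summarize_changes(cluster_changes(st))               # Table-style summary
#>  total: forest 203.0 ± 3.1, rubber 168.9 ± 2.6 Mg C ha-1
#>         change -34.1 ± 1.8 Mg C ha-1  (-16.8 ± 0.8 %)

ch <- chronosequence_fits(st, seed = 42)
ch$fits[["0-0.15"]]$mono
#> <soc_decay_fit> mono-exponential, n = 11, converged: TRUE
#>   Xe = 68.31 (SE 2.13, p = 1.38e-10)
#>   k  = 0.1797 (SE 0.0521, p = 0.00729)
#>   r = 0.7250 (p = 0.0116); steady state at 21.3 yr (69.0% remaining)

depth_contrasts(fit_landuse_model(st))
#>  0-0.15   -12.9 ± 2.0  p_holm 2.1e-10 ***
#>  0.15-0.3  -9.5 ± 2.0  p_holm 5.0e-06 ***
#>  0.3-0.6   -7.7 ± 2.0  p_holm 2.5e-04 ***
#>  0.6-0.9   -3.7 ± 2.0  p_holm 0.123
#>  0.9-1.2   -0.8 ± 2.0  p_holm 0.665
```

Reading: this synthetic study lost a third of its topsoil carbon
(equilibrium at 68% of the forest stock, reached after ~21 years at decay
rate 0.18 yr⁻¹), losses concentrate in the upper 0.6 m, and the deep
subsoil shows no significant change — the pattern the clustered design is
built to detect.

`run_pipeline()` (or the `inst/scripts/socchrono` CLI) runs the whole
chain and writes report tables: characteristics and litter/tree summaries,
per-cluster and summarized stock changes with significance flags, the
correlation screen, decay-fit parameters and fitted curves, the
corrected-versus-uncorrected BD comparison, a run log and a JSON manifest.

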