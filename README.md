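# riverassembly

Quantitative tools for asking how human activity restructures river
bacterioplankton communities. Given a site-by-OTU count table, sample
metadata (season, reach, water chemistry), sub-basin land-use fractions
and geographic distance parameters, the package:

- computes the **human activity intensity of land surface** index,
  HAILS = S_i / S × 100% over direct-interference land-cover classes
  (farmland + urban), and classifies sites into low/middle/high levels;
- diagnoses **deterministic vs stochastic community assembly**: Sloan's
  neutral community model (occurrence frequency of an OTU with mean
  relative abundance *p* predicted as 1 − I_d(Nmp, Nm(1−p)), with the
  immigration rate *m* fitted by least squares), checkerboard **C-score
  null models** with sequential-swap randomization and standardized
  effect sizes, and **Levins' niche breadth** B_j = 1 / Σ_i P_ij²;
- builds signed **co-occurrence networks** per site group (correlation
  threshold + permutation FDR), computes the standard 13-index topology
  panel (TN, TL, NL, PL, NP, R, avgK, avgCC, APD, CD, GD, NM, M),
  detects modules by greedy modularity maximisation, classifies node
  roles by within-module degree z-score and participation coefficient
  (zi/pi with the 2.5 / 0.62 thresholds), and regresses network
  stability proxies on HAILS;
- attributes variation to **land use, water chemistry and geographic
  distance**: Mantel and distance-decay tests, exhaustive bioenv
  best-subset search, RDA with marginal permutation tests, and
  three-matrix variation partitioning with adjusted R² (fractions
  [a]–[g] plus unexplained, summing to 1 exactly);
- generates complete **synthetic studies** with controllable neutral vs
  niche assembly and a built HAILS gradient, so every stage is testable
  with known ground truth.

Everything is tibble-first: community tables are wide tibbles
(`sample_id` + one integer column per OTU), results come back as tidy
tibbles, fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a two-season, 15-site study under neutral assembly (m = 0.5,
770 OTUs, 24,343 reads per sample) and refit the neutral model:

```r
library(riverassembly)

bundle <- simulate_study(sim_config(seed = 1))
fit <- fit_ncm(bundle$tables$dry)
glance(fit)
#> # A tibble: 1 × 7
#>       m     Nm     N r_squared detection_limit n_otus n_samples
#>   <dbl>  <dbl> <dbl>     <dbl>           <dbl>  <int>     <int>
#> 1 0.484 11791. 24343     0.951       0.0000205    759        15
```

The fitted immigration rate (0.484) recovers the simulated m = 0.5, and
R² = 0.95 says occurrence frequencies sit tightly on the neutral
prediction — the signature of dispersal-dominated assembly. HAILS and
niche breadth:

```r
hails <- classify_hails(
  dplyr::left_join(hails_index(bundle$metadata),
                   bundle$metadata[c("sample_id", "reach")],
                   by = "sample_id"),
  scheme = "reach-map")
head(hails, 4)
#>   sample_id hails reach level
#> 1 L01        4    upper low
#> 2 L02        7.71 upper low
#> 3 L03       11.4  upper low
#> 4 L04       15.1  upper low

niche_breadth(bundle$tables$dry)$summary
#> # A tibble: 1 × 5
#>   group mean_B n_otus n_communities n_excluded
#> 1 all     10.6    759            15         11
```

A mean Levins' B of 10.6 across 15 communities indicates generalist
habitat use, as expected without species sorting. The C-score null model
agrees — no segregation signal on neutral data:

```r
null_model_ses(presence_matrix(bundle$tables$dry),
               n_simulations = 200, burn_in = 5000, thin = 50, seed = 2)
#>   observed_statistic null_mean null_sd   ses      p
#> 1               6.68      6.69 0.00408 -1.54 0.0697
```

Raising `niche_strength` in `sim_config()` flips all three diagnostics:
NCM R² falls, mean B shrinks, and SES climbs far above +2 (segregation).
`run_pipeline()` chains every stage — HAILS, diversity/ordination,
assembly diagnostics, gradient networks, driver attribution — from a
YAML config into TSV/JSON outputs plus a run manifest.

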