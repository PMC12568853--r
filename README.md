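# dustindices

Contamination assessment for heavy metals in road dust and soil, for
environmental scientists who have a site × metal concentration table and
want the full standard battery: individual pollution indices with their
published classification schemes, composite indices, zone-level
contamination degrees, representative local enrichment levels, k-medoids
clustering of site profiles with validity and stability diagnostics,
correlation-PCA source attribution, and nonparametric zone comparison —
plus a synthetic generator with known ground truth to validate the whole
pipeline end to end.

## The indices

For a concentration `C` of metal *i* at a site, with geochemical background
`CB_i` and pre-industrial reference `Cp_j`:

| Index | Definition | Level |
|---|---|---|
| Geo-accumulation | `Igeo = log2(C_i / 1.5 CB_i)` | site × metal |
| Pollution index | `PI = C_i / CB_i` | site × metal |
| Enrichment factor | `EF = (C_i/C_norm) / (CB_i/CB_norm)` | site × metal |
| Contamination factor | `CF_j = mean_zone(C_j) / Cp_j` | zone × metal |
| Pollution load index | `PLI = (prod PI_j)^(1/n)` | site |
| Nemerow index | `PI_Nem = sqrt((mean(PI)² + max(PI)²)/2)` | site |
| Combined pollution index | `CPI = mean(PI_j)` | site |
| Contamination degree | `CD = sum(CF_j)`, `mCD = CD/n` | zone |

Each index carries its standard class intervals (e.g. `CF ≥ 6` "very
high"); `classify()` is exhaustive and exclusive. Background values are
config-mandatory — the package ships pre-industrial references (Cd 1,
Cr 90, Cu 50, Ni 68, Pb 70, Zn 175, Mn 850 µg/g) but deliberately no
background compilation. Beyond the index battery, `representative_level()`
condenses a zone's per-metal index series to its modal equal-width
sub-interval (the "representative local level"), `kmedoids()` /
`select_k()` / `stability()` cluster site profiles with majority-vote model
selection and bootstrap-Jaccard stability, and `pca()` attributes sources
on the correlation matrix. See `vignette("contamination-assessment")` for
the methodology and design choices.

## Worked example

Zone-level contamination degrees from a published table of per-zone mean
concentrations (mg/kg), through the contamination-factor path:

```r
library(dustindices)
ref <- reference_set()   # packaged pre-industrial values
kf <- cf_from_means(c(Cd = 33.219, Cr = 104.14, Cu = 59.970, Ni = 1325.4,
                      Pb = 103.9, Zn = 712.86, Mn = 233.667), ref)
contamination_degree(kf)$CD
#> <composite_table> CD over {Cd, Cr, Cu, Ni, Pb, Zn, Mn}
#>       value     class
#> mean 60.899 very high
```

`CD = 60.90`: the zone sums to a "very high" contamination degree, driven
by Cd (`CF = 33.2`) and Ni (`CF = 19.5`); the modified degree
`mCD = 8.70` is likewise "very high" (above 6 on the per-metal scale).

The full pipeline on a synthetic two-zone survey with planted sources:

```r
g <- generate_concentrations(seed = 20250829)
ref <- reference_set(background = g$truth$background_used)
bundle <- run_pipeline(g$conc, ref, out_dir = "results/report")
recovery_check(g$truth, g$conc, normalizer = "Fe")
#> <recovery_report>
#>   EF ranking ok: KF=TRUE, D=TRUE
#>   ARI = 1.000 (ok: TRUE)
#>   PCA cosine: KF=0.728, D=0.812 (ok: FALSE)
#>   some checks flagged
```

Enrichment ranking and the zone partition are recovered exactly in this
draw; the zone-KF source alignment falls just short of its 0.8 cosine bar
at the full survey-like noise level — at lower noise all three checks pass
(see the vignette's recovery-regime discussion).

The `analysis/` directory holds the numbered drivers that run the whole
sequence (`01_simulate.R` … `05_multivariate.R`), printing what each stage
found and writing tables under `results/`.

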