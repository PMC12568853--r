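---
title: "Heavy-metal contamination assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-metal contamination assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustindices)
```

`dustindices` assesses heavy-metal contamination in road dust or soil from a
single measured input: a site x metal matrix of concentrations in mg/kg dry
weight (numerically identical to ug/g). This vignette is the package's own
account of the methodology: the indices and their classification schemes,
the representative-level condensation, the clustering and ordination
machinery, the synthetic ground-truth generator, and the design decisions
taken where the methodology left genuine choices open.

## Individual indices

Four per-site (or per-zone) indices are computed, each against a reference
concentration:

* **Geo-accumulation index** `Igeo = log2(C / (1.5 CB))`, where `CB` is the
  geochemical background of the metal. The factor 1.5 buffers natural
  lithological variation, so a site begins to count as polluted only beyond
  1.5 times background. Seven classes from "unpolluted" (`Igeo < 0`) to
  "extremely polluted" (`Igeo >= 5`).
* **Pollution index** `PI = C / CB`, the plain background ratio; five
  classes, from none (`< 1`) to very accentuated (`>= 5`). `PI` and `Igeo`
  are algebraically locked: `PI = 1.5 * 2^Igeo`, which the tests verify to
  1e-12 relative error.
* **Enrichment factor** `EF_i = (C_i / C_norm) / (CB_i / CB_norm)` with a
  conservative crustal element as normalizer (Mn and Fe are the packaged
  candidates). The double ratio cancels uniform dilution of a sample, so
  `EF` isolates enrichment relative to crustal composition; it is invariant
  to rescaling a site's whole profile, which is tested as a property.
* **Contamination factor** `CF_j = C_avj / C_pj`: a *zone mean* (over at
  least five samples, enforced) divided by a pre-industrial reference
  level. The seven packaged pre-industrial values (Cd 1, Cr 90, Cu 50,
  Ni 68, Pb 70, Zn 175, Mn 850 ug/g) are the classical Hakanson reference
  list.

Two reference-value decisions deserve emphasis. First, geochemical
*background* values are deliberately **config-mandatory**: published
background compilations differ, and silently shipping one would bake
unverifiable numbers into every downstream index. `reference_set()` and the
YAML config accept any user background set; only the pre-industrial list is
packaged. Second, metals without a pre-industrial reference (Co, Ba, Fe
here) are excluded from the CF family with a warning rather than given
invented references.

All classification intervals close on the left (`[a, b)`), with the topmost
class closed below per the usual ">=" wording; `classify()` is exhaustive
and exclusive, and boundary behavior is pinned by tests (e.g. `PI = 5` is
"very accentuated", `CF = 1` is "moderate").

## Composite indices

Per site, over a chosen metal subset: the **pollution load index** (geometric
mean of PI), the **Nemerow index** `sqrt((mean(PI)^2 + max(PI)^2)/2)` which
up-weights the worst pollutant, and the **combined pollution index**
(arithmetic mean of PI). `PLI <= CPI` (AM-GM) and
`mean(PI) <= PI_Nem <= max(PI)` are tested as properties on random tables.

Per zone, the **contamination degree** `CD = sum(CF_j)` and the **modified
contamination degree** `mCD = CD / n`. CD is classified on the CF intervals
multiplied by the number of metals; mCD is classified on the *raw* CF
intervals. The latter is a deliberate reading: with seven metals, zone
values near 8.7 and 4.8 classify as "very high" (`> 6`) and "high"
(`[3, 6)`) only under unscaled intervals, which is the only interpretation
consistent with the verdicts such values are reported to carry.

Because a single dominating pollutant (typically Cd) can swamp every
composite, `sensitivity_without()` recomputes any composite with one metal
excluded and reports both variants side by side.

## Representative local level

`representative_level()` condenses a zone's per-metal index series (one
value per site) into a single representative level per metal:

1. split `[min, max]` into `m = 3` equal-width bins (left-closed,
   right-open, the last bin closed so the maximum is binned);
2. count the sites in each bin;
3. pick the most populated bin; break frequency ties toward the bin whose
   internal mean is closest to the row mean (exact-distance ties go to the
   leftmost such bin — a tie-break the source procedure leaves unspecified);
4. if any bin is empty, decrement `m` until none is (never below 2,
   which cannot be empty when the row has two distinct values), recording
   `m_used`.

The procedure fixes `m = 3` but also requires void-free bins; the automatic
decrement resolves that tension deterministically. The numeric level
reported for a metal is the mean of the values inside the chosen bin — the
natural choice given that the tie-break already privileges bin-internal
means — and the interval bounds are always reported alongside. Correctness
is established against an independent brute-force enumeration (500 random
rows, tie cases included, 100% agreement required), plus permutation
invariance and scale equivariance properties.

## Clustering

Site profiles are clustered by **k-medoids (PAM)** on Euclidean distances
between z-scored metal columns. Standardization is essential: Fe and Ni are
3–4 orders of magnitude above Cd, and unscaled distances would be an Fe/Ni
ruler. The implementation is the classical build/swap scheme run from
`n_restarts = 10` random initializations (seeded, hence bit-reproducible);
on instances of up to 8 sites the tests require the exhaustive optimum over
all medoid subsets in at least 95% of cases, and `cluster::pam` serves as an
independent cross-check of the objective. Medoids are always data points
and every site is assigned to its nearest medoid, both tested invariants.

The number of clusters is put to a **majority vote** of five internal
indices — mean silhouette, Dunn, Calinski–Harabasz, Davies–Bouldin, and the
gap statistic (Tibshirani first-SE rule) — with ties broken toward the
smaller k. This is a reduced panel reproducing the majority-vote mechanism
of the full 30-index NbClust battery. Solution quality is reported as
connectivity (10 nearest neighbors), Dunn, and mean silhouette; cluster
reproducibility as **bootstrap-Jaccard stability**: each of `B = 100`
nonparametric resamples is reclustered, the resample clustering is extended
to all sites by nearest-medoid classification, and each original cluster
records its best Jaccard overlap. Means above 0.85 are labeled "highly
stable", 0.6–0.85 "stable" — thresholds chosen so that values like 0.92 and
0.80 carry the verbal labels such values conventionally receive.

## PCA and zone comparison

`pca()` eigendecomposes the **correlation** matrix (mixed metal scales rule
out covariance PCA), making the analysis invariant to per-metal affine
rescaling. Loadings are eigenvectors scaled by the square root of their
eigenvalues, so `cos2 = loading^2` and each metal's cos2 across all
components sums to 1. Component signs are fixed by making each component's
largest-magnitude loading positive, removing the eigenvector sign
ambiguity. Component counts are reported under the Kaiser rule
(eigenvalue > 1) and a cumulative-variance rule (default threshold 0.8,
"more than four fifths"), with the operative choice being the Kaiser count
extended until the threshold is met. Contributions are
`100 * loading^2 / eigenvalue` per component, combined across components by
eigenvalue weighting, with `100 / n_metals` as the expected-average
reference line.

Zones are compared on the **indicator series** (Igeo, PI, EF under each
normalizer), not on raw concentrations: indices are dimensionless and
comparable across metals, concentrations of different metals are not. The
"nonparametric ANOVA" is implemented as the Kruskal–Wallis rank test — the
standard reading; the test function is swappable. When every value is tied
the statistic is degenerate and `H = 0, p = 1` is returned by convention.
Null calibration (uniform p-values, KS check) is part of the test suite.

## Synthetic generator

Because no raw per-site survey matrix is public, `generate_concentrations()`
produces matrices with known ground truth:

```
C[s, i] = CB_i * zb[z(s), i] * (1 + sum_k e[s, k] (P[k, i] - 1)) * noise
```

with `CB` a clearly-labeled synthetic background set (plausible for a
carbonate-diluted arid urban setting; *not* a published compilation),
`zb` a deterministic geogenic baseline multiplier per zone, `P` the source
enrichment profiles, `e` nonnegative site exposures, and mean-one
multiplicative lognormal noise (concentrations stay positive and
right-skewed, matching the positive skew and heavy kurtosis of real road
dust). The expected concentration equals the deterministic mixture term,
verified by Monte Carlo at 1e5 draws within 1%.

The default `uae_like_scenario()` plants: zone KF (15 sites) with an
ultramafic geogenic source (Ni x30, Cr x1.9, Co x2.8; exposure cv 0.2,
varying smoothly as substrate does) and a port/industrial source (Cd x80,
Zn x12, Pb x5.5, Cu x2.4); zone D (14 sites) with a traffic source (Cd x60,
Zn x5.5, Pb x1.9, Cu x2.5, Ni x4.5, Ba x1.7); an ophiolite baseline shift
for Fe (x1.5) and Mn (x1.25) in zone KF; and a single-site ultramafic
exposure spike (x2.2) emulating a nickel hot spot. Anthropogenic exposures
are modeled as a diffuse regional component (0.4) plus a localized gamma
component, overall cv 0.45 — deposition near emitters is patchy, but no
site in an urban zone escapes the diffuse load. The default noise cv is
0.3, matching the within-zone dispersion of published road-dust surveys.
Multipliers were calibrated by simulation so zone means land on the scale
such surveys report (zone-KF mean Ni about 1.3 g/kg).

**What the generator does and does not emulate.** It reproduces zone-level
means and dispersions, multi-metal source structure, hot-spot-driven skew,
and a two-zone partition. It does not reproduce spatial autocorrelation,
censoring at detection limits, inter-metal measurement covariance, or any
particular survey's per-site values — so passing recovery tests show that
the *pipeline* identifies planted structure, not that any specific field
data set would behave identically.

**Recovery regime.** `recovery_check()` verifies that (a) zone-mean EF
ranks every truly enriched metal above every non-enriched one, (b)
k-medoids at the true group count matches the planted partition (adjusted
Rand index), and (c) among the leading components of a zone's PCA, some
loading vector aligns with a planted source contrast (absolute cosine).
Cluster recovery is guaranteed only when between-source separation is well
clear of the noise (roughly five times); at the full survey-like noise
cv 0.3 the two default zones genuinely overlap — exactly as in real
surveys, where clustering is done within zones and cross-zone separability
is never claimed. The acceptance suite therefore scores the EF ranking at
noise cv 0.3 (pass rate over 100 seeds) and the partition/source recovery
at noise cv 0.15, the level at which the default scenario satisfies the
separability premise, aggregating ARI and cosine as medians over the same
seeds.

## Numerical conventions and problem sizes

* Equality of PLI with 1 ("baseline") is tested at 1e-9; `CD = n * mCD`
  holds to 1e-12 relative.
* Descriptive statistics use bias-corrected sample skewness and *excess*
  kurtosis (platykurtic metals are negative).
* Degenerate inputs fail loudly and early: non-positive concentrations,
  constant metal columns (PCA), constant index rows (binning), zones with
  fewer than five sites (CF), k outside `[2, n]`.
* Seeds are explicit everywhere randomness enters (restarts, bootstrap,
  gap-statistic references, generation); the packaged default is 20250829.
  Identical inputs and seed give byte-identical pipeline output.
* Test and example problem sizes — 29 x 10 matrices, 100-seed recovery
  panels, 200 exhaustive-search micro-instances, B = 100 bootstrap
  resamples — were chosen so the whole suite completes in a few minutes on
  one core while keeping every estimate's Monte Carlo error far below the
  margins being asserted.

## Known limitations

* Igeo/PI/EF site values depend entirely on the user's background set; two
  users with different compilations will disagree numerically (the package
  intentionally refuses to pick for them).
* The EF normalizer must itself be unenriched for the double ratio to read
  as anthropogenic enrichment; the default report shows both Mn- and
  Fe-normalized tables so a shifted normalizer is visible.
* The k-selection panel is five indices, not thirty; on small zones the
  gap statistic's reference draws dominate its vote variance.
* Bootstrap-Jaccard stability on zones of 14–15 sites is itself noisy;
  B below 20 triggers a warning.
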