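Package: dustindices
Title: Heavy-Metal Pollution Indices, Local Enrichment Levels, and
    Source Attribution for Road Dust and Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contamination assessment for site-by-metal concentration
    matrices from road dust or soil. Computes the individual pollution
    indices (geo-accumulation index, pollution index, enrichment factor,
    contamination factor) and their composites (pollution load index,
    Nemerow index, combined pollution index, contamination degree and
    modified contamination degree) with published classification schemes;
    condenses a zone's per-metal index series into representative local
    levels by modal equal-width binning; groups site profiles by
    k-medoids with validity- and bootstrap-Jaccard-stability-based model
    selection; attributes sources by correlation-matrix principal
    component analysis; and compares zones by nonparametric rank tests.
    Includes a synthetic concentration-matrix generator with known
    ground truth (geogenic baseline plus localized anthropogenic
    enrichment) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    e1071,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
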