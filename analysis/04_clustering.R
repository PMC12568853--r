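#!/usr/bin/env Rscript
# Stage 4 — cluster the site profiles within each zone.
#
# k-medoids on z-scored concentrations; the number of clusters is put
# to a majority vote of five internal indices, then the winning
# solution is scored for validity (connectivity, Dunn, silhouette) and
# bootstrap-Jaccard stability.

suppressPackageStartupMessages(library(dustindices))
dir.create("results", showWarnings = FALSE)
seed <- 20250829L

conc <- read_concentrations("results/synthetic_concentrations.csv")

for (z in unique(zones(conc))) {
  prof <- standardize_profiles(zone_subset(conc, z))
  sel <- select_k(prof, 2:6, seed = seed)
  sol <- kmedoids(prof, sel$chosen_k, seed = seed)
  val <- validity(sol, prof)
  st <- stability(prof, sel$chosen_k, B = 100, seed = seed)

  cat(sprintf("Zone %s: votes [%s] -> k = %d\n", z,
              paste(sprintf("k=%s:%d", names(sel$votes), sel$votes),
                    collapse = ", "), sel$chosen_k))
  cat(sprintf("  medoids: %s; total cost %.3f\n",
              paste(sol$medoid_sites, collapse = ", "), sol$total_cost))
  cat(sprintf("  connectivity %.2f, Dunn %.3f, mean silhouette %.3f\n",
              val$connectivity, val$dunn, val$silhouette))
  cat(sprintf("  stability (mean Jaccard over %d resamples): %s\n\n",
              st$B,
              paste(sprintf("cluster %s %.2f (%s)", names(st$jaccard),
                            st$jaccard, st$labels), collapse = "; ")))
  utils::write.csv(
    data.frame(site = names(sol$assignment), cluster = sol$assignment),
    sprintf("results/clusters_%s.csv", z), row.names = FALSE)
}
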