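#!/usr/bin/env Rscript
# Stage 2 — individual and composite pollution indices.
#
# Computes Igeo, PI and EF (Mn- and Fe-normalized) per site, CF / CD /
# mCD per zone on the synthetic survey, and reproduces the published
# zone-level contamination degrees from the shipped zone-mean table.
# Also runs the with/without-Cd sensitivity recomputation: Cd's PI is
# so high that it swamps every composite.

suppressPackageStartupMessages(library(dustindices))
dir.create("results", showWarnings = FALSE)

conc <- read_concentrations("results/synthetic_concentrations.csv")
ref <- read_reference_config("results/synthetic_background.yml")

ind <- list(Igeo = igeo(conc, ref), PI = pollution_index(conc, ref),
            EF_Mn = enrichment_factor(conc, ref, "Mn"),
            EF_Fe = enrichment_factor(conc, ref, "Fe"))
for (nm in names(ind)) {
  utils::write.csv(data.frame(site = rownames(ind[[nm]]$values),
                              ind[[nm]]$values, check.names = FALSE),
                   sprintf("results/index_%s.csv", nm), row.names = FALSE)
}

pi_tab <- ind$PI
comp <- data.frame(site = rownames(pi_tab$values),
                   PLI = unname(pli(pi_tab)$values),
                   PI_Nem = unname(nemerow(pi_tab)$values),
                   PI_Nem_noCd = unname(
                     sensitivity_without(nemerow, pi_tab, "Cd")$without$values),
                   CPI = unname(cpi(pi_tab)$values))
utils::write.csv(comp, "results/composites.csv", row.names = FALSE)

zs <- unique(zones(conc))
cat("Per-site composite ranges:\n")
for (z in zs) {
  idx <- zones(conc) == z
  cat(sprintf("  zone %s: PLI %.3f-%.3f, PI_Nem (no Cd) %.2f-%.2f\n", z,
              min(comp$PLI[idx]), max(comp$PLI[idx]),
              min(comp$PI_Nem_noCd[idx]), max(comp$PI_Nem_noCd[idx])))
}

cat("\nZone contamination degrees on the synthetic survey:\n")
for (z in zs) {
  cd <- contamination_degree(suppressWarnings(
    contamination_factor(conc, ref, z)))
  cat(sprintf("  zone %s: CD = %.2f (%s), mCD = %.2f (%s)\n", z,
              cd$CD$values, cd$CD$classes, cd$mCD$values, cd$mCD$classes))
}

cat("\nPublished zone-mean table, same CF/CD path:\n")
means <- utils::read.csv(system.file(
  "extdata", "uae_zone_mean_concentrations.csv", package = "dustindices"))
pref <- reference_set()
for (i in seq_len(nrow(means))) {
  v <- unlist(means[i, names(pref$preindustrial)])
  cd <- contamination_degree(cf_from_means(v, pref))
  cat(sprintf("  zone %s: CD = %.2f (%s), mCD = %.2f (%s)\n",
              means$zone[i], cd$CD$values, cd$CD$classes,
              cd$mCD$values, cd$mCD$classes))
}
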