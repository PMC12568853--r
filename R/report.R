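# Report assembly: descriptive statistics and the end-to-end pipeline
# mirroring the full contamination-assessment sequence.

#' Per-zone descriptive statistics
#'
#' Mean, min, max, standard deviation, sample skewness and excess
#' kurtosis per metal within each zone (e1071 type-2, bias-corrected
#' sample conventions; kurtosis is excess, so a platykurtic metal is
#' negative).
#'
#' @param conc a `conc_matrix`
#' @return named list (one element per zone) of stat-by-metal matrices
#'   with rows mean, min, max, sd, skewness, kurtosis
#' @export
descriptive_stats <- function(conc) {
  stopifnot(inherits(conc, "conc_matrix"))
  lapply(stats::setNames(nm = unique(conc$zones)), function(z) {
    v <- zone_subset(conc, z)$values
    rbind(mean = colMeans(v),
          min = apply(v, 2L, min),
          max = apply(v, 2L, max),
          sd = apply(v, 2L, stats::sd),
          skewness = apply(v, 2L, e1071::skewness, type = 2),
          kurtosis = apply(v, 2L, e1071::kurtosis, type = 2))
  })
}

as_df <- function(m) data.frame(row = rownames(m), m, check.names = FALSE,
                                stringsAsFactors = FALSE)

#' Run the full contamination-assessment pipeline
#'
#' Chains every stage on one concentration matrix: (1) per-zone
#' descriptive statistics; (2) individual index tables with classes
#' (Igeo, PI, EF per normalizer, CF per zone); (3) composites (PLI,
#' Nemerow, CPI per site; CD and mCD per zone) including a
#' with/without-one-metal sensitivity variant; (4) representative local
#' enrichment levels per zone; (5) k-medoids clustering per zone with
#' majority-vote k, validity and bootstrap-Jaccard stability; (6)
#' correlation PCA per zone with component selection and variable
#' contributions; (7) nonparametric between-zone comparison of the
#' indicator series. Stages whose inputs are unavailable (no background
#' set, too few sites for CF) are replaced by a notice naming the stage;
#' later stages that do not depend on them still run. Writes `report.json`
#' plus per-stage CSVs to `out_dir` when given; the returned bundle (and
#' the JSON) is byte-reproducible for fixed inputs and seed.
#'
#' @param conc a `conc_matrix`
#' @param ref a `reference_set`
#' @param out_dir output directory, or `NULL` to skip writing
#' @param normalizers enrichment-factor normalizers, default Mn and Fe
#' @param exclude_metal metal for the composite sensitivity variant
#'   (default "Cd", the usual dominating pollutant), or `NULL`
#' @param candidate_ks candidate cluster counts
#' @param stability_B bootstrap resamples for the stability stage
#' @param seed integer seed for clustering and stability
#' @return invisibly, the report bundle (nested list, one element per
#'   stage; failed stages carry a `notice` string)
#' @export
run_pipeline <- function(conc, ref, out_dir = NULL,
                         normalizers = ref$normalizers,
                         exclude_metal = "Cd", candidate_ks = 2:6,
                         stability_B = 100L, seed = 20250829L) {
  stopifnot(inherits(conc, "conc_matrix"), inherits(ref, "reference_set"))
  bundle <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      list(notice = paste0("stage '", name, "' skipped: ",
                           conditionMessage(e))))
  }
  zs <- unique(conc$zones)

  bundle$descriptive <- stage("descriptive", descriptive_stats(conc))

  bundle$individual <- stage("individual", {
    out <- list(Igeo = igeo(conc, ref), PI = pollution_index(conc, ref))
    for (nm in normalizers)
      out[[paste0("EF_", nm)]] <- enrichment_factor(conc, ref, nm)
    out
  })
  bundle$cf <- lapply(stats::setNames(nm = zs), function(z)
    stage(paste0("CF ", z),
          suppressWarnings(contamination_factor(conc, ref, z))))

  bundle$composite <- stage("composite", {
    pi_tab <- bundle$individual$PI
    if (is.null(pi_tab$values)) stop("PI table unavailable")
    out <- list(PLI = pli(pi_tab), PI_Nem = nemerow(pi_tab),
                CPI = cpi(pi_tab))
    if (!is.null(exclude_metal) &&
        exclude_metal %in% colnames(pi_tab$values)) {
      out$sensitivity <- list(
        PLI = sensitivity_without(pli, pi_tab, exclude_metal),
        PI_Nem = sensitivity_without(nemerow, pi_tab, exclude_metal),
        CPI = sensitivity_without(cpi, pi_tab, exclude_metal))
    }
    out
  })
  bundle$contamination_degree <- lapply(stats::setNames(nm = zs),
                                        function(z) {
    cf <- bundle$cf[[z]]
    if (!inherits(cf, "index_table"))
      return(cf)  # notice from the CF stage
    contamination_degree(cf)
  })

  bundle$ef_local <- lapply(stats::setNames(nm = zs), function(z)
    stage(paste0("EF_local ", z),
          ef_local_report(conc, ref, z, normalizer = normalizers[1L])))

  bundle$clustering <- lapply(stats::setNames(nm = zs), function(z)
    stage(paste0("clustering ", z), {
      prof <- standardize_profiles(zone_subset(conc, z))
      ks <- candidate_ks[candidate_ks < nrow(prof)]
      sel <- select_k(prof, ks, seed = seed)
      sol <- kmedoids(prof, sel$chosen_k, seed = seed)
      list(selection = sel, solution = sol,
           validity = validity(sol, prof),
           stability = stability(prof, sel$chosen_k, B = stability_B,
                                 seed = seed))
    }))

  bundle$pca <- lapply(stats::setNames(nm = zs), function(z)
    stage(paste0("PCA ", z), {
      res <- pca(conc, zone = z)
      sel <- select_components(res)
      list(result = res, selection = sel,
           contributions = contributions(res, seq_len(max(sel$chosen, 1L))))
    }))

  bundle$zone_comparison <- stage("zone comparison", {
    ind <- bundle$individual
    if (!is.null(ind$notice)) stop("indicator tables unavailable")
    tabs <- lapply(ind, function(tab)
      lapply(stats::setNames(nm = zs), function(z)
        tab$values[names(conc$zones)[conc$zones == z], , drop = FALSE]))
    list(between_zones = compare_zones(tabs),
         within_zone = lapply(stats::setNames(nm = zs), function(z)
           do.call(rbind, lapply(names(ind), function(nm) {
             sub <- ind[[nm]]
             sub$values <- sub$values[names(conc$zones)[conc$zones == z], ,
                                      drop = FALSE]
             kw <- compare_metals(sub)
             data.frame(indicator = nm, H = kw$H, df = kw$df,
                        p_value = kw$p_value)
           }))))
  })

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

# Serialize the bundle: report.json plus flat CSVs for the main tables.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (z in names(bundle$descriptive)) {
    d <- bundle$descriptive[[z]]
    if (is.matrix(d))
      utils::write.csv(as_df(d),
                       file.path(out_dir, paste0("descriptive_", z, ".csv")),
                       row.names = FALSE)
  }
  ind <- bundle$individual
  if (is.null(ind$notice)) {
    for (nm in names(ind))
      utils::write.csv(as_df(ind[[nm]]$values),
                       file.path(out_dir, paste0("index_", nm, ".csv")),
                       row.names = FALSE)
  }
  comp <- bundle$composite
  if (is.null(comp$notice)) {
    per_site <- data.frame(site = names(comp$PLI$values),
                           PLI = unname(comp$PLI$values),
                           PI_Nem = unname(comp$PI_Nem$values),
                           CPI = unname(comp$CPI$values))
    utils::write.csv(per_site, file.path(out_dir, "composites.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle_to_json(bundle),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Reduce the bundle to JSON-friendly primitives (drop S3 wrappers).
bundle_to_json <- function(x) {
  if (inherits(x, "index_table"))
    return(list(index = x$index_name, normalizer = x$normalizer,
                values = as.data.frame(x$values),
                classes = as.data.frame(x$classes)))
  if (inherits(x, "composite_table"))
    return(list(index = x$index_name, metals = x$metal_subset,
                values = as.list(x$values), classes = as.list(x$classes)))
  if (inherits(x, "cluster_solution"))
    return(list(k = x$k, medoids = x$medoid_sites,
                assignment = as.list(x$assignment),
                total_cost = x$total_cost))
  if (inherits(x, "cluster_stability"))
    return(list(jaccard = as.list(x$jaccard), labels = as.list(x$labels)))
  if (inherits(x, "k_selection"))
    return(list(votes = as.list(x$votes), chosen_k = x$chosen_k))
  if (inherits(x, "pca_result"))
    return(list(eigenvalues = x$eigenvalues,
                explained_pct = x$explained_pct,
                cumulative_pct = x$cumulative_pct,
                loadings = as.data.frame(x$loadings)))
  if (inherits(x, "recovery_report")) return(unclass(x))
  if (is.matrix(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, bundle_to_json))
  x
}
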