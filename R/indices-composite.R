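# Composite indices: PLI, Nemerow PI, CPI (per site, from a PI table)
# and CD / mCD (per zone, from a CF table).

composite_table <- function(index_name, values, classes, metal_subset,
                            normalizer = NULL) {
  structure(list(index_name = index_name, values = values,
                 classes = classes, metal_subset = metal_subset,
                 normalizer = normalizer),
            class = "composite_table")
}

#' @export
print.composite_table <- function(x, ...) {
  cat(sprintf("<composite_table> %s over {%s}\n", x$index_name,
              paste(x$metal_subset, collapse = ", ")))
  print(data.frame(value = signif(x$values, 5), class = x$classes))
  invisible(x)
}

check_pi_table <- function(pi_table, metal_subset) {
  stopifnot(inherits(pi_table, "index_table"))
  if (pi_table$index_name != "PI")
    stop("composite indices are defined over a PI table, got ",
         pi_table$index_name)
  if (length(metal_subset) == 0L) stop("metal subset must be non-empty")
  missing <- setdiff(metal_subset, colnames(pi_table$values))
  if (length(missing) > 0L)
    stop("metal not in PI table: ", paste(missing, collapse = ", "))
  pi_table$values[, metal_subset, drop = FALSE]
}

#' Pollution load index
#'
#' Per-site geometric mean of the pollution index over the chosen metals:
#' `PLI = (prod PI_j)^(1/n)`. Below 1 indicates "perfection" (mean
#' conditions at background), 1 baseline, above 1 contamination; equality
#' with 1 is tested at a 1e-9 tolerance.
#'
#' @param pi_table an `index_table` from [pollution_index()]
#' @param metal_subset metals to aggregate; default all in the table
#' @return a `composite_table` with one value and class per site
#' @export
pli <- function(pi_table, metal_subset = colnames(pi_table$values)) {
  v <- check_pi_table(pi_table, metal_subset)
  val <- exp(rowMeans(log(v)))
  cls <- ifelse(abs(val - 1) <= 1e-9, "baseline contamination",
                ifelse(val < 1, "perfection", "contamination"))
  composite_table("PLI", val, cls, metal_subset)
}

#' Nemerow pollution index
#'
#' Quadratic mean of the site's average and maximum pollution index,
#' `PI_Nem = sqrt((mean(PI)^2 + max(PI)^2) / 2)`, weighting the worst
#' pollutant. Classes: `[0,0.7)` no pollution, `[0.7,1)` warning,
#' `[1,2)` slight, `[2,3)` moderate, at least 3 heavy pollution.
#'
#' @inheritParams pli
#' @return a `composite_table`
#' @export
nemerow <- function(pi_table, metal_subset = colnames(pi_table$values)) {
  v <- check_pi_table(pi_table, metal_subset)
  val <- sqrt((rowMeans(v)^2 + apply(v, 1L, max)^2) / 2)
  composite_table("PI_Nem", val, classify(val, "PI_Nem"), metal_subset)
}

#' Combined pollution index
#'
#' Per-site arithmetic mean of the pollution index over the chosen
#' metals; values above 1 are flagged as high contamination. By the
#' AM-GM inequality `CPI >= PLI` at every site.
#'
#' @inheritParams pli
#' @return a `composite_table`
#' @export
cpi <- function(pi_table, metal_subset = colnames(pi_table$values)) {
  v <- check_pi_table(pi_table, metal_subset)
  val <- rowMeans(v)
  cls <- ifelse(val > 1, "high contamination", "not high")
  composite_table("CPI", val, cls, metal_subset)
}

#' Contamination degree and modified contamination degree
#'
#' `CD` sums a zone's contamination factors over the assessed metals;
#' `mCD = CD / n` averages them. CD is classified on the CF intervals
#' multiplied by the number of metals; mCD on the raw CF intervals
#' (low / moderate / high / very high).
#'
#' @param cf_table an `index_table` from [contamination_factor()] or
#'   [cf_from_means()] (one row per zone)
#' @param metal_subset metals to sum; default all metals in the CF table
#' @return a list with `composite_table`s `CD` and `mCD`
#' @export
#' @examples
#' ref <- reference_set()
#' cf <- cf_from_means(c(Cd = 33.219, Cr = 104.14, Cu = 59.970,
#'                       Ni = 1325.4, Pb = 103.9, Zn = 712.86,
#'                       Mn = 233.667), ref)
#' contamination_degree(cf)$CD$values   # 60.90
contamination_degree <- function(cf_table,
                                 metal_subset = colnames(cf_table$values)) {
  stopifnot(inherits(cf_table, "index_table"))
  if (cf_table$index_name != "CF")
    stop("contamination degree is defined over a CF table")
  missing <- setdiff(metal_subset, colnames(cf_table$values))
  if (length(missing) > 0L)
    stop("metal not in CF table: ", paste(missing, collapse = ", "))
  v <- cf_table$values[, metal_subset, drop = FALSE]
  n <- length(metal_subset)
  cd <- rowSums(v)
  mcd <- cd / n
  cd_scheme <- classification_scheme(
    "CD", index_schemes$CF$breakpoints * n, index_schemes$CF$labels)
  list(CD = composite_table("CD", cd, classify(cd, cd_scheme), metal_subset),
       mCD = composite_table("mCD", mcd, classify(mcd, "CF"), metal_subset))
}

#' Recompute a composite with one metal excluded
#'
#' Sensitivity analysis for a dominating pollutant: recomputes a
#' composite index on the subset minus one metal and reports both
#' variants side by side (e.g. the Nemerow index with and without Cd,
#' whose very high PI can swamp the composite).
#'
#' @param index_op one of [pli()], [nemerow()], [cpi()]
#' @param pi_table an `index_table` from [pollution_index()]
#' @param exclude metal symbol to drop; must be in `metal_subset`
#' @param metal_subset metals for the full variant
#' @return a list with `with` and `without` `composite_table`s and the
#'   excluded metal
#' @export
sensitivity_without <- function(index_op, pi_table, exclude,
                                metal_subset = colnames(pi_table$values)) {
  if (!exclude %in% metal_subset)
    stop("excluded metal '", exclude, "' is not in the metal subset")
  reduced <- setdiff(metal_subset, exclude)
  if (length(reduced) == 0L)
    stop("excluding '", exclude, "' leaves an empty metal subset")
  list(with = index_op(pi_table, metal_subset),
       without = index_op(pi_table, reduced),
       excluded = exclude)
}
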