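# Individual pollution indices: Igeo, PI, EF, CF, with their published
# classification schemes.

#' Classification scheme for a pollution index
#'
#' Encodes the ordered class intervals an index maps into. All intervals
#' close on the left (`[a, b)`), with the topmost class closed below per
#' the usual ">=" wording; the bottom interval is open below (so for the
#' geo-accumulation index the "unpolluted" class is the open interval
#' below 0). Classification is exhaustive and exclusive: every finite
#' value maps to exactly one class.
#'
#' @param index_name name of the index the scheme belongs to
#' @param breakpoints strictly increasing interior breakpoints
#' @param labels class labels, one more than there are breakpoints
#' @return an object of class `class_scheme`
#' @export
classification_scheme <- function(index_name, breakpoints, labels) {
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  if (length(labels) != length(breakpoints) + 1L)
    stop("need one label per interval: ", length(breakpoints) + 1L)
  structure(list(index_name = index_name, breakpoints = breakpoints,
                 labels = labels),
            class = "class_scheme")
}

# Published interval schemes for the individual and composite indices.
index_schemes <- list(
  Igeo = classification_scheme("Igeo", c(0, 1, 2, 3, 4, 5),
    c("unpolluted", "unpolluted to moderately polluted",
      "moderately polluted", "moderately to strongly polluted",
      "strongly polluted", "strongly to extremely polluted",
      "extremely polluted")),
  PI = classification_scheme("PI", c(1, 2, 3, 5),
    c("none", "low", "moderate", "strong", "very accentuated")),
  EF = classification_scheme("EF", c(2, 5, 20, 40),
    c("deficient to minimal", "moderate", "significant",
      "very high", "extremely high")),
  CF = classification_scheme("CF", c(1, 3, 6),
    c("low", "moderate", "high", "very high")),
  PI_Nem = classification_scheme("PI_Nem", c(0.7, 1, 2, 3),
    c("no pollution", "warning", "slight pollution",
      "moderate pollution", "heavy pollution"))
)

#' Classify index values under a scheme
#'
#' @param values numeric vector/matrix of finite index values
#' @param scheme a [classification_scheme()] or the name of a packaged
#'   scheme (`"Igeo"`, `"PI"`, `"EF"`, `"CF"`, `"PI_Nem"`)
#' @return character labels with the shape of `values`
#' @export
classify <- function(values, scheme) {
  if (is.character(scheme)) scheme <- index_schemes[[scheme]]
  stopifnot(inherits(scheme, "class_scheme"))
  idx <- findInterval(values, scheme$breakpoints, left.open = FALSE) + 1L
  out <- scheme$labels[idx]
  if (is.matrix(values)) {
    out <- matrix(out, nrow(values), ncol(values),
                  dimnames = dimnames(values))
  } else {
    names(out) <- names(values)
  }
  out
}

# Shared constructor for per-site, per-metal index tables.
index_table <- function(index_name, values, scheme, normalizer = NULL) {
  structure(list(index_name = index_name, normalizer = normalizer,
                 values = values, classes = classify(values, scheme)),
            class = "index_table")
}

#' @export
print.index_table <- function(x, ...) {
  cat(sprintf("<index_table> %s%s: %d sites x %d metals\n", x$index_name,
              if (is.null(x$normalizer)) "" else
                paste0(" (normalizer ", x$normalizer, ")"),
              nrow(x$values), ncol(x$values)))
  print(signif(utils::head(x$values, 4L), 4))
  if (nrow(x$values) > 4L) cat("...\n")
  invisible(x)
}

#' Geo-accumulation index
#'
#' `Igeo = log2(C / (1.5 * CB))` per site and metal, where `C` is the
#' measured concentration and `CB` the geochemical background; the factor
#' 1.5 buffers natural lithological variation. Seven pollution classes
#' from "unpolluted" (`Igeo < 0`) to "extremely polluted" (`Igeo >= 5`).
#'
#' @param conc a [concentration_matrix()]
#' @param ref a [reference_set()] with background values for every metal
#'   in `conc` (or every metal in `metal_subset`)
#' @param metal_subset metals to compute; default all metals in `conc`
#' @return an `index_table` with `values` and `classes`
#' @export
igeo <- function(conc, ref, metal_subset = metals(conc)) {
  stopifnot(inherits(conc, "conc_matrix"), inherits(ref, "reference_set"))
  cb <- require_background(ref, metal_subset)
  v <- log2(sweep(conc$values[, metal_subset, drop = FALSE], 2L,
                  1.5 * cb, "/"))
  index_table("Igeo", v, "Igeo")
}

#' Pollution index
#'
#' `PI = C / CB`: the plain concentration-to-background ratio. Classes:
#' below 1 no pollution, `[1,2)` low, `[2,3)` moderate, `[3,5)` strong,
#' at least 5 very accentuated.
#'
#' @inheritParams igeo
#' @return an `index_table`
#' @export
pollution_index <- function(conc, ref, metal_subset = metals(conc)) {
  stopifnot(inherits(conc, "conc_matrix"), inherits(ref, "reference_set"))
  cb <- require_background(ref, metal_subset)
  v <- sweep(conc$values[, metal_subset, drop = FALSE], 2L, cb, "/")
  index_table("PI", v, "PI")
}

#' Enrichment factor
#'
#' Double ratio `EF_i = (C_i / C_norm)_sample / (CB_i / CB_norm)` with a
#' crustal reference element (typically Mn or Fe) as normalizer, so that
#' uniform dilution or concentration of a sample cancels and what remains
#' is enrichment relative to the background composition. The normalizer
#' metal itself always has `EF = 1`. Classes: below 2 deficient to
#' minimal, `[2,5)` moderate, `[5,20)` significant, `[20,40)` very high,
#' at least 40 extremely high.
#'
#' @inheritParams igeo
#' @param normalizer metal symbol used as the crustal reference element;
#'   must be present in both the matrix and the background set
#' @return an `index_table` carrying its `normalizer`
#' @export
enrichment_factor <- function(conc, ref, normalizer = "Mn",
                              metal_subset = metals(conc)) {
  stopifnot(inherits(conc, "conc_matrix"), inherits(ref, "reference_set"))
  if (!normalizer %in% metals(conc))
    stop("normalizer '", normalizer, "' not present in the matrix")
  cb <- require_background(ref, unique(c(metal_subset, normalizer)))
  sample_ratio <- sweep(conc$values[, metal_subset, drop = FALSE], 1L,
                        conc$values[, normalizer], "/")
  bg_ratio <- cb[metal_subset] / cb[normalizer]
  v <- sweep(sample_ratio, 2L, bg_ratio, "/")
  index_table("EF", v, "EF", normalizer = normalizer)
}

#' Contamination factor from zone mean concentrations
#'
#' `CF_j = C_avj / C_pj`: the ratio of a mean concentration (over at
#' least five samples in the Hakanson scheme) to the pre-industrial
#' reference level. This lower-level entry point takes a vector of
#' already-averaged concentrations, e.g. the per-zone means printed in a
#' study's descriptive-statistics table; [contamination_factor()] wraps
#' it for raw site-by-metal matrices.
#'
#' @param means named numeric vector of mean concentrations (mg/kg)
#' @param ref a [reference_set()]; metals without a pre-industrial value
#'   are dropped with a warning
#' @return an `index_table` with one row ("mean")
#' @export
cf_from_means <- function(means, ref) {
  stopifnot(inherits(ref, "reference_set"))
  have <- intersect(names(means), names(ref$preindustrial))
  drop <- setdiff(names(means), have)
  if (length(have) == 0L)
    stop("no pre-industrial reference value for any requested metal")
  if (length(drop) > 0L)
    warning("no pre-industrial reference for ",
            paste(drop, collapse = ", "), "; excluded from CF")
  v <- matrix(means[have] / ref$preindustrial[have], nrow = 1L,
              dimnames = list("mean", have))
  index_table("CF", v, "CF")
}

#' Contamination factor for one zone
#'
#' Averages each metal's concentration over the zone's sites (arithmetic
#' mean) and divides by the pre-industrial reference. Requires at least
#' five sites in the zone, per the index's definition; metals without a
#' pre-industrial reference are excluded with a warning. Classes:
#' `[0,1)` low, `[1,3)` moderate, `[3,6)` high, above 6 very high.
#'
#' @inheritParams igeo
#' @param zone zone label in `zones(conc)`
#' @param min_sites minimum number of sites required (default 5)
#' @return an `index_table` with a single row named after the zone
#' @export
contamination_factor <- function(conc, ref, zone, min_sites = 5L) {
  stopifnot(inherits(conc, "conc_matrix"))
  zc <- zone_subset(conc, zone)
  if (nrow(zc$values) < min_sites)
    stop(sprintf(
      "zone '%s' has %d sites; the contamination factor is defined over the mean of at least %d samples",
      zone, nrow(zc$values), min_sites))
  tab <- cf_from_means(colMeans(zc$values), ref)
  rownames(tab$values) <- rownames(tab$classes) <- zone
  tab
}
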