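# Core data containers: concentration matrices and reference sets.

#' Construct a validated site-by-metal concentration matrix
#'
#' The concentration matrix is the pipeline's sole measured input: one row
#' per sampling site, one column per metal, values in mg/kg dry weight
#' (numerically identical to ug/g; both are 1e-6 mass fraction). Every site
#' belongs to exactly one zone (e.g. two urban areas sampled in the same
#' campaign); zone membership is either supplied explicitly or inferred
#' from the leading letters of the site id ("KF1" -> zone "KF").
#'
#' @param values numeric matrix, sites in rows (rownames = site ids),
#'   metals in columns (colnames = metal symbols such as "Cd", "Ni").
#' @param zones optional named character vector mapping site id to zone
#'   label. When `NULL`, zones are inferred from the non-digit prefix of
#'   each site id. An explicit mapping always wins over inference.
#' @return an object of class `conc_matrix` with elements `values`
#'   (the validated matrix) and `zones` (named character vector).
#' @export
#' @examples
#' m <- matrix(c(5, 8, 40, 60), 2, 2,
#'             dimnames = list(c("A1", "A2"), c("Cd", "Ni")))
#' cm <- concentration_matrix(m)
#' zones(cm)
concentration_matrix <- function(values, zones = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (sites x metals)")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("need at least 1 site and 1 metal")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("metal symbols must be supplied as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate site id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate metal symbol: ",
         colnames(values)[duplicated(colnames(values))][1L])
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    s <- rownames(values)[bad[1L, 1L]]
    m <- colnames(values)[bad[1L, 2L]]
    stop(sprintf(
      "concentration must be strictly positive and finite: site %s, metal %s (value %s)",
      s, m, format(values[bad[1L, 1L], bad[1L, 2L]])))
  }
  if (is.null(zones)) {
    zones <- infer_zones(rownames(values))
  } else {
    zones <- zones[rownames(values)]
    if (anyNA(zones) || is.null(names(zones)))
      stop("`zones` must name a zone for every site; missing: ",
           paste(rownames(values)[is.na(zones)], collapse = ", "))
  }
  structure(list(values = values, zones = zones), class = "conc_matrix")
}

# Non-digit leading prefix of each site id defines its zone ("KF3" -> "KF").
infer_zones <- function(site_ids) {
  z <- sub("^([^0-9]*).*$", "\\1", site_ids)
  z[z == ""] <- "all"
  names(z) <- site_ids
  z
}

#' @export
print.conc_matrix <- function(x, ...) {
  cat(sprintf("<conc_matrix> %d sites x %d metals; zones: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s (n=%d)", names(table(x$zones)),
                            as.integer(table(x$zones))), collapse = ", ")))
  print(utils::head(x$values, 4L))
  if (nrow(x$values) > 4L) cat("...\n")
  invisible(x)
}

#' @rdname concentration_matrix
#' @param x a `conc_matrix`
#' @export
zones <- function(x) x$zones

#' @rdname concentration_matrix
#' @export
sites <- function(x) rownames(x$values)

#' @rdname concentration_matrix
#' @export
metals <- function(x) colnames(x$values)

#' Subset a concentration matrix to one zone
#'
#' @param x a `conc_matrix`
#' @param zone zone label present in `zones(x)`
#' @return a `conc_matrix` holding only that zone's sites
#' @export
zone_subset <- function(x, zone) {
  stopifnot(inherits(x, "conc_matrix"))
  keep <- names(x$zones)[x$zones == zone]
  if (length(keep) == 0L)
    stop("no sites in zone '", zone, "'")
  concentration_matrix(x$values[keep, , drop = FALSE],
                       zones = x$zones[keep])
}

#' Read a concentration table from a delimited file
#'
#' Canonical format is a wide CSV (UTF-8, "." decimal separator): first
#' column site ids, remaining columns one metal each, header row of metal
#' symbols. A long format with columns `site`, `metal`, `value` is
#' accepted via `long = TRUE`.
#'
#' @param path path to a CSV file
#' @param zones optional named character vector site -> zone; `NULL`
#'   infers zones from site-id prefixes
#' @param long logical; read three-column long format instead of wide
#' @param sep field separator, default ","
#' @return a validated [concentration_matrix()]
#' @export
read_concentrations <- function(path, zones = NULL, long = FALSE, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (long) {
    need <- c("site", "metal", "value")
    if (!all(need %in% names(df)))
      stop("long format requires columns site, metal, value")
    site_lv <- unique(df$site); metal_lv <- unique(df$metal)
    m <- matrix(NA_real_, length(site_lv), length(metal_lv),
                dimnames = list(site_lv, metal_lv))
    m[cbind(match(df$site, site_lv), match(df$metal, metal_lv))] <- df$value
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value: site %s, metal %s",
                   site_lv[idx[1L]], metal_lv[idx[2L]]))
    }
    return(concentration_matrix(m, zones = zones))
  }
  site_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric concentration values in ", path)
  rownames(vals) <- site_ids
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value: site %s, metal %s",
                 site_ids[idx[1L]], colnames(vals)[idx[2L]]))
  }
  concentration_matrix(vals, zones = zones)
}

#' Write a concentration matrix to CSV
#'
#' Round-trips with [read_concentrations()]: decimal values of up to 15
#' significant digits are reproduced bit-identically.
#'
#' @param x a `conc_matrix`
#' @param path output path
#' @export
write_concentrations <- function(x, path) {
  stopifnot(inherits(x, "conc_matrix"))
  df <- data.frame(site = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pre-industrial reference concentrations (ug/g), Hakanson scheme.
# These are the seven metals the contamination-factor family is defined for.
PREINDUSTRIAL_DEFAULTS <- c(Cd = 1, Cr = 90, Cu = 50, Ni = 68,
                            Pb = 70, Zn = 175, Mn = 850)

#' Construct a reference set
#'
#' A reference set carries the two kinds of per-metal reference
#' concentrations the indices need: geochemical *background* values
#' (`CB`, mg/kg) used by the geo-accumulation index, pollution index and
#' enrichment factor, and *pre-industrial* values (`Cp`, ug/g) used by
#' the contamination factor. Pre-industrial defaults for Cd, Cr, Cu, Ni,
#' Pb, Zn and Mn are packaged (Hakanson's reference list); background
#' values have no packaged defaults and must be supplied — silently
#' assuming a background set would bake unverifiable numbers into every
#' downstream index.
#'
#' @param background named numeric vector metal -> background (mg/kg), or
#'   `NULL` if only CF-family indices are needed
#' @param preindustrial named numeric vector of overrides/additions to the
#'   packaged pre-industrial defaults
#' @param normalizers character vector of metals acceptable as enrichment
#'   normalizers (crustal reference elements), default `c("Mn", "Fe")`
#' @return an object of class `reference_set`
#' @export
#' @examples
#' ref <- reference_set(background = c(Cd = 0.4, Ni = 45, Mn = 200))
#' ref$preindustrial["Cd"]   # packaged default: 1
reference_set <- function(background = NULL, preindustrial = NULL,
                          normalizers = c("Mn", "Fe")) {
  pre <- PREINDUSTRIAL_DEFAULTS
  check_ref <- function(v, what) {
    if (is.null(v)) return(NULL)
    v <- unlist(v)
    if (is.null(names(v)) || any(names(v) == ""))
      stop(what, " values must be named by metal symbol")
    if (any(!is.finite(v) | v <= 0))
      stop(what, " reference must be strictly positive: ",
           names(v)[which(!is.finite(v) | v <= 0)][1L])
    v
  }
  background <- check_ref(background, "background")
  preindustrial <- check_ref(preindustrial, "preindustrial")
  if (!is.null(preindustrial)) pre[names(preindustrial)] <- preindustrial
  structure(list(background = background, preindustrial = pre,
                 normalizers = normalizers),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>\n  background: ",
      if (is.null(x$background)) "(none supplied)" else
        paste(names(x$background), signif(x$background, 4),
              sep = "=", collapse = ", "),
      "\n  preindustrial: ",
      paste(names(x$preindustrial), x$preindustrial,
            sep = "=", collapse = ", "),
      "\n  normalizers: ", paste(x$normalizers, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read a reference configuration from YAML
#'
#' The config may declare blocks `background:`, `preindustrial:`,
#' `normalizers:` and `zones:` (site -> zone). User values are merged over
#' the packaged pre-industrial defaults; an empty config yields the seven
#' packaged pre-industrial values and no backgrounds.
#'
#' @param path path to a YAML file
#' @return a `reference_set`; if the config declares `zones:` they are
#'   attached as attribute `"zones"` (a named character vector)
#' @export
read_reference_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  ref <- reference_set(
    background = cfg$background,
    preindustrial = cfg$preindustrial,
    normalizers = if (is.null(cfg$normalizers)) c("Mn", "Fe")
                  else as.character(cfg$normalizers))
  if (!is.null(cfg$zones))
    attr(ref, "zones") <- unlist(cfg$zones)
  ref
}

# Background lookup shared by the background-referenced indices.
require_background <- function(ref, metals_needed) {
  if (is.null(ref$background))
    stop("no background concentrations supplied; ",
         "background values are config-mandatory for this index")
  missing <- setdiff(metals_needed, names(ref$background))
  if (length(missing) > 0L)
    stop("missing background value for metal: ",
         paste(missing, collapse = ", "))
  ref$background[metals_needed]
}
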