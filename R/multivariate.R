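# Correlation-matrix PCA for source attribution, component selection,
# variable contributions / cos2, and nonparametric zone comparison.

#' Correlation-matrix principal component analysis
#'
#' z-scores each metal column and eigendecomposes the correlation
#' matrix, so the analysis is invariant to per-metal affine rescaling of
#' the raw concentrations and no single high-magnitude metal dominates.
#' Loadings are eigenvectors scaled by the square root of their
#' eigenvalue (so `cos2 = loading^2` per metal and component, and the
#' cos2 of a metal over all components sums to 1). Component signs are
#' fixed so each component's largest-magnitude loading is positive.
#'
#' @param x a `conc_matrix`, or any numeric site-by-variable matrix
#' @param zone optional zone label; when given, only that zone's sites
#'   enter the analysis
#' @return an object of class `pca_result`: `eigenvalues`,
#'   `explained_pct`, `cumulative_pct`, `loadings`, `contributions_pct`,
#'   `cos2` (all metal-by-component), `site_scores`
#' @export
pca <- function(x, zone = NULL) {
  if (inherits(x, "conc_matrix")) {
    if (!is.null(zone)) x <- zone_subset(x, zone)
    x <- x$values
  }
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("PCA needs at least 3 sites")
  z <- standardize_profiles(x)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  vec <- eig$vectors
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  p <- ncol(x)
  dimn <- list(colnames(x), paste0("PC", seq_len(p)))
  loadings <- sweep(vec, 2L, sqrt(ev), "*")
  dimnames(loadings) <- dimn
  contrib <- sweep(vec^2, 2L, ifelse(ev > 0, 1, NA), "*") * 100
  dimnames(contrib) <- dimn
  cos2 <- loadings^2
  scores <- z %*% vec
  colnames(scores) <- dimn[[2L]]
  structure(list(
    eigenvalues = ev,
    explained_pct = 100 * ev / sum(ev),
    cumulative_pct = cumsum(100 * ev / sum(ev)),
    loadings = loadings,
    contributions_pct = contrib,
    cos2 = cos2,
    site_scores = scores), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n")
  print(data.frame(eigenvalue = round(x$eigenvalues, 3),
                   explained_pct = round(x$explained_pct, 3),
                   cumulative_pct = round(x$cumulative_pct, 3),
                   row.names = colnames(x$loadings)))
  invisible(x)
}

#' Choose how many principal components to retain
#'
#' Reports the component count under the Kaiser rule (eigenvalue above
#' 1), under a cumulative-explained-variance rule (smallest count
#' reaching `variance_threshold`), and the operative choice: the Kaiser
#' count, extended with further components while the cumulative
#' explained variance stays below the threshold.
#'
#' @param result a [pca()] result
#' @param variance_threshold target fraction of variance, default 0.8
#'   ("more than four fifths" of the initial variables' variance)
#' @return list `kaiser`, `variance_rule`, `chosen` (integer counts) and
#'   `cumulative_pct` at the chosen count
#' @export
select_components <- function(result, variance_threshold = 0.8) {
  stopifnot(inherits(result, "pca_result"))
  kaiser <- sum(result$eigenvalues > 1)
  cum <- result$cumulative_pct
  variance_rule <- which(cum >= 100 * variance_threshold)[1L]
  chosen <- kaiser
  if (chosen == 0L || cum[max(chosen, 1L)] < 100 * variance_threshold)
    chosen <- variance_rule
  list(kaiser = kaiser, variance_rule = as.integer(variance_rule),
       chosen = as.integer(chosen),
       cumulative_pct = unname(cum[chosen]))
}

#' Variable contributions to one or several components
#'
#' The contribution of metal `i` to component `c` is
#' `100 * loading(i,c)^2 / eigenvalue(c)` (percent; each component's
#' contributions sum to 100). Over several components the contributions
#' are combined as an eigenvalue-weighted average, and the expected
#' average contribution reference (the level every metal would have if
#' all contributed equally) is `100 / n_metals`.
#'
#' @param result a [pca()] result
#' @param dims integer vector of component indices, default `1:3`
#' @return list `contributions` (named percent per metal, sorted
#'   decreasing), `expected_average`
#' @export
contributions <- function(result, dims = 1:3) {
  stopifnot(inherits(result, "pca_result"))
  ctr <- result$contributions_pct[, dims, drop = FALSE]
  ev <- result$eigenvalues[dims]
  combined <- drop(ctr %*% ev) / sum(ev)
  list(contributions = sort(combined, decreasing = TRUE),
       expected_average = 100 / nrow(result$loadings))
}

#' Compare index distributions between zones
#'
#' For each supplied indicator (per-site index table, e.g. Igeo, PI and
#' the enrichment factor under each normalizer), pools the per-site,
#' per-metal values of each zone and applies the Kruskal-Wallis rank
#' test between zones. Testing the index series rather than the raw
#' concentration series keeps the comparison physically meaningful:
#' the indices are dimensionless and comparable across metals, raw
#' concentrations of different metals are not. When every value is tied
#' across groups the test statistic is undefined; `H = 0, p = 1` is
#' returned by convention.
#'
#' @param index_tables named list of lists: for each indicator name, a
#'   list of per-zone `index_table`s (or plain numeric vectors/matrices)
#' @return data.frame with one row per indicator: `indicator`, `H`,
#'   `df`, `p_value`
#' @export
#' @examples
#' a <- matrix(1:6, 2, 3, dimnames = list(NULL, c("Cd", "Ni", "Zn")))
#' b <- a + 10
#' compare_zones(list(PI = list(KF = a, D = b)))
compare_zones <- function(index_tables) {
  stopifnot(is.list(index_tables), !is.null(names(index_tables)))
  rows <- lapply(names(index_tables), function(ind) {
    groups <- lapply(index_tables[[ind]], function(g) {
      if (inherits(g, "index_table")) g <- g$values
      as.numeric(g)
    })
    if (length(groups) < 2L || any(lengths(groups) < 2L))
      stop("indicator ", ind, ": need >= 2 groups with >= 2 values each")
    values <- unlist(groups)
    if (length(unique(values)) == 1L) {
      return(data.frame(indicator = ind, H = 0, df = length(groups) - 1L,
                        p_value = 1))
    }
    g <- factor(rep(names(groups), lengths(groups)))
    kw <- stats::kruskal.test(values, g)
    data.frame(indicator = ind, H = unname(kw$statistic),
               df = unname(kw$parameter), p_value = kw$p.value)
  })
  do.call(rbind, rows)
}

#' Compare index levels across metals within one zone
#'
#' Within a zone, tests whether the per-site index series of the
#' different metals share a common distribution (Kruskal-Wallis across
#' metals). A small p-value says the metals sit at significantly
#' different pollution levels.
#'
#' @param index_tab an `index_table` for one zone
#' @return list `H`, `df`, `p_value`
#' @export
compare_metals <- function(index_tab) {
  stopifnot(inherits(index_tab, "index_table"))
  v <- index_tab$values
  if (ncol(v) < 2L || nrow(v) < 2L)
    stop("need >= 2 metals and >= 2 sites")
  if (length(unique(as.numeric(v))) == 1L)
    return(list(H = 0, df = ncol(v) - 1L, p_value = 1))
  g <- factor(rep(colnames(v), each = nrow(v)))
  kw <- stats::kruskal.test(as.numeric(v), g)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value)
}
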