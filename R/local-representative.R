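# Representative local level of an index series: condense a zone's
# per-metal index values into the modal equal-width sub-interval.

#' Representative sub-interval of each metal's index series
#'
#' For each metal (one row of the site-by-metal index matrix, transposed
#' so a "row" is that metal's values over the zone's sites):
#' \enumerate{
#'   \item split the range `[min, max]` into `m` equal-width bins,
#'     left-closed, right-open, the last bin closed on the right so the
#'     maximum is binned;
#'   \item count the values falling in each bin;
#'   \item the representative sub-interval is the bin with the highest
#'     count; ties are broken toward the bin whose internal mean is
#'     closest to the mean of the whole row (remaining exact-distance
#'     ties toward the leftmost such bin);
#'   \item if any bin is empty, `m` is decremented until no bin is empty
#'     (never below 2) and the value used is recorded as `m_used`.
#' }
#' The representative value reported for the metal is the mean of the
#' values inside the chosen sub-interval.
#'
#' @param index_matrix numeric site-by-metal matrix of index values for
#'   one zone (e.g. `$values` of an `index_table`)
#' @param m number of equal-width bins to attempt, default 3
#' @return a data.frame of class `representative_level` with one row per
#'   metal: `metal`, interval bounds `lo` / `hi`, `frequency`,
#'   `representative_value`, `m_used`
#' @export
#' @examples
#' x <- matrix(c(1, 2, 5, 6, 9), 5, 1, dimnames = list(NULL, "Cd"))
#' representative_level(x)   # chooses [3.667, 6.333), value 5.5
representative_level <- function(index_matrix, m = 3L) {
  stopifnot(is.matrix(index_matrix), is.numeric(index_matrix))
  if (m < 2L) stop("m must be at least 2")
  out <- lapply(colnames(index_matrix), function(met) {
    row <- index_matrix[, met]
    if (length(unique(row)) < 2L)
      stop("metal ", met,
           ": all index values identical; bins are undefined")
    res <- representative_bin(row, m)
    data.frame(metal = met, lo = res$lo, hi = res$hi,
               frequency = res$frequency,
               representative_value = res$value,
               m_used = res$m_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("representative_level", "data.frame")
  out
}

# Core per-row binning. Decrements m while any bin is empty; with >= 2
# distinct values, m = 2 always has the min in the first bin and the max
# in the last, so termination is guaranteed.
representative_bin <- function(row, m) {
  lo <- min(row); hi <- max(row)
  for (m_try in seq(m, 2L)) {
    edges <- seq(lo, hi, length.out = m_try + 1L)
    bin <- findInterval(row, edges, rightmost.closed = TRUE)
    freq <- tabulate(bin, nbins = m_try)
    if (all(freq > 0L)) {
      best <- which(freq == max(freq))
      if (length(best) > 1L) {
        target <- mean(row)
        dist <- vapply(best, function(b) abs(mean(row[bin == b]) - target),
                       numeric(1))
        best <- best[which.min(dist)]
      }
      inside <- row[bin == best]
      return(list(lo = edges[best], hi = edges[best + 1L],
                  frequency = max(freq), value = mean(inside),
                  m_used = m_try))
    }
  }
  stop("no non-empty binning found (unreachable for >= 2 distinct values)")
}

#' Representative local enrichment levels for a zone
#'
#' Chains [enrichment_factor()] (or another per-site index) with
#' [representative_level()]: computes the index over the zone's sites,
#' then condenses each metal's series to its representative
#' sub-interval. The same condensation applies to pollution-index or
#' geo-accumulation matrices via `index`.
#'
#' @inheritParams contamination_factor
#' @param normalizer crustal reference element for the enrichment factor
#' @param m bin count passed to [representative_level()]
#' @param index which per-site index to condense: `"EF"` (default),
#'   `"PI"` or `"Igeo"`
#' @return a `representative_level` data.frame, metals in matrix order
#' @export
ef_local_report <- function(conc, ref, zone, normalizer = "Mn", m = 3L,
                            index = c("EF", "PI", "Igeo")) {
  index <- match.arg(index)
  zc <- zone_subset(conc, zone)
  tab <- switch(index,
    EF = enrichment_factor(zc, ref, normalizer = normalizer),
    PI = pollution_index(zc, ref),
    Igeo = igeo(zc, ref))
  vals <- tab$values
  if (index == "EF")  # the normalizer's own EF is identically 1
    vals <- vals[, setdiff(colnames(vals), normalizer), drop = FALSE]
  rl <- representative_level(vals, m = m)
  attr(rl, "zone") <- zone
  attr(rl, "index") <- index
  attr(rl, "normalizer") <- if (index == "EF") normalizer else NULL
  rl
}
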