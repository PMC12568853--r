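# Independent brute-force oracles, deliberately written with plain loops
# and explicit comparisons so they share no code path with the package.

# Representative sub-interval by explicit enumeration: scan every bin,
# count members by direct comparison, resolve ties by recomputing bin
# means from scratch.
brute_representative <- function(row, m = 3L) {
  lo <- min(row)
  hi <- max(row)
  for (mm in seq(m, 2L)) {
    width <- (hi - lo) / mm
    counts <- integer(mm)
    members <- vector("list", mm)
    for (x in row) {
      placed <- FALSE
      for (b in seq_len(mm)) {
        left <- lo + (b - 1L) * width
        right <- lo + b * width
        inside <- if (b < mm) (x >= left && x < right)
                  else (x >= left && x <= hi)
        if (inside) {
          counts[b] <- counts[b] + 1L
          members[[b]] <- c(members[[b]], x)
          placed <- TRUE
          break
        }
      }
      stopifnot(placed)
    }
    if (any(counts == 0L)) next
    top <- which(counts == max(counts))
    if (length(top) > 1L) {
      target <- mean(row)
      dists <- sapply(top, function(b) abs(mean(members[[b]]) - target))
      top <- top[which.min(dists)]
    }
    return(list(bin = top, lo = lo + (top - 1L) * (hi - lo) / mm,
                hi = lo + top * (hi - lo) / mm,
                frequency = max(counts),
                value = mean(members[[top]]), m_used = mm))
  }
  stop("constant row")
}

# Exhaustive k-medoids optimum: enumerate every medoid subset.
exhaustive_kmedoids_cost <- function(profiles, k) {
  D <- as.matrix(stats::dist(profiles))
  n <- nrow(D)
  best <- Inf
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(D[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# Gaussian clouds at given centers; rows shuffled to avoid ordered labels.
make_clouds <- function(centers, n_per = 8L, sd = 0.2, seed = 1L,
                        shuffle = TRUE) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(stats::rnorm(n_per * ncol(centers), mean = centers[i, ],
                        sd = sd),
           n_per, ncol(centers), byrow = TRUE)))
  labels <- rep(seq_len(nrow(centers)), each = n_per)
  if (shuffle) {
    ord <- sample(nrow(x))
    x <- x[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  rownames(x) <- paste0("p", seq_len(nrow(x)))
  list(x = x, labels = labels)
}

# Tiny valid concentration matrix for I/O and index tests.
toy_conc <- function() {
  m <- matrix(c(1.2, 2.4, 0.9,
                40, 80, 30,
                300, 600, 225),
              nrow = 3,
              dimnames = list(c("KF1", "KF2", "D1"),
                              c("Cd", "Ni", "Mn")))
  concentration_matrix(m)
}

toy_ref <- function() {
  reference_set(background = c(Cd = 0.4, Ni = 40, Mn = 300, Fe = 10000))
}
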