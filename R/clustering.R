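# k-medoids clustering of site concentration profiles, internal validity
# indices, majority-vote selection of k, and bootstrap-Jaccard stability.

#' Standardize site profiles for clustering and ordination
#'
#' z-scores each metal column (mean 0, sd 1) so that high-magnitude
#' metals (Fe, Ni) do not dominate Euclidean dissimilarities.
#'
#' @param x a `conc_matrix` or numeric site-by-metal matrix
#' @return a plain numeric matrix of z-scores
#' @export
standardize_profiles <- function(x) {
  if (inherits(x, "conc_matrix")) x <- x$values
  s <- apply(x, 2L, stats::sd)
  if (any(s == 0))
    stop("constant metal column: ",
         paste(colnames(x)[s == 0], collapse = ", "))
  z <- scale(x)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  z
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Total cost of a medoid set: sum over points of the distance to the
# nearest medoid. D is the full symmetric distance matrix.
medoid_cost <- function(D, medoids) {
  sum(apply(D[, medoids, drop = FALSE], 1L, min))
}

#' k-medoids clustering (PAM) with seeded restarts
#'
#' Partitions site profiles into `k` clusters, each represented by one of
#' its own members (the medoid), minimizing the sum of point-to-medoid
#' dissimilarities. Each restart draws a random initial medoid set and
#' applies best-improvement swaps (exchange a medoid for a non-medoid)
#' until no swap lowers the objective; the best local optimum over
#' `n_restarts` restarts is kept. Deterministic for a fixed seed.
#'
#' @param profiles numeric site-by-feature matrix, typically
#'   [standardize_profiles()] output
#' @param k number of clusters, `2 <= k <= n_sites`
#' @param seed integer seed for the restart draws
#' @param n_restarts random restarts (default 10)
#' @return an object of class `cluster_solution`: `k`, `medoids` (row
#'   indices), `medoid_sites`, `assignment` (named cluster index per
#'   site), `total_cost`
#' @export
kmedoids <- function(profiles, k, seed = 20250829L, n_restarts = 10L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k < 2L || k > n)
    stop("k must satisfy 2 <= k <= number of sites (", n, ")")
  D <- as.matrix(stats::dist(profiles))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      medoids <- sort(sample.int(n, k))
      cost <- medoid_cost(D, medoids)
      repeat {
        best_swap <- NULL
        best_cost <- cost
        for (m_i in seq_along(medoids)) {
          for (h in setdiff(seq_len(n), medoids)) {
            cand <- medoids
            cand[m_i] <- h
            cc <- medoid_cost(D, cand)
            if (cc < best_cost - 1e-12) {
              best_cost <- cc
              best_swap <- cand
            }
          }
        }
        if (is.null(best_swap)) break
        medoids <- sort(best_swap)
        cost <- best_cost
      }
      if (is.null(best) || cost < best$cost - 1e-12) {
        best <- list(medoids = medoids, cost = cost)
      }
    }
  })
  assignment <- apply(D[, best$medoids, drop = FALSE], 1L, which.min)
  names(assignment) <- rownames(profiles)
  structure(list(k = k, medoids = best$medoids,
                 medoid_sites = rownames(profiles)[best$medoids],
                 assignment = assignment, total_cost = best$cost),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, total cost %.4f\n",
              x$k, x$total_cost))
  cat("medoids:", paste(x$medoid_sites, collapse = ", "), "\n")
  print(table(cluster = x$assignment))
  invisible(x)
}

# --- internal validity indices ------------------------------------------

# Connectivity (neighbor-count formulation): for each point, its j-th
# nearest neighbor (j = 1..L) contributes 1/j if it lies in a different
# cluster. Lower is better.
connectivity_index <- function(D, assignment, L = 10L) {
  n <- nrow(D)
  L <- min(L, n - 1L)
  total <- 0
  for (i in seq_len(n)) {
    nn <- order(D[i, ])[-1L][seq_len(L)]
    diff_cl <- assignment[nn] != assignment[i]
    total <- total + sum((1 / seq_len(L))[diff_cl])
  }
  total
}

# Dunn: minimum between-cluster point distance / maximum cluster diameter.
dunn_index <- function(D, assignment) {
  cl <- unique(assignment)
  same <- outer(assignment, assignment, "==")
  diam <- max(D[same & upper.tri(D)])
  inter <- min(D[!same & upper.tri(D)])
  inter / diam
}

calinski_harabasz <- function(profiles, assignment) {
  n <- nrow(profiles)
  k <- length(unique(assignment))
  grand <- colMeans(profiles)
  W <- 0; B <- 0
  for (cl in unique(assignment)) {
    x <- profiles[assignment == cl, , drop = FALSE]
    cen <- colMeans(x)
    W <- W + sum(sweep(x, 2L, cen)^2)
    B <- B + nrow(x) * sum((cen - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

davies_bouldin <- function(profiles, assignment) {
  cls <- sort(unique(assignment))
  cen <- t(vapply(cls, function(cl)
    colMeans(profiles[assignment == cl, , drop = FALSE]),
    numeric(ncol(profiles))))
  S <- vapply(seq_along(cls), function(i) {
    x <- profiles[assignment == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(x, 2L, cen[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cen))
  mean(vapply(seq_along(cls), function(i) {
    max(vapply(seq_along(cls)[-i],
               function(j) (S[i] + S[j]) / M[i, j], numeric(1)))
  }, numeric(1)))
}

#' Internal validity scores of a clustering
#'
#' Connectivity (degree to which nearest neighbors share a cluster;
#' lower is better, `L` nearest neighbors considered), the Dunn index
#' (minimum between-cluster distance over maximum cluster diameter;
#' higher is better) and the mean silhouette width (higher is better).
#'
#' @param solution a `cluster_solution`
#' @param profiles the matrix the solution was fitted on
#' @param L neighbors for the connectivity index, default 10
#' @return named list `connectivity`, `dunn`, `silhouette`
#' @export
validity <- function(solution, profiles, L = 10L) {
  profiles <- as.matrix(profiles)
  D <- as.matrix(stats::dist(profiles))
  sil <- cluster::silhouette(solution$assignment, stats::dist(profiles))
  list(connectivity = connectivity_index(D, solution$assignment, L),
       dunn = dunn_index(D, solution$assignment),
       silhouette = mean(sil[, "sil_width"]))
}

# --- choice of k ---------------------------------------------------------

#' Select the number of clusters by majority vote
#'
#' Runs k-medoids for each candidate `k` and lets five internal indices
#' each cast one vote for the `k` they prefer: mean silhouette (max),
#' Dunn (max), Calinski-Harabasz (max), Davies-Bouldin (min), and the
#' gap statistic (Tibshirani first-SE rule via [cluster::clusGap()]).
#' The `k` with the most votes wins; ties break toward the smaller `k`.
#'
#' @param profiles site-by-feature matrix (standardized)
#' @param candidate_ks integer vector of candidate cluster counts
#'   (at least two candidates, each `>= 2`)
#' @param seed integer seed (restarts and gap-reference draws)
#' @param n_restarts restarts per k-medoids fit
#' @param gap_B reference datasets for the gap statistic, default 30
#' @return a list of class `k_selection`: `candidate_ks`, `votes`
#'   (named count per k), `index_choice` (which k each index chose),
#'   `chosen_k`
#' @export
select_k <- function(profiles, candidate_ks = 2:6, seed = 20250829L,
                     n_restarts = 10L, gap_B = 30L) {
  profiles <- as.matrix(profiles)
  candidate_ks <- sort(unique(as.integer(candidate_ks)))
  if (length(candidate_ks) < 2L) stop("need at least two candidate ks")
  if (max(candidate_ks) >= nrow(profiles))
    stop("candidate k must be below the number of sites")
  D <- as.matrix(stats::dist(profiles))
  fits <- lapply(candidate_ks, function(k)
    kmedoids(profiles, k, seed = seed + k, n_restarts = n_restarts))
  sil <- vapply(fits, function(f)
    mean(cluster::silhouette(f$assignment,
                             stats::dist(profiles))[, "sil_width"]),
    numeric(1))
  dunn <- vapply(fits, function(f) dunn_index(D, f$assignment), numeric(1))
  ch <- vapply(fits, function(f)
    calinski_harabasz(profiles, f$assignment), numeric(1))
  db <- vapply(fits, function(f)
    davies_bouldin(profiles, f$assignment), numeric(1))
  gap_k <- with_seed(seed + 7919L, gap_choice(profiles, candidate_ks,
                                              n_restarts, gap_B))
  index_choice <- c(
    silhouette = candidate_ks[which.max(sil)],
    dunn = candidate_ks[which.max(dunn)],
    calinski_harabasz = candidate_ks[which.max(ch)],
    davies_bouldin = candidate_ks[which.min(db)],
    gap = gap_k)
  votes <- table(factor(index_choice, levels = candidate_ks))
  chosen_k <- candidate_ks[which.max(votes)]  # ties -> smaller k
  structure(list(candidate_ks = candidate_ks,
                 votes = stats::setNames(as.integer(votes), candidate_ks),
                 index_choice = index_choice,
                 scores = data.frame(k = candidate_ks, silhouette = sil,
                                     dunn = dunn, calinski_harabasz = ch,
                                     davies_bouldin = db),
                 chosen_k = chosen_k),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> votes:",
      paste(sprintf("k=%s: %d", names(x$votes), x$votes), collapse = ", "),
      "\n  chosen k =", x$chosen_k, "\n")
  invisible(x)
}

# Gap-statistic vote via cluster::clusGap over k = 1..max(candidates),
# Tibshirani 2001 first-SE rule, clamped to the candidate set.
gap_choice <- function(profiles, candidate_ks, n_restarts, B) {
  pam_fun <- function(x, k) {
    if (k == 1L) return(list(cluster = rep(1L, nrow(x))))
    list(cluster = unname(
      kmedoids(x, k, seed = sample.int(2^31 - 1L, 1L),
               n_restarts = n_restarts)$assignment))
  }
  gp <- cluster::clusGap(profiles, FUNcluster = pam_fun,
                         K.max = max(candidate_ks), B = B, verbose = FALSE)
  tab <- gp$Tab
  k_star <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                           method = "Tibs2001SEmax")
  # clamp to the nearest candidate (smaller on ties)
  candidate_ks[which.min(abs(candidate_ks - k_star))]
}

# --- bootstrap-Jaccard stability ----------------------------------------

jaccard_sets <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Bootstrap-Jaccard cluster stability
#'
#' Fits the reference k-medoids solution, then for each of `B`
#' nonparametric bootstrap resamples reclusters the resampled sites,
#' extends the resample clustering to every original site by
#' nearest-medoid classification, and records, for every original
#' cluster, the maximal Jaccard overlap with any resample cluster. The
#' mean over resamples scores how reproducible each cluster is: above
#' 0.85 "highly stable", 0.6--0.85 "stable", below 0.6 "unstable".
#'
#' @param profiles site-by-feature matrix (standardized)
#' @param k number of clusters
#' @param B bootstrap resamples (default 100; below 20 triggers a
#'   warning, the estimate is noisy)
#' @param seed integer seed
#' @param n_restarts restarts per fit
#' @return a list of class `cluster_stability`: `solution` (the
#'   reference fit), `jaccard` (mean per cluster), `labels`
#' @export
stability <- function(profiles, k, B = 100L, seed = 20250829L,
                      n_restarts = 10L) {
  if (B < 20L)
    warning("B = ", B, " bootstrap resamples gives an unstable ",
            "Jaccard estimate; use B >= 20")
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  ref <- kmedoids(profiles, k, seed = seed, n_restarts = n_restarts)
  orig_sets <- split(seq_len(n), ref$assignment)
  acc <- matrix(NA_real_, B, length(orig_sets))
  with_seed(seed + 1L, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- kmedoids(profiles[idx, , drop = FALSE], k,
                      seed = sample.int(2^31 - 1L, 1L),
                      n_restarts = n_restarts)
      # classify every original site to its nearest resample medoid
      med_rows <- idx[fit$medoids]
      d_to_med <- as.matrix(stats::dist(profiles))[, med_rows,
                                                   drop = FALSE]
      ext <- apply(d_to_med, 1L, which.min)
      boot_sets <- split(seq_len(n), ext)
      for (ci in seq_along(orig_sets)) {
        acc[b, ci] <- max(vapply(boot_sets, jaccard_sets,
                                 numeric(1), a = orig_sets[[ci]]))
      }
    }
  })
  jac <- colMeans(acc)
  names(jac) <- names(orig_sets)
  labels <- ifelse(jac > 0.85, "highly stable",
                   ifelse(jac >= 0.6, "stable", "unstable"))
  structure(list(solution = ref, jaccard = jac, labels = labels, B = B),
            class = "cluster_stability")
}

#' @export
print.cluster_stability <- function(x, ...) {
  cat(sprintf("<cluster_stability> k = %d, B = %d\n", x$solution$k, x$B))
  print(data.frame(cluster = names(x$jaccard),
                   mean_jaccard = round(x$jaccard, 3),
                   label = x$labels, row.names = NULL))
  invisible(x)
}
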