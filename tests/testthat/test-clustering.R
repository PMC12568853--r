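test_that("k-medoids solves small instances exactly and degenerately", {
  # 5 points on a line: optimum is {0,1,2} around medoid 1 and {10,11}
  x <- matrix(c(0, 1, 2, 10, 11), 5, 1,
              dimnames = list(paste0("s", 1:5), "f"))
  sol <- kmedoids(x, 2, seed = 1)
  expect_equal(sol$total_cost, 3)  # |0-1|+|2-1|+|10/11 -> 1|
  expect_equal(unname(sol$assignment), c(1, 1, 1, 2, 2))
  expect_true("s2" %in% sol$medoid_sites)
  expect_equal(sol$total_cost, exhaustive_kmedoids_cost(x, 2))
  # k = n: every site its own medoid, zero cost
  sol_n <- kmedoids(x, 5, seed = 1)
  expect_equal(sol_n$total_cost, 0)
  expect_equal(sort(sol_n$medoids), 1:5)
  expect_error(kmedoids(x, 1, seed = 1), "k must satisfy")
  expect_error(kmedoids(x, 6, seed = 1), "k must satisfy")
})

test_that("k-medoids is deterministic given the seed and nearest-medoid-consistent", {
  cl <- make_clouds(rbind(c(0, 0), c(6, 6), c(-6, 6)), n_per = 7,
                    sd = 0.5, seed = 3)
  a <- kmedoids(cl$x, 3, seed = 77)
  b <- kmedoids(cl$x, 3, seed = 77)
  expect_identical(a, b)
  D <- as.matrix(dist(cl$x))
  nearest <- apply(D[, a$medoids], 1, which.min)
  expect_equal(unname(a$assignment), unname(nearest))
  # medoids belong to the clusters they represent
  expect_equal(unname(a$assignment[a$medoids]), seq_len(3))
})

test_that("well-separated clouds are recovered exactly", {
  cl <- make_clouds(rbind(c(0, 0, 0), c(20, 0, 0)), n_per = 10,
                    sd = 0.5, seed = 9)
  sol <- kmedoids(cl$x, 2, seed = 5)
  expect_equal(mclust::adjustedRandIndex(sol$assignment, cl$labels), 1)
})

test_that("restarted swaps reach the exhaustive optimum on random micro-instances", {
  set.seed(31)
  hits <- 0L
  n_inst <- 40L
  for (i in seq_len(n_inst)) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(paste0("s", 1:n), NULL))
    sol <- kmedoids(x, k, seed = i)
    opt <- exhaustive_kmedoids_cost(x, k)
    expect_gte(sol$total_cost, opt - 1e-9)
    if (sol$total_cost <= opt + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_inst))
})

test_that("the PAM objective matches the independent cluster::pam route", {
  set.seed(17)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(60), 15, 4,
                dimnames = list(paste0("s", 1:15), NULL))
    ours <- kmedoids(x, 3, seed = i)
    ref <- cluster::pam(x, 3)
    ref_cost <- sum(apply(as.matrix(dist(x))[, ref$id.med, drop = FALSE],
                          1, min))
    expect_lte(ours$total_cost, ref_cost + 1e-9)
  }
})

test_that("validity indices match hand computations and limits", {
  x <- matrix(c(0, 1, 10, 11), 4, 1,
              dimnames = list(paste0("s", 1:4), "f"))
  sol <- kmedoids(x, 2, seed = 1)
  v <- validity(sol, x, L = 1)
  expect_equal(v$dunn, 9)          # min inter 9 / max diameter 1
  expect_gt(v$silhouette, 0.85)    # tight, well-separated pairs
  expect_equal(v$connectivity, 0)  # every 1st neighbor shares its cluster
  # with L = 2 each point's 2nd neighbor crosses over: 4 * 1/2
  expect_equal(validity(sol, x, L = 2)$connectivity, 2)
  # silhouette tends to 1 as the separation grows
  sep_sil <- vapply(c(5, 50, 500), function(gap) {
    y <- matrix(c(0, 1, gap, gap + 1), 4, 1,
                dimnames = list(paste0("s", 1:4), "f"))
    validity(kmedoids(y, 2, seed = 1), y, L = 2)$silhouette
  }, numeric(1))
  expect_true(all(diff(sep_sil) > 0))
  expect_gt(sep_sil[3], 0.99)
})

test_that("majority vote selects k on constructed separable instances", {
  cl2 <- make_clouds(rbind(c(0, 0), c(12, 0)), n_per = 9, sd = 0.6,
                     seed = 2)
  sel2 <- select_k(cl2$x, 2:6, seed = 10, gap_B = 15)
  expect_equal(sel2$chosen_k, 2L)
  expect_gte(sel2$votes[["2"]], 3L)
  cl3 <- make_clouds(rbind(c(0, 0), c(12, 0), c(6, 10.4)), n_per = 7,
                     sd = 0.6, seed = 6)
  sel3 <- select_k(cl3$x, 2:6, seed = 10, gap_B = 15)
  expect_equal(sel3$chosen_k, 3L)
})

test_that("vote ties break toward the smaller k", {
  votes <- table(factor(c(2, 2, 3, 3, 4), levels = 2:6))
  expect_equal((2:6)[which.max(votes)], 2L)  # documents the rule used
  # and through the interface: equal clouds where indices may disagree
  cl <- make_clouds(rbind(c(0, 0), c(8, 0)), n_per = 8, sd = 0.8, seed = 4)
  sel <- select_k(cl$x, 2:4, seed = 3, gap_B = 10)
  top <- max(sel$votes)
  expect_equal(sel$chosen_k,
               min(as.integer(names(sel$votes)[sel$votes == top])))
})

test_that("bootstrap Jaccard stability separates real from spurious structure", {
  cl <- make_clouds(rbind(c(0, 0), c(15, 0)), n_per = 10, sd = 0.5,
                    seed = 13)
  st <- stability(cl$x, 2, B = 40, seed = 50)
  expect_true(all(st$jaccard >= 0.95))
  expect_true(all(st$labels == "highly stable"))
  set.seed(60)
  noise <- matrix(stats::rnorm(40), 20, 2,
                  dimnames = list(paste0("s", 1:20), NULL))
  st_noise <- stability(noise, 3, B = 40, seed = 50)
  expect_lt(mean(st_noise$jaccard), mean(st$jaccard))
  # single-resample runs warn about the unstable estimate but reproduce
  expect_warning(s1 <- stability(cl$x, 2, B = 1, seed = 8), "B = 1")
  expect_warning(s2 <- stability(cl$x, 2, B = 1, seed = 8), "B = 1")
  expect_identical(s1$jaccard, s2$jaccard)
})
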