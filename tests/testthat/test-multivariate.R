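test_that("correlation PCA reproduces closed-form degenerate spectra", {
  set.seed(2)
  base <- stats::rnorm(30)
  x <- cbind(A = 3 + 2 * base, B = 100 - 5 * base)  # perfectly correlated
  rownames(x) <- paste0("s", 1:30)
  res <- pca(x)
  expect_equal(unname(res$eigenvalues), c(2, 0), tolerance = 1e-10)
  expect_equal(sum(res$explained_pct), 100, tolerance = 1e-10)
  # two perfectly correlated variables contribute 50% each to PC1
  expect_equal(unname(res$contributions_pct[, 1]), c(50, 50),
               tolerance = 1e-8)
  # near-independent metals at large n push all eigenvalues toward 1
  set.seed(5)
  y <- matrix(stats::rnorm(5000 * 4), 5000, 4,
              dimnames = list(NULL, paste0("M", 1:4)))
  expect_equal(unname(pca(y)$eigenvalues), rep(1, 4), tolerance = 0.1)
})

test_that("PCA invariants hold: cos2 budget, reconstruction, affine invariance", {
  set.seed(14)
  x <- matrix(exp(stats::rnorm(120, 3, 1)), 20, 6,
              dimnames = list(paste0("s", 1:20), paste0("M", 1:6)))
  res <- pca(x)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_equal(unname(rowSums(res$cos2)), rep(1, 6), tolerance = 1e-8)
  expect_equal(unname(colSums(res$contributions_pct)), rep(100, 6),
               tolerance = 1e-8)
  # full-component reconstruction of the standardized data
  z <- standardize_profiles(x)
  vec <- sweep(res$loadings, 2, sqrt(res$eigenvalues), "/")
  expect_equal(res$site_scores %*% t(vec), z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # per-metal affine rescaling leaves a correlation PCA untouched
  x2 <- sweep(sweep(x, 2, c(2, 0.1, 7, 1, 3, 10), "*"),
              2, c(0, 5, -2, 1, 0, 100), "+")
  res2 <- pca(x2)
  expect_equal(res2$loadings, res$loadings, tolerance = 1e-8)
  expect_equal(res2$eigenvalues, res$eigenvalues, tolerance = 1e-10)
  # sign convention: dominant loading of each component is positive
  for (j in 1:6)
    expect_gte(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  expect_error(pca(cbind(A = c(1, 1, 1), B = c(1, 2, 3))), "constant")
})

fake_pca <- function(ev) {
  pct <- 100 * ev / sum(ev)
  structure(list(eigenvalues = ev, explained_pct = pct,
                 cumulative_pct = cumsum(pct),
                 loadings = matrix(0, length(ev), length(ev))),
            class = "pca_result")
}

test_that("component selection applies Kaiser, variance, and the extension rule", {
  sel <- select_components(fake_pca(c(3.6, 2.6, 1.9, 0.9, 0.5, 0.3, 0.2)))
  expect_equal(sel$kaiser, 3L)
  expect_equal(sel$chosen, 3L)  # Kaiser count already explains >= 80%
  # eigenvalues {5, 1.2, 0.9, 0.9, 0.9, 0.6, 0.5}: Kaiser stops at 2 but
  # cumulative 62% < 80%, so the choice extends to the variance rule
  sel2 <- select_components(fake_pca(c(5, 1.2, 0.9, 0.9, 0.9, 0.6, 0.5)))
  expect_equal(sel2$kaiser, 2L)
  expect_gt(sel2$chosen, 2L)
  expect_gte(sel2$cumulative_pct, 80)
  # all eigenvalues exactly 1: Kaiser yields none, variance rule decides
  sel3 <- select_components(fake_pca(rep(1, 5)))
  expect_equal(sel3$kaiser, 0L)
  expect_equal(sel3$chosen, 4L)  # 4/5 = 80%
})

test_that("variable contributions aggregate by eigenvalue weighting", {
  set.seed(23)
  x <- matrix(exp(stats::rnorm(100, 2, 1)), 20, 5,
              dimnames = list(paste0("s", 1:20), paste0("M", 1:5)))
  res <- pca(x)
  ctr <- contributions(res, dims = 1:2)
  expect_equal(ctr$expected_average, 20)
  manual <- (res$contributions_pct[, 1] * res$eigenvalues[1] +
             res$contributions_pct[, 2] * res$eigenvalues[2]) /
    sum(res$eigenvalues[1:2])
  expect_equal(sort(ctr$contributions, decreasing = TRUE),
               sort(manual, decreasing = TRUE), tolerance = 1e-10)
  expect_equal(sum(ctr$contributions), 100, tolerance = 1e-8)
  one <- contributions(res, dims = 1)
  expect_equal(unname(sum(one$contributions)), 100, tolerance = 1e-8)
})

test_that("the rank test reproduces the hand-computed H for two blocks", {
  out <- compare_zones(list(idx = list(g1 = c(1, 2, 3),
                                       g2 = c(10, 11, 12))))
  expect_equal(out$H, 27 / 7, tolerance = 1e-3)  # 3.857
  expect_equal(out$p_value, 0.0495, tolerance = 0.002)
  same <- compare_zones(list(idx = list(g1 = c(1, 5, 9), g2 = c(1, 5, 9))))
  expect_equal(same$H, 0, tolerance = 1e-12)
  tied <- compare_zones(list(idx = list(g1 = c(2, 2), g2 = c(2, 2))))
  expect_equal(tied$p_value, 1)
  expect_error(compare_zones(list(idx = list(g1 = 1:3))), ">= 2 groups")
})

test_that("strongly separated zones give small p, and nulls give uniform p", {
  set.seed(77)
  a <- matrix(stats::runif(30, 0, 1), 10, 3,
              dimnames = list(NULL, c("Cd", "Ni", "Zn")))
  b <- a + 10  # disjoint ranges
  out <- compare_zones(list(Igeo = list(KF = a, D = b)))
  expect_lt(out$p_value, 0.05)
  # null calibration: Kruskal-Wallis p-values approximately uniform
  pvals <- vapply(1:500, function(i) {
    x <- stats::rnorm(50)
    g <- rep(c("a", "b"), each = 25)
    stats::kruskal.test(x, factor(g))$p.value
  }, numeric(1))
  # rank-based p-values are discrete, hence tied; the KS tie warning is
  # expected and immaterial to the calibration check
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("within-zone metal comparison flags unequal index levels", {
  set.seed(31)
  vals <- cbind(Cd = stats::runif(12, 30, 40),
                Ni = stats::runif(12, 1, 2),
                Zn = stats::runif(12, 3, 5))
  rownames(vals) <- paste0("KF", 1:12)
  tab <- dustindices:::index_table("PI", vals, "PI")
  out <- compare_metals(tab)
  expect_lt(out$p_value, 1e-4)
  flat <- dustindices:::index_table(
    "PI", matrix(2, 4, 2, dimnames = list(paste0("s", 1:4), c("A", "B"))),
    "PI")
  expect_equal(compare_metals(flat)$p_value, 1)
})
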