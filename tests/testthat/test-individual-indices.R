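test_that("geo-accumulation index matches its closed form and classes", {
  bg <- c(Cd = 0.4, Ni = 40, Mn = 300)
  ref <- reference_set(background = bg)
  m <- rbind(`1.5x` = 1.5 * bg, `3x` = 3 * bg, `48x` = 48 * bg)
  cm <- concentration_matrix(m)
  tab <- igeo(cm, ref)
  expect_equal(unname(tab$values["1.5x", ]), rep(0, 3))
  expect_equal(unname(tab$values["3x", ]), rep(1, 3))
  expect_equal(unname(tab$values["48x", ]), rep(5, 3))  # log2(32)
  expect_equal(unname(tab$classes["1.5x", "Cd"]),
               "unpolluted to moderately polluted")
  expect_equal(unname(tab$classes["48x", "Cd"]), "extremely polluted")
  # below the 1.5 buffer the class is "unpolluted"
  cm2 <- concentration_matrix(rbind(low = 1.4 * bg))
  expect_true(all(igeo(cm2, ref)$classes == "unpolluted"))
})

test_that("pollution index is the background ratio with closed-left classes", {
  bg <- c(Cd = 0.4, Ni = 40)
  ref <- reference_set(background = bg)
  cm <- concentration_matrix(rbind(a = bg, b = 0.5 * bg, c = 5 * bg))
  tab <- pollution_index(cm, ref)
  expect_equal(unname(tab$values["a", ]), c(1, 1))
  expect_equal(unname(tab$classes["a", "Cd"]), "low")
  expect_equal(unname(tab$classes["b", "Cd"]), "none")
  # the top class closes at 5 ("higher than or equal to 5")
  expect_equal(unname(tab$values["c", "Ni"]), 5)
  expect_equal(unname(tab$classes["c", "Ni"]), "very accentuated")
})

test_that("PI and Igeo satisfy PI = 1.5 * 2^Igeo to 1e-12 relative", {
  set.seed(42)
  bg <- stats::setNames(exp(stats::rnorm(10, 2, 1.5)), paste0("M", 1:10))
  ref <- reference_set(background = bg)
  vals <- matrix(exp(stats::rnorm(1000, 2, 2)), 100, 10,
                 dimnames = list(paste0("S", 1:100), names(bg)))
  cm <- concentration_matrix(vals)
  pi_v <- pollution_index(cm, ref)$values
  ig_v <- igeo(cm, ref)$values
  expect_equal(pi_v, 1.5 * 2^ig_v, tolerance = 1e-12)
})

test_that("missing background values are errors naming the metal", {
  ref <- reference_set(background = c(Cd = 0.4))
  cm <- toy_conc()
  expect_error(igeo(cm, ref), "background.*Ni")
  expect_error(pollution_index(cm, reference_set()), "config-mandatory")
})

test_that("enrichment factor is the double ratio with the stated classes", {
  bg <- c(Cd = 0.5, Ni = 50, Mn = 500)
  ref <- reference_set(background = bg)
  # sample holding exact background ratios -> EF = 1 everywhere
  cm <- concentration_matrix(rbind(s1 = 2 * bg, s2 = 10 * bg))
  ef <- enrichment_factor(cm, ref, normalizer = "Mn")
  expect_equal(unname(ef$values), matrix(1, 2, 3), tolerance = 1e-12)
  expect_identical(ef$normalizer, "Mn")
  # 2-site toy: Cd/Mn ratio doubled relative to background -> EF = 2
  m <- rbind(s1 = c(Cd = 1.0, Ni = 50, Mn = 500),
             s2 = c(Cd = 2.0, Ni = 100, Mn = 1000))
  ef2 <- enrichment_factor(concentration_matrix(m), ref, "Mn")
  expect_equal(unname(ef2$values[, "Cd"]), c(2, 2))
  expect_equal(unname(ef2$classes[, "Cd"]), rep("moderate", 2))
  # the normalizer's own EF is identically 1
  expect_equal(unname(ef2$values[, "Mn"]), c(1, 1))
  expect_error(enrichment_factor(cm, ref, "Fe"), "not present")
})

test_that("EF is invariant to rescaling a site's profile by a common factor", {
  set.seed(7)
  bg <- stats::setNames(exp(stats::rnorm(5, 3, 1)), paste0("M", 1:5))
  ref <- reference_set(background = bg)
  vals <- matrix(exp(stats::rnorm(20, 3, 1)), 4, 5,
                 dimnames = list(paste0("S", 1:4), names(bg)))
  scaled <- vals * c(0.1, 1, 7, 100)  # per-site dilution factors
  ef1 <- enrichment_factor(concentration_matrix(vals), ref, "M1")
  ef2 <- enrichment_factor(concentration_matrix(scaled), ref, "M1")
  expect_equal(ef1$values, ef2$values, tolerance = 1e-12)
})

test_that("each index is strictly increasing in the target concentration", {
  bg <- c(Cd = 0.4, Ni = 40, Mn = 300)
  ref <- reference_set(background = bg)
  conc_at <- function(cd) concentration_matrix(
    rbind(s = c(Cd = cd, Ni = 40, Mn = 300)))
  grid <- c(0.1, 0.5, 2, 10, 50)
  for (fn in list(function(cm) igeo(cm, ref)$values[1, "Cd"],
                  function(cm) pollution_index(cm, ref)$values[1, "Cd"],
                  function(cm) enrichment_factor(cm, ref,
                                                 "Mn")$values[1, "Cd"])) {
    v <- vapply(grid, function(cd) fn(conc_at(cd)), numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("classification is exhaustive and exclusive over random values", {
  set.seed(3)
  for (nm in c("Igeo", "PI", "EF", "CF", "PI_Nem")) {
    sch <- dustindices:::index_schemes[[nm]]
    vals <- c(stats::runif(200, -10, 60), sch$breakpoints)  # hit boundaries
    if (nm != "Igeo") vals <- vals[vals >= 0]
    cls <- classify(vals, nm)
    expect_false(anyNA(cls))
    expect_true(all(cls %in% sch$labels))
    # boundary values fall in the interval that closes on them (left)
    expect_identical(classify(sch$breakpoints, nm),
                     sch$labels[-1L])
  }
})

test_that("contamination factor divides zone means by pre-industrial values", {
  ref <- reference_set()
  # zone summary built from a published per-zone mean table
  kf_means <- c(Cd = 33.219, Cr = 104.14, Cu = 59.970, Ni = 1325.4,
                Pb = 103.9, Zn = 712.86, Mn = 233.667)
  cf <- cf_from_means(kf_means, ref)
  expect_equal(unname(cf$values[1, "Cd"]), 33.219)
  expect_equal(unname(cf$classes[1, "Cd"]), "very high")
  expect_equal(unname(cf$values[1, "Mn"]), 233.667 / 850, tolerance = 1e-12)
  expect_equal(unname(cf$classes[1, "Mn"]), "low")
  # boundary: zone mean exactly at the reference -> CF 1, "moderate"
  cf1 <- cf_from_means(c(Cd = 1), ref)
  expect_equal(unname(cf1$values[1, 1]), 1)
  expect_equal(unname(cf1$classes[1, 1]), "moderate")
})

test_that("CF requires five sites per zone and drops unreferenced metals", {
  set.seed(5)
  vals <- matrix(exp(stats::rnorm(60, 3, 1)), 10, 6,
                 dimnames = list(c(paste0("KF", 1:6), paste0("D", 1:4)),
                                 c("Cd", "Cr", "Ni", "Co", "Ba", "Fe")))
  cm <- concentration_matrix(vals)
  ref <- reference_set()
  expect_error(contamination_factor(cm, ref, "D"), "at least 5")
  expect_warning(cf <- contamination_factor(cm, ref, "KF"),
                 "Co.*Ba.*Fe|no pre-industrial")
  expect_identical(colnames(cf$values), c("Cd", "Cr", "Ni"))
  expect_equal(unname(cf$values[1, "Cd"]),
               mean(vals[1:6, "Cd"]) / 1, tolerance = 1e-12)
  expect_error(cf_from_means(c(Co = 3), ref), "no pre-industrial")
})
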