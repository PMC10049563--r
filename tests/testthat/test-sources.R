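test_that("Pearson matrix has unit diagonal and detects proportionality", {
  s <- big_draw("A", n = 50, seed = 31)
  s$Cu <- 3.7 * s$Zn  # perfectly proportional pair
  cm <- pearson_matrix(s)
  expect_equal(diag(cm$r), stats::setNames(rep(1, 6), hm_elements()))
  expect_equal(cm$r["Zn", "Cu"], 1)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$n, 50)
  expect_error(pearson_matrix(s[1:2, ]), "at least 3")
})

test_that("zero-variance elements are flagged, correlations set to NA", {
  s <- big_draw("A", n = 20, seed = 32)
  s$Hg <- rep(0.03, 20)
  cm <- pearson_matrix(s)
  expect_equal(attr(cm, "flagged"), "Hg")
  expect_true(all(is.na(cm$r["Hg", hm_elements() != "Hg"])))
  expect_equal(cm$r["Hg", "Hg"], 1)
})

test_that("KMO is 0.5 for any two-variable matrix and bounded in [0,1]", {
  for (r in c(-0.9, -0.3, 0.2, 0.7)) {
    m <- matrix(c(1, r, r, 1), 2)
    expect_equal(kmo(m), 0.5, tolerance = 1e-12)
  }
  for (a in c("A", "B", "C")) {
    k <- kmo(area_correlations(a))
    expect_true(k >= 0 && k <= 1)
  }
  expect_warning(k0 <- kmo(diag(6)), "undefined")
  expect_true(is.na(k0))
  singular <- matrix(1, 3, 3)  # rank one
  expect_error(kmo(singular), "singular")
})

test_that("synthetic agricultural-area KMO lands in the reference band", {
  cm <- pearson_matrix(big_draw("C"))
  expect_gt(kmo(cm), 0.75)
  expect_lt(kmo(cm), 0.89)
})

test_that("Bartlett sphericity: identity null, df, significance", {
  b0 <- bartlett_sphericity(diag(6), n = 30)
  expect_equal(b0$chi2, 0)
  expect_equal(b0$p_value, 1)
  expect_equal(b0$df, 15)  # p(p-1)/2 for six variables
  expect_error(bartlett_sphericity(diag(6), n = 6), "n greater")

  s <- generate_area(area_generator_config("C", n = 62), seed = 8)
  b <- bartlett_sphericity(pearson_matrix(s))
  expect_gt(b$chi2, 0)
  expect_lt(b$p_value, 0.001)
})

test_that("PCA conserves total variance and communalities under rotation", {
  for (a in c("A", "B", "C")) {
    pc <- pca_varimax(area_correlations(a))
    expect_equal(sum(pc$eigenvalues), 6, tolerance = 1e-10)
    expect_equal(sum(pc$variance_pct), 100, tolerance = 1e-8)
    expect_equal(rowSums(pc$loadings^2), rowSums(pc$loadings_rotated^2),
                 tolerance = 1e-8)
    # rotation is orthogonal: the retained-subspace reconstruction is shared
    expect_equal(pc$loadings %*% t(pc$loadings),
                 pc$loadings_rotated %*% t(pc$loadings_rotated),
                 tolerance = 1e-8)
  }
})

test_that("Kaiser retention reproduces the reference 3/2/2 pattern", {
  expect_equal(pca_varimax(area_correlations("A"))$n_retained, 3)
  expect_equal(pca_varimax(area_correlations("B"))$n_retained, 2)
  expect_equal(pca_varimax(area_correlations("C"))$n_retained, 2)
})

test_that("PCA degenerate structures behave as closed forms dictate", {
  expect_error(pca_varimax(diag(6)), "Kaiser")
  pc1 <- pca_varimax(diag(6), retain = 2)  # fixed-k override path
  expect_equal(pc1$n_retained, 2)

  rank1 <- matrix(1, 6, 6)
  pc <- pca_varimax(rank1, retain = 1)
  expect_equal(pc$eigenvalues, c(6, rep(0, 5)), tolerance = 1e-10)
  expect_equal(unname(pc$loadings[, 1]), rep(1, 6), tolerance = 1e-8)
})

test_that("loading reconstruction matches the retained eigen-subspace", {
  R <- area_correlations("C")
  pc <- pca_varimax(R)
  e <- eigen(R, symmetric = TRUE)
  k <- pc$n_retained
  Rk <- e$vectors[, 1:k] %*% diag(e$values[1:k]) %*% t(e$vectors[, 1:k])
  expect_equal(norm(pc$loadings_rotated %*% t(pc$loadings_rotated) - Rk, "F"),
               0, tolerance = 1e-8)
})

test_that("synthetic agricultural-area PCA recovers the reference structure", {
  pc <- pca_varimax(pearson_matrix(big_draw("C")))
  expect_equal(pc$n_retained, 2)
  expect_lt(abs(pc$variance_pct[1] - 67.38), 5)
})

test_that("element clustering merges co-varying elements first", {
  s <- big_draw("B", n = 40, seed = 33)
  s$Cu <- 2 * s$Zn  # r = 1, distance 0
  cl <- cluster_elements(s, k = 3)
  expect_equal(cl$heights[1], 0, tolerance = 1e-12)
  expect_equal(cl$clusters[["Zn"]], cl$clusters[["Cu"]])
  expect_true(all(diff(cl$heights) >= -1e-12))  # average linkage is monotone

  cl6 <- cluster_elements(s, k = 6)
  expect_equal(sort(unique(cl6$clusters)), 1:6)  # singletons
})

test_that("commercial-area clustering separates Pb/As from Cu/Hg", {
  cl <- cluster_elements(big_draw("A"), k = 2)
  expect_equal(cl$clusters[["Pb"]], cl$clusters[["As"]])
  expect_equal(cl$clusters[["Cu"]], cl$clusters[["Hg"]])
  expect_false(cl$clusters[["Pb"]] == cl$clusters[["Cu"]])
})
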