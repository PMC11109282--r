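test_that("window means: counts, constants, and coverage errors", {
  sites <- gen_sites(2, archetype_map = "semiarid_plains", seed = 6)
  wx <- gen_daily_weather(sites, weather_config(n_years = 1, seed = 6))
  panel <- compute_panel(wx[wx$SITE == sites$code[1], ],
                         lat = sites$lat[1])
  wm <- window_means(panel)
  expect_equal(nrow(wm), 1 * 19 * 4)  # 1 year x 19 covariables x 4 windows
  expect_equal(sort(unique(wm$WINDOW)), c("W1", "W2", "W3", "W4"))
  # constant series -> window mean equals the constant
  panel2 <- panel
  panel2$RH <- 55
  wm2 <- window_means(panel2)
  expect_equal(unique(wm2$VALUE[wm2$COVARIABLE == "RH"]), 55)
  # weather gap spanning a whole window -> named missing-data error
  md <- format(panel$DATE, "%m-%d")
  gap <- panel[!(md >= "07-16" & md <= "08-15"), ]
  expect_error(window_means(gap), "W2")
})

test_that("window spec validation rejects overlap and year wrap", {
  expect_error(window_spec(tibble::tibble(label = c("A", "B"),
                                          start = c("06-01", "06-15"),
                                          end = c("06-20", "07-01"))),
               "non-overlapping")
  expect_error(window_spec(tibble::tibble(label = "X", start = "12-01",
                                          end = "01-15")), "year")
})

test_that("W matrix has year x covariable x window columns, scaled", {
  sites <- gen_sites(19)
  stats2 <- site_window_stats(sites, n_years = 2, seed = 10)
  w <- build_w(stats2)
  expect_s3_class(w, "w_matrix")
  expect_equal(dim(w$W), c(19, 2 * 19 * 4))
  expect_equal(w$n_cols_full, 152)
  expect_lt(max(abs(colMeans(w$W))), 1e-8)
  expect_equal(unname(apply(w$W, 2, sd)), rep(1, ncol(w$W)),
               tolerance = 1e-8)
  # unscaled mode preserves raw window means
  w0 <- build_w(stats2, scale = FALSE)
  expect_equal(dim(w0$W), c(19, 152))
  one <- stats2[stats2$SITE == "ALM" & stats2$COVARIABLE == "RH" &
                  stats2$WINDOW == "W1" & stats2$YEAR == 2002, ]
  expect_equal(w0$W["ALM", paste(2002, "RH", "W1", sep = "|")],
               one$VALUE, ignore_attr = TRUE)
})

test_that("small W example and zero-variance column handling", {
  spec1 <- window_spec(tibble::tibble(label = "W1", start = "06-15",
                                      end = "07-15"))
  sites <- gen_sites(2, archetype_map = "arid_north", seed = 2)
  stats1 <- site_window_stats(sites, n_years = 1, seed = 2, spec = spec1)
  w <- build_w(stats1, scale = FALSE)
  expect_equal(dim(w$W), c(2, 19))  # 2 sites x (1 year x 19 cov x 1 window)
  # a constant covariable produces a zero-variance column that is dropped
  stats1$VALUE[stats1$COVARIABLE == "N"] <- 12
  expect_warning(ws <- build_w(stats1, scale = TRUE), "zero-variance")
  expect_equal(ncol(ws$W), 18)
  expect_true(all(ws$col_meta$dropped[ws$col_meta$COVARIABLE == "N"]))
})

test_that("enviromic kernel: trace, identity case, PSD, degenerate error", {
  withr::with_seed(42, {
    W <- matrix(rnorm(5 * 40), 5, 40,
                dimnames = list(paste0("E", 1:5), NULL))
    K <- enviromic_kernel(W)
    expect_equal(sum(diag(K$K)), 5, tolerance = 1e-12)
    expect_equal(K$K, t(K$K))
    expect_gt(min(eigen(K$K, symmetric = TRUE)$values), -1e-8)
    # orthonormal rows -> identity kernel
    Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:3]
    KI <- enviromic_kernel(t(Q))
    expect_equal(KI$K, diag(3), ignore_attr = TRUE, tolerance = 1e-12)
    expect_error(enviromic_kernel(matrix(0, 3, 4)), "degenerate")
  })
})

test_that("kernel PSD and trace hold across random W draws", {
  withr::with_seed(7, {
    for (i in 1:200) {
      W <- matrix(rnorm(8 * 15), 8, 15)
      K <- enviromic_kernel(W)$K
      expect_equal(sum(diag(K)), 8, tolerance = 1e-8)
      expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                -1e-8)
    }
  })
})

test_that("kernel distance is the feature-space Euclidean metric", {
  withr::with_seed(13, {
    W <- matrix(rnorm(6 * 20), 6, 20,
                dimnames = list(paste0("E", 1:6), NULL))
    W[2, ] <- W[1, ]  # duplicated environments
    K <- enviromic_kernel(W)
    D <- kernel_to_distance(K)
    expect_equal(D[1, 2], 0)
    expect_equal(diag(D), rep(0, 6), ignore_attr = TRUE)
    expect_equal(D, t(D))
    # oracle: Euclidean distance between rows of any factorization of K
    eg <- eigen(K$K, symmetric = TRUE)
    F <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
    D_oracle <- as.matrix(dist(F))
    expect_equal(D, D_oracle, ignore_attr = TRUE, tolerance = 1e-8)
    # identity kernel -> all off-diagonal sqrt(2)
    DI <- kernel_to_distance(diag(3))
    expect_equal(unique(DI[upper.tri(DI)]), sqrt(2))
    # triangle inequality
    for (i in 1:6) for (j in 1:6) for (l in 1:6) {
      expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-8)
    }
  })
})

test_that("UPGMA clustering: duplicates merge at zero, extremes of k, errors", {
  withr::with_seed(3, {
    W <- matrix(rnorm(5 * 12), 5, 12,
                dimnames = list(c("AA", "BB", "CC", "DD", "EE"), NULL))
    W[4, ] <- W[3, ]
    D <- kernel_to_distance(enviromic_kernel(W))
    p <- cluster_environments(D, k = 4)
    expect_equal(p$assignment[["CC"]], p$assignment[["DD"]])
    expect_equal(min(p$hclust$height), 0)
    expect_equal(p$k, 4)  # k = n - 1: exactly one pair merged
    expect_error(cluster_environments(D, k = 1), "k must be")
    expect_error(cluster_environments(D, k = 5), "k must be")
  })
})

test_that("clustering is permutation-equivariant in site order", {
  sites <- gen_sites(19)
  stats2 <- site_window_stats(sites, n_years = 1, seed = 21)
  p1 <- cluster_environments(
    kernel_to_distance(enviromic_kernel(build_w(stats2))), k = 4)
  shuf <- withr::with_seed(5, stats2[sample(nrow(stats2)), ])
  p2 <- cluster_environments(
    kernel_to_distance(enviromic_kernel(build_w(shuf))), k = 4)
  expect_equal(adjusted_rand(p1, p2), 1)
})

test_that("envirotype clustering recovers the planted archetypes", {
  sites <- gen_sites(19)
  truth <- archetype_truth(sites)
  stats2 <- site_window_stats(sites, n_years = 2, seed = 30)
  part <- cluster_environments(
    kernel_to_distance(enviromic_kernel(build_w(stats2))), k = 4)
  expect_equal(adjusted_rand(part, truth), 1)
})

test_that("covariable PCA: contributions, symmetry, planted yield signs", {
  withr::with_seed(17, {
    X <- matrix(rnorm(12 * 5), 12, 5,
                dimnames = list(sprintf("E%02d", 1:12),
                                c("RH", "VPD", "SW", "GDD", "WSM")))
    pca <- pca_covariables(X)
    expect_equal(colSums(pca$contributions), rep(100, ncol(pca$contributions)),
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_true(all(diff(pca$explained) <= 1e-12))
    expect_true(all(pca$explained >= 0 & pca$explained <= 1))
    # duplicated variable -> equal contributions for the pair
    X2 <- cbind(X, RH2 = X[, "RH"])
    pca2 <- suppressWarnings(pca_covariables(X2))
    expect_equal(pca2$contributions["RH", 1], pca2$contributions["RH2", 1],
                 tolerance = 1e-6)
    # planted associations: yield +0.9 with RH, -0.9 with VPD
    y <- 0.9 * scale(X[, "RH"])[, 1] - 0.9 * scale(X[, "VPD"])[, 1] +
      0.1 * rnorm(12)
    names(y) <- rownames(X)
    pca3 <- pca_covariables(X, yield = y)
    assoc <- stats::setNames(pca3$yield_assoc$sign,
                             pca3$yield_assoc$COVARIABLE)
    expect_equal(assoc[["RH"]], "positive")
    expect_equal(assoc[["VPD"]], "negative")
    expect_error(pca_covariables(X[1:2, ]), "at least 3")
  })
})
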