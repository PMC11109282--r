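test_that("ge_means averages replicates and ignores row order", {
  tr2 <- random_trial(4, 3, 3, seed = 1)
  M <- ge_means(tr2)
  expect_equal(dim(M), c(4, 3))
  expect_equal(M["G01", "E01"],
               mean(tr2$GY_KG_HA[tr2$GEN == "G01" & tr2$ENV == "E01"]))
  M2 <- ge_means(withr::with_seed(8, tr2[sample(nrow(tr2)), ]))
  expect_identical(M, M2)
  tr3 <- gen_trial_yields(trial_config(41, 19, 3, seed = 2))
  expect_equal(dim(ge_means(tr3)), c(41, 19))
})

test_that("GGE centering and SVD reconstruction identities", {
  withr::with_seed(11, {
    M <- matrix(rnorm(8 * 6, 1500, 300), 8, 6,
                dimnames = list(sprintf("G%02d", 1:8),
                                sprintf("E%02d", 1:6)))
    for (svp in c("symmetric", "environment", "genotype")) {
      fit <- fit_gge(M, svp = svp)
      expect_lt(max(abs(colMeans(fit$centered))), 1e-8)
      recon <- fit$u %*% diag(fit$d) %*% t(fit$v)
      expect_equal(recon, fit$centered, ignore_attr = TRUE,
                   tolerance = 1e-8)
      # scores product reconstructs the centered matrix for every svp
      prod <- fit$genotype_scores %*% t(fit$env_scores)
      expect_equal(prod, fit$centered, ignore_attr = TRUE,
                   tolerance = 1e-8)
    }
    # rank-2 reconstruction error = sum of squared trailing singular values
    fit <- fit_gge(M)
    r2 <- fit$u[, 1:2] %*% diag(fit$d[1:2]) %*% t(fit$v[, 1:2])
    err <- sum((fit$centered - r2)^2)
    expect_equal(err, sum(fit$d[-(1:2)]^2), tolerance = 1e-6)
    expect_true(all(diff(fit$explained) <= 1e-12))
  })
})

test_that("rank-1 structure loads entirely on PC1; constant matrix errors", {
  g <- rnorm(6); e <- rnorm(5)
  M <- 1500 + outer(g, e)
  dimnames(M) <- list(sprintf("G%02d", 1:6), sprintf("E%02d", 1:5))
  fit <- fit_gge(M)
  expect_equal(fit$explained[1], 1, tolerance = 1e-9)
  expect_error(fit_gge(matrix(7, 4, 4)), "zero-variance")
})

test_that("svp modes agree on the scores product", {
  M <- ge_means(random_trial(6, 5, 2, seed = 3))
  prods <- lapply(c("symmetric", "environment", "genotype"), function(s) {
    fit <- fit_gge(M, svp = s)
    fit$genotype_scores %*% t(fit$env_scores)
  })
  expect_equal(prods[[1]], prods[[2]], tolerance = 1e-8)
  expect_equal(prods[[1]], prods[[3]], tolerance = 1e-8)
})

test_that("which-won-where winners match the rank-2 argmax oracle", {
  for (i in 1:50) {
    M <- withr::with_seed(3000 + i, {
      g <- sample(4:8, 1); e <- sample(3:6, 1)
      matrix(rnorm(g * e, 1500, 250), g, e,
             dimnames = list(sprintf("G%02d", 1:g), sprintf("E%02d", 1:e)))
    })
    fit <- fit_gge(M)
    www <- tryCatch(which_won_where(fit), error = function(err) NULL)
    if (is.null(www)) next  # degenerate hull draw
    # oracle: argmax over ALL genotypes of the rank-2 modeled value
    r2 <- fit$u[, 1:2] %*% diag(fit$d[1:2]) %*% t(fit$v[, 1:2])
    oracle_winner <- rownames(M)[apply(r2, 2, which.max)]
    expect_equal(unname(www$winner_of_env), oracle_winner)
  }
})

test_that("three non-collinear genotypes all sit on the hull", {
  M <- withr::with_seed(5, matrix(rnorm(9, 0, 100), 3, 3,
                                  dimnames = list(paste0("G", 1:3),
                                                  paste0("E", 1:3))))
  www <- which_won_where(fit_gge(M))
  expect_setequal(www$hull_vertices, paste0("G", 1:3))
})

test_that("sector membership is equivariant under rotation of scores", {
  M <- ge_means(random_trial(7, 6, 2, seed = 14))
  fit <- fit_gge(M)
  www1 <- which_won_where(fit)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fit2 <- fit
  fit2$genotype_scores[, 1:2] <- fit$genotype_scores[, 1:2] %*% R
  fit2$env_scores[, 1:2] <- fit$env_scores[, 1:2] %*% R
  www2 <- which_won_where(fit2)
  expect_identical(www1$winner_of_env, www2$winner_of_env)
  expect_identical(www1$sector_of_env, www2$sector_of_env)
})

test_that("collinear genotype scores raise a degenerate-hull error", {
  g <- c(-1, 0, 1, 2)
  M <- 1500 + outer(g, rnorm(4))
  dimnames(M) <- list(paste0("G", 1:4), paste0("E", 1:4))
  expect_error(which_won_where(fit_gge(M)), "collinear")
})

test_that("planted 4-ME rank-2 truth is fully recovered", {
  sites <- gen_sites(19)
  truth <- archetype_truth(sites)
  tr <- gen_trial_yields(trial_config(
    20, 19, 3, me_assignment = truth, winner_bonus = 1500,
    env_codes = sites$code, seed = 404))
  fit <- fit_gge(ge_means(tr))
  www <- which_won_where(fit)
  expect_equal(adjusted_rand(www_partition(www), truth), 1)
  expect_setequal(www$winner_of_sector, c("G01", "G02", "G03", "G04"))
  expect_equal(adjusted_rand(env_similarity_groups(fit, k = 4), truth), 1)
})

test_that("discriminativeness tracks column SD and representativeness the AEA", {
  withr::with_seed(23, {
    # rank-2 synthetic data: vector length should rank like column SDs
    U <- matrix(rnorm(10 * 2), 10, 2)
    V <- matrix(rnorm(8 * 2), 8, 2) %*% diag(c(3, 1))
    M <- 1500 + U %*% t(V)
    dimnames(M) <- list(sprintf("G%02d", 1:10), sprintf("E%02d", 1:8))
    fit <- fit_gge(M)
    dr <- discrim_vs_repres(fit)
    col_sd <- apply(fit$centered, 2, sd)[dr$env]
    expect_equal(order(dr$vector_length), order(col_sd))
    expect_true(all(dr$cos_aea >= -1 & dr$cos_aea <= 1))
    expect_true(all(dr$vector_length >= 0))
    expect_setequal(unique(dr$class),
                    intersect(c("both", "discriminative", "representative",
                                "neither"), unique(dr$class)))
    expect_gt(max(dr$cos_aea), 0.5)  # AEA well defined on this draw
  })
})

test_that("environments aligned with the average-environment axis have cos 1", {
  # all environments on one direction: every env IS the average direction
  lens <- c(1, 2, 3, 4)
  V <- cbind(lens * cos(0.4), lens * sin(0.4))
  U <- withr::with_seed(31, matrix(rnorm(10), 5, 2))
  M <- 1500 + 300 * U %*% t(V)
  dimnames(M) <- list(sprintf("G%02d", 1:5), sprintf("E%02d", 1:4))
  dr <- discrim_vs_repres(fit_gge(M))
  expect_equal(dr$cos_aea, rep(1, 4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("D&R classification is invariant to positive yield rescaling", {
  M <- ge_means(random_trial(8, 6, 3, seed = 77))
  dr1 <- discrim_vs_repres(fit_gge(M))
  dr2 <- discrim_vs_repres(fit_gge(M * 3.7))
  expect_equal(dr1$class, dr2$class)
  expect_equal(dr1$cos_aea, dr2$cos_aea, tolerance = 1e-8)
  expect_equal(dr2$vector_length, 3.7 * dr1$vector_length,
               tolerance = 1e-8)
})

test_that("angular similarity groups: identical vectors together, antipodes apart", {
  # construct env scores directly through a rank-2 matrix
  ang <- c(0, 0.05, pi, pi + 0.05, pi / 2, -pi / 2)
  V <- cbind(cos(ang), sin(ang))
  U <- withr::with_seed(9, matrix(rnorm(12), 6, 2))
  M <- 1500 + 300 * U %*% t(V)
  dimnames(M) <- list(sprintf("G%02d", 1:6), sprintf("E%02d", 1:6))
  fit <- fit_gge(M)
  p2 <- env_similarity_groups(fit, k = 2)
  # the two near-antipodal families on the x-axis must separate
  expect_false(p2$assignment[["E01"]] == p2$assignment[["E03"]])
  expect_equal(p2$assignment[["E01"]], p2$assignment[["E02"]])
  expect_equal(p2$assignment[["E03"]], p2$assignment[["E04"]])
  expect_error(env_similarity_groups(fit, k = 20), "k must be")
})
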