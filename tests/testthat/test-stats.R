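# Group-level inference and behavioral scoring.

test_that("recall scoring weights semantically correct answers by half", {
  expect_equal(score_recall(20, 4, 50), 44)
  expect_equal(score_recall(0, 0, 80), 0)
  expect_equal(score_recall(80, 0, 80), 100)
  expect_equal(score_recall(c(20, 0), c(4, 0), c(50, 80)), c(44, 0))
  expect_error(score_recall(10, 0, 0), "positive")
  expect_error(score_recall(50, 40, 80), "exceed")
})

test_that("spearman family: rank invariance, partialling, degenerate guards", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(spearman(x, exp(x)), 1)                 # monotone transform
  expect_equal(spearman(x, -x^3), -1)
  expect_true(is.na(spearman(rep(1, 10), x[1:10])))
  # independent covariate barely changes the correlation
  d <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(200); y <- x + rnorm(200); z <- rnorm(200)
    abs(partial_spearman(x, y, z) - spearman(x, y))
  }, 0)
  expect_lt(max(d), 0.08)
  # confound identical to the predictor: nothing left to correlate
  set.seed(2)
  x <- rnorm(40); y <- x + rnorm(40, 0, 0.1)
  expect_lt(abs(partial_spearman(x, y, x)), 0.1)
})

test_that("circular correlation coefficients behave at their extremes", {
  set.seed(4)
  ph <- runif(100, -pi, pi)
  expect_equal(circ_linear_corr(ph, sin(ph)), 1, tolerance = 1e-6)
  expect_equal(circ_circ_corr(ph, ph), 1, tolerance = 1e-9)
  # null calibration: independent angles stay near zero
  r_null <- vapply(1:20, function(s) {
    set.seed(s)
    abs(circ_circ_corr(runif(500, -pi, pi), runif(500, -pi, pi)))
  }, 0)
  expect_gte(sum(r_null <= 0.12), 19)
  expect_true(is.na(circ_circ_corr(rep(0.3, 10), ph[1:10])))
})

test_that("dependent-correlation bootstrap keeps pairing and its seed", {
  set.seed(7)
  n <- 33
  y <- rnorm(n)
  x1 <- y + rnorm(n, 0, 0.6)       # strong predictor
  x2 <- rnorm(n)                   # noise
  b <- bootstrap_compare_dependent_corrs(x1, y, x2, n_boot = 500, seed = 3)
  expect_gt(b$ci95[1], 0)          # CI95 excludes zero for this draw
  expect_lt(b$p, 0.05)
  b2 <- bootstrap_compare_dependent_corrs(x1, y, x2, n_boot = 500, seed = 3)
  expect_identical(b$draws, b2$draws)
  # identical predictors: the difference is degenerate at zero
  b3 <- bootstrap_compare_dependent_corrs(x1, y, x1, n_boot = 200, seed = 1)
  expect_equal(unname(b3$ci95), c(0, 0))
  # permuting subject rows identically leaves the statistic unchanged
  set.seed(9); o <- sample(n)
  b4 <- bootstrap_compare_dependent_corrs(x1[o], y[o], x2[o], n_boot = 500, seed = 3)
  expect_equal(b4$delta_rho, b$delta_rho)
})

test_that("effect sizes: paired d and cluster averaging", {
  set.seed(12)
  d_big <- cohens_d_paired(rnorm(1e4, 0.5, 1), 0)
  expect_lt(abs(d_big - 0.5), 0.05)
  a <- rnorm(10)
  expect_true(is.na(cohens_d_paired(a, a - 3)))        # zero-variance diff
  da <- matrix(rnorm(30 * 3), 30)
  db <- matrix(rnorm(30 * 3), 30)
  dd <- vapply(1:3, function(j) cohens_d_paired(da[, j], db[, j]), 0)
  expect_equal(cluster_effect_size(da, db, 1:3), mean(dd))
})

test_that("paired cluster permutation finds a banded shift, is seeded", {
  set.seed(21)
  a <- matrix(rnorm(20 * 30), 20)
  b <- a + matrix(rnorm(20 * 30, 0, 1), 20)
  b[, 10:15] <- b[, 10:15] + 1
  cr <- cluster_permutation_paired(b, a, n_perm = 500, seed = 5)
  sig <- which(cr$clusters$significant & cr$clusters$sign > 0)
  expect_gte(length(sig), 1)
  hit <- any(vapply(sig, function(i) any(cr$members[[i]] %in% 10:15), TRUE))
  expect_true(hit)
  expect_true(all(cr$clusters$p >= 0 & cr$clusters$p <= 1))
  cr2 <- cluster_permutation_paired(b, a, n_perm = 500, seed = 5)
  expect_identical(cr$clusters, cr2$clusters)
  expect_error(cluster_permutation_paired(a, a[, 1:3]), "mismatch")
})

test_that("channel-graph clustering respects the montage adjacency", {
  chans <- c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4", "O1", "O2")
  adj <- channel_adjacency(chans)
  expect_length(adj, 11)
  expect_true(which(chans == "Fz") %in% adj[[which(chans == "F3")]])
  expect_false(which(chans == "O1") %in% adj[[which(chans == "F3")]])
  # an effect on F3+Fz+F4 clusters as one frontal component
  set.seed(3)
  a <- matrix(rnorm(25 * 11), 25)
  b <- a + matrix(rnorm(25 * 11, 0, 0.5), 25)
  b[, 1:3] <- b[, 1:3] + 1
  cr <- cluster_permutation_paired(b, a, adjacency = adj, n_perm = 500, seed = 2)
  big <- which.max(cr$clusters$size)
  expect_true(all(1:3 %in% cr$members[[big]]))
  expect_true(cr$clusters$significant[big])
})

test_that("correlation cluster test recovers a channel-level association", {
  set.seed(14)
  n <- 20
  latent <- rnorm(n)
  x <- sapply(1:2, function(j) latent + rnorm(n, 0, 0.4))
  colnames(x) <- c("F3", "Fz")
  y <- latent + rnorm(n, 0, 0.3)
  cr <- cluster_permutation_corr(x, y, channel_adjacency(colnames(x)),
                                 n_perm = 500, seed = 8)
  expect_gte(nrow(cr$clusters), 1)
  expect_true(any(cr$clusters$significant & cr$clusters$sign > 0))
  expect_gt(min(cr$rho), 0.5)
})
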