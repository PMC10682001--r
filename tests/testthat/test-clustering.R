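# temporal z-scoring, clustering, PCA, early/late calls and sigmoid
# inflection fitting

make_profiles <- function(n_down = 30, n_up = 30, noise = 0.2,
                          seed = 1) {
  set.seed(seed)
  tt <- unname(sgdynamics:::minutes_of(sgdynamics:::TIME_LABELS))
  tt[8:9] <- c(185, 190)  # recovery appended after the HS course
  down <- 1 - stats::plogis(0.15 * (tt - 21))
  up <- stats::plogis(0.15 * (tt - 30))
  z <- rbind(
    t(replicate(n_down, down + rnorm(9, 0, noise))),
    t(replicate(n_up, up + rnorm(9, 0, noise))))
  z <- t(scale(t(z)))  # row z-scores
  rownames(z) <- sprintf("P%03d", seq_len(nrow(z)))
  colnames(z) <- sgdynamics:::TIME_LABELS
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

test_that("z-scoring uses the sample standard deviation", {
  lm <- matrix(0, 2, 9,
               dimnames = list(c("a", "const"),
                               sgdynamics:::TIME_LABELS))
  lm["a", ] <- c(1, 2, 3, 2, 1, 2, 3, 2, 2)
  lm["const", ] <- 5
  m <- make_quant_from_means(lm)
  z <- zscore_profiles(m)
  expect_equal(unname(z["a", ]),
               unname((lm["a", ] - mean(lm["a", ])) / sd(lm["a", ])))
  # row (1,2,3): sample sd 1 -> z exactly (-1, 0, 1)
  expect_equal(unname((c(1, 2, 3) - 2) / sd(c(1, 2, 3))),
               c(-1, 0, 1))
  # constant row: zeros plus degeneracy flag
  expect_true(all(z["const", ] == 0))
  expect_true(attr(z, "degenerate")[["const"]])
  # non-degenerate rows: mean ~ 0, sd ~ 1
  expect_lt(abs(mean(z["a", ])), 1e-9)
  expect_lt(abs(sd(z["a", ]) - 1), 1e-9)
})

test_that("agglomerative clustering uses Chebyshev distance and average linkage", {
  # Chebyshev: d((0,0),(3,4)) = 4
  expect_equal(as.numeric(dist(rbind(c(0, 0), c(3, 4)),
                               method = "maximum")), 4)
  # average linkage on 1-d profiles 0, 2, 5: merge heights 2 then
  # mean(3, 5) = 4
  z <- matrix(c(0, 2, 5), 3, 9)
  rownames(z) <- c("a", "b", "c"); colnames(z) <-
    sgdynamics:::TIME_LABELS
  hc <- hierarchical_cluster(z, k = 2)
  expect_equal(hc$tree$height, c(2, 4))
  expect_equal(unname(hc$labels), c(1, 1, 2))
  expect_error(hierarchical_cluster(z, k = 5), "exceeds")
})

test_that("a 2-cut recovers a planted two-template split exactly", {
  z <- make_profiles(30, 30, noise = 0.2, seed = 7)
  hc <- hierarchical_cluster(z, k = 2)
  truth <- rep(1:2, each = 30)
  names(truth) <- rownames(z)
  lab <- hc$labels[names(truth)]
  agree <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_equal(agree, 1)

  # invariance to input row order
  perm <- sample(nrow(z))
  hc2 <- hierarchical_cluster(z[perm, ], k = 2)
  expect_equal(hc2$labels[names(hc$labels)], hc$labels)
})

test_that("PC1 loadings separate antiphase templates into two modes", {
  z <- make_profiles(40, 40, noise = 0.15, seed = 3)
  p <- pca_loadings(z)
  l1 <- p$loadings[, 1]
  g1 <- l1[1:40]; g2 <- l1[41:80]
  expect_true(all(sign(median(g1)) != sign(median(g2))))
  expect_true(min(abs(median(g1)), abs(median(g2))) > 0.5)

  # permutation invariance up to global sign
  perm <- sample(nrow(z))
  p2 <- pca_loadings(z[perm, ])
  l2 <- p2$loadings[rownames(z), 1]
  expect_true(isTRUE(all.equal(l2, l1, tolerance = 1e-8)) ||
                isTRUE(all.equal(l2, -l1, tolerance = 1e-8)))

  # duplicated single profile: no variance across proteins
  zd <- matrix(rep(z[1, ], each = 5), 5, dimnames = list(
    paste0("d", 1:5), colnames(z)))
  pd <- pca_loadings(zd)
  expect_equal(unname(pd$explained_variance[1]), 0)
})

test_that("early/late identities follow the HS10 vs HS180 contrast", {
  z <- make_profiles(10, 10, noise = 0.05, seed = 5)
  labels <- setNames(rep(c(1L, 2L), each = 10), rownames(z))
  a <- assign_early_late(labels, z)
  expect_equal(unique(a$cluster[1:10]), "early")
  expect_equal(unique(a$cluster[11:20]), "late")

  # relabelling cluster ids leaves identities unchanged
  a2 <- assign_early_late(setNames(3L - labels, names(labels)), z)
  expect_equal(a2$cluster, a$cluster)

  # both clusters decreasing: steeper one is early, with a warning
  steep <- seq(1, -1, length.out = 9)
  shallow <- seq(0.3, -0.3, length.out = 9)
  zz <- rbind(matrix(steep, 5, 9, byrow = TRUE),
              matrix(shallow, 5, 9, byrow = TRUE))
  rownames(zz) <- sprintf("q%02d", 1:10)
  colnames(zz) <- sgdynamics:::TIME_LABELS
  labs <- setNames(rep(c(1L, 2L), each = 5), rownames(zz))
  expect_warning(a3 <- assign_early_late(labs, zz), "same way")
  expect_equal(unique(a3$cluster[1:5]), "early")

  # exact tie is an error
  zt <- matrix(0, 2, 9, dimnames = list(c("x", "y"),
                                        sgdynamics:::TIME_LABELS))
  expect_error(assign_early_late(setNames(c(1L, 2L), c("x", "y")), zt),
               "tie")
})

test_that("sigmoid fitting recovers generative parameters", {
  tt <- c(0, 10, 20, 30, 60, 120, 180)
  v <- -1 + (1 - (-1)) / (1 + exp(-(-0.2) * (tt - 25)))
  f <- fit_sigmoid(tt, v)
  expect_true(f$converged)
  expect_equal(f$t0, 25, tolerance = 1e-3)
  expect_equal(f$direction, "decreasing")
  expect_true(f$t0 >= min(tt) && f$t0 <= max(tt))

  # flat values: degenerate
  ff <- fit_sigmoid(tt, rep(2, 7))
  expect_false(ff$converged)

  expect_error(fit_sigmoid(c(0, 10, 20), c(1, 2, 3)), ">= 4 points")
  expect_error(fit_sigmoid(c(0, 10, 10, 20), c(1, 2, 3, 4)),
               "strictly increasing")
})

test_that("averaging noisy profiles recovers the planted inflection", {
  tt <- c(0, 10, 20, 30, 60, 120, 180)
  set.seed(11)
  prof <- t(replicate(200,
                      1 - stats::plogis(0.15 * (tt - 21)) +
                        rnorm(7, 0, 0.2)))
  f <- fit_sigmoid(tt, colMeans(prof))
  expect_true(f$converged)
  expect_lte(abs(f$t0 - 21), 3)
})
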