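test_that("min-max scaling maps endpoints, degenerates to zero, and inverts", {
  m <- rbind(c(1, 5, 3), c(3, 5, 7), c(2, 5, 4))
  sc <- minMaxScale(m)
  expect_equal(range(sc$scaled[, 1]), c(0, 1))
  expect_equal(sc$scaled[, 2], rep(0, 3))       # degenerate dimension
  inv <- minMaxInvert(sc$scaled, sc)
  expect_equal(inv[, c(1, 3)], m[, c(1, 3)])
  ## single-model ensemble scales to the zero vector
  one <- minMaxScale(matrix(c(2, 9), 1, 2))
  expect_equal(as.numeric(one$scaled), c(0, 0))
  ## round trip on random matrices
  set.seed(1)
  r <- matrix(rnorm(60), 15, 4)
  s <- minMaxScale(r)
  expect_equal(minMaxInvert(s$scaled, s), r, tolerance = 1e-12)
})

test_that("clustering finds planted Gaussian clusters and degenerate cases", {
  ## identical models collapse to one cluster
  dup <- matrix(0.4, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  space <- ParameterSpace(c("a", "b", "c"), rep(0, 3), rep(1, 3),
                          rep("linear", 3))
  ens <- new("Ensemble", space = space, params = dup, sse = rep(0, 6),
             provenance = list())
  cl <- clusterModels(ens)
  expect_identical(nclusters(cl), 1L)
  ## two spherical clusters separated by 10 sigma
  set.seed(101)
  sigma <- 0.3
  pts <- rbind(matrix(rnorm(200, 0, sigma), 100, 2),
               matrix(rnorm(200, 10 * sigma / sqrt(2) * 2, sigma), 100, 2))
  truthLab <- rep(1:2, each = 100)
  colnames(pts) <- c("a", "b")
  sp2 <- ParameterSpace(c("a", "b"), apply(pts, 2, min) - 1,
                        apply(pts, 2, max) + 1, rep("linear", 2))
  e2 <- new("Ensemble", space = sp2, params = pts,
            sse = rep(0, 200), provenance = list())
  c2 <- clusterModels(e2)
  expect_identical(nclusters(c2), 2L)
  expect_gte(mclust::adjustedRandIndex(clusterLabels(c2), truthLab), 0.99)
  ## three planted clusters of unequal size (200 / 100 / 50)
  set.seed(202)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  sizes <- c(200, 100, 50)
  pts3 <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(2 * sizes[g], 0, 0.3), sizes[g], 2), 2,
          centers[g, ], "+")))
  colnames(pts3) <- c("a", "b")
  lab3 <- rep(1:3, sizes)
  sp3 <- ParameterSpace(c("a", "b"), apply(pts3, 2, min) - 1,
                        apply(pts3, 2, max) + 1, rep("linear", 2))
  e3 <- new("Ensemble", space = sp3, params = pts3,
            sse = rep(0, 350), provenance = list())
  c3 <- clusterModels(e3)
  expect_identical(nclusters(c3), 3L)
  expect_gte(mclust::adjustedRandIndex(clusterLabels(c3), lab3), 0.99)
})

test_that("the mixture density matches its closed forms and the loop oracle", {
  ## single model: peak density of one Gaussian
  S <- matrix(c(0.02, 0.005, 0.005, 0.03), 2, 2)
  cl1 <- makeClusteredFixture(matrix(c(0.4, 0.6), 1, 2), 1L, list(S))
  expect_equal(mixtureDensity(cl1, c(0.4, 0.6)),
               1 / (2 * pi * sqrt(det(S))), tolerance = 1e-12)
  expect_error(mixtureDensity(cl1, c(0.4, 0.6, 0.1)), "dimension")
  ## two single-model clusters contribute half the mass each
  S2 <- diag(0.01, 2)
  cl2 <- makeClusteredFixture(rbind(c(0.2, 0.2), c(0.8, 0.8)), c(1L, 2L),
                              list(S, S2))
  atA <- mixtureDensity(cl2, c(0.2, 0.2))
  expect_equal(atA,
               0.5 * oracleDmvnorm(c(0.2, 0.2), c(0.2, 0.2), S) +
               0.5 * oracleDmvnorm(c(0.2, 0.2), c(0.8, 0.8), S2),
               tolerance = 1e-12)
  ## random mixture against the explicit-loop oracle
  set.seed(7)
  pts <- matrix(runif(24), 12, 2)
  labs <- rep(1:3, each = 4)
  covs <- replicate(3, {
    A <- matrix(rnorm(4, 0, 0.05), 2, 2)
    crossprod(A) + diag(0.01, 2)
  }, simplify = FALSE)
  clR <- makeClusteredFixture(pts, labs, covs)
  for (k in 1:5) {
    x <- runif(2)
    expect_equal(mixtureDensity(clR, x),
                 oracleMixtureDensity(x, pts, labs, covs),
                 tolerance = 1e-10)
  }
  expect_true(all(mixtureDensity(clR, matrix(runif(40), 20, 2)) >= 0))
})

test_that("discrete probabilities are density-weighted with equal cluster mass", {
  ## symmetric two-model cluster: equal probabilities
  S <- diag(0.02, 2)
  clSym <- makeClusteredFixture(rbind(c(0.3, 0.5), c(0.7, 0.5)), c(1L, 1L),
                                list(S))
  pSym <- discreteProbabilities(clSym)
  expect_equal(pSym, c(0.5, 0.5))
  ## single-model clusters are forced to 1/N regardless of covariances
  clOne <- makeClusteredFixture(rbind(c(0.1, 0.1), c(0.5, 0.9),
                                      c(0.9, 0.2)), 1:3,
                                list(diag(0.01, 2), diag(0.2, 2),
                                     diag(0.05, 2)))
  expect_equal(discreteProbabilities(clOne), rep(1 / 3, 3))
  ## grid oracle on a two-cluster toy: density at each model location,
  ## renormalized per cluster to mass 1/2
  set.seed(31)
  pts <- rbind(matrix(runif(10, 0, 0.4), 5, 2),
               matrix(runif(14, 0.6, 1), 7, 2))
  labs <- c(rep(1L, 5), rep(2L, 7))
  covs <- list(diag(0.02, 2), diag(0.03, 2))
  cl <- makeClusteredFixture(pts, labs, covs)
  p <- discreteProbabilities(cl)
  dens <- vapply(seq_len(nrow(pts)), function(i)
    oracleMixtureDensity(pts[i, ], pts, labs, covs), 0)
  expected <- numeric(length(dens))
  for (g in 1:2) {
    idx <- labs == g
    expected[idx] <- dens[idx] / sum(dens[idx]) / 2
  }
  expect_equal(p, expected, tolerance = 1e-10)
  ## contract: per-cluster mass 1/N, total 1
  expect_equal(sum(p[labs == 1]), 0.5, tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  ## permuting model order within clusters permutes probabilities
  perm <- c(5:1, 12:6)
  clP <- makeClusteredFixture(pts[perm, ], labs[perm], covs)
  expect_equal(discreteProbabilities(clP), p[perm], tolerance = 1e-12)
})

test_that("entropy follows its closed forms and upper bound", {
  expect_equal(entropyOf(1), 0)
  expect_equal(entropyOf(rep(0.1, 10)), 1.0)
  ## uniform-within-cluster entropy equals log10(N) + mean(log10 n_C)
  sizes <- c(433, 921, 425, 711, 680, 744, 552, 771)
  p <- unlist(lapply(sizes, function(n) rep(1 / (8 * n), n)))
  expect_equal(entropyOf(p),
               log10(8) + mean(log10(sizes)), tolerance = 1e-9)
  ## the uniform-within-cluster value bounds density-weighted entropies
  set.seed(17)
  pts <- matrix(runif(40), 20, 2)
  labs <- rep(1:4, each = 5)
  covs <- replicate(4, diag(runif(1, 0.01, 0.1), 2), simplify = FALSE)
  cl <- makeClusteredFixture(pts, labs, covs)
  H <- ensembleEntropy(ensembleDistribution(cl))
  bound <- log10(4) + mean(log10(tabulate(labs)))
  expect_lte(H, bound + 1e-12)
  expect_gte(H, 0)
})
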