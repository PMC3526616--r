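test_that("graph geodesics reduce to the input on complete graphs and sum along chains", {
  set.seed(11)
  P <- matrix(rnorm(21), 7)
  D <- shapeDistanceMatrix(as.matrix(dist(P)))
  G <- geodesicDistances(D, k = 6)
  expect_equal(distanceValues(G), distanceValues(D), tolerance = 1e-12)

  # 4 collinear points, spacing 1, k = 1: end-to-end geodesic is the path sum
  chain <- shapeDistanceMatrix(abs(outer(0:3, 0:3, "-")) * 1.0)
  Gc <- geodesicDistances(chain, k = 1)
  expect_equal(distanceValues(Gc)[1, 4], 3)

  # two far-apart pairs at k = 1 cannot connect
  far <- shapeDistanceMatrix(as.matrix(dist(c(0, 1, 100, 101))))
  expect_error(geodesicDistances(far, k = 1), "component sizes: 2, 2")
})

test_that("graph geodesics equal Floyd-Warshall on random instances and never undercut direct edges", {
  set.seed(19)
  for (n in c(8, 10, 12)) {
    P <- matrix(rnorm(n * 3), n)
    M <- as.matrix(dist(P))
    D <- shapeDistanceMatrix(M)
    G <- distanceValues(geodesicDistances(D, k = 3))
    W <- knnAdjacency(M, 3)
    expect_equal(unname(G), floydWarshall(W), tolerance = 1e-12)
    # shortest path never exceeds an existing direct edge
    hasEdge <- is.finite(W) & upper.tri(W)
    expect_true(all(G[hasEdge] <= W[hasEdge] + 1e-12))
    # and never shrinks below the input distance
    expect_true(all(G >= M - 1e-12))
  }
})

test_that("classical scaling realizes Euclidean distance matrices exactly", {
  two <- shapeDistanceMatrix(rbind(c(0, 4), c(4, 0)))
  E2 <- classicalScaling(two, 1)
  expect_equal(unname(sort(drop(embeddingCoordinates(E2)))), c(-2, 2),
               tolerance = 1e-9)

  tri <- shapeDistanceMatrix(matrix(1, 3, 3) - diag(3))
  E3 <- classicalScaling(tri, 2)
  ed <- as.matrix(dist(embeddingCoordinates(E3)))
  expect_equal(ed[upper.tri(ed)], rep(1, 3), tolerance = 1e-9)

  set.seed(29)
  for (n in c(6, 12, 20)) {
    P <- matrix(rnorm(n * 3, sd = 2), n)
    D <- shapeDistanceMatrix(as.matrix(dist(P)))
    E <- classicalScaling(D, 3)
    ed <- as.matrix(dist(embeddingCoordinates(E)))
    expect_equal(ed, distanceValues(D), tolerance = 1e-9)
    # eigenvalues agree with the cmdscale oracle
    ora <- cmdscale(distanceValues(D), k = 3, eig = TRUE)
    expect_equal(embeddingEigenvalues(E), ora$eig[1:3], tolerance = 1e-9)
  }
  expect_error(classicalScaling(two, 2), "1..n-1")
})

test_that("embedding outputs are centered, eigenvalue-ordered and sign-deterministic", {
  set.seed(37)
  P <- matrix(rnorm(30), 10)
  D <- shapeDistanceMatrix(as.matrix(dist(P)))
  E <- classicalScaling(D, 3)
  C <- embeddingCoordinates(E)
  expect_true(all(abs(colMeans(C)) < 1e-9))
  expect_true(!is.unsorted(rev(embeddingEigenvalues(E))))
  for (j in seq_len(ncol(C)))
    expect_gt(C[which.max(abs(C[, j])), j], 0)
  # identical inputs give identical coordinates (no sign flips)
  expect_identical(C, embeddingCoordinates(classicalScaling(D, 3)))
})

test_that("ISOMAP is exact on Euclidean data and unrolls a curved 1-D manifold", {
  set.seed(43)
  P <- matrix(rnorm(36), 12)
  D <- shapeDistanceMatrix(as.matrix(dist(P)))
  E <- isomapEmbedding(D, k = 11, m = 11)
  expect_equal(fidelity(E), 1, tolerance = 1e-9)

  # points along a circular arc: chord distances, small k, one dimension
  t <- seq(0, 1.8, length.out = 40)
  arc <- cbind(cos(t), sin(t))
  Da <- shapeDistanceMatrix(as.matrix(dist(arc)))
  E1 <- isomapEmbedding(Da, k = 3, m = 1)
  expect_gt(fidelity(E1), 0.99)
  # geodesic order along the arc is preserved
  expect_true(all(diff(order(embeddingCoordinates(E1)[, 1])) %in% c(1, -1)))

  # disconnection triggers automatic k doubling with a warning
  far <- shapeDistanceMatrix(as.matrix(dist(c(0, 1, 2, 50, 51, 52))))
  ws <- capture_warnings(E6 <- isomapEmbedding(far, k = 1, m = 2))
  expect_true(any(grepl("doubling k", ws)))
  expect_identical(nrow(embeddingCoordinates(E6)), 6L)
})

test_that("embedding fidelity is the upper-triangle Pearson correlation", {
  set.seed(47)
  P <- matrix(rnorm(30), 10)
  D <- shapeDistanceMatrix(as.matrix(dist(P)))
  E <- classicalScaling(D, 3)
  expect_equal(embeddingFidelity(E, D), 1, tolerance = 1e-9)
  # scale invariance
  Dc <- shapeDistanceMatrix(3.7 * distanceValues(D))
  expect_equal(embeddingFidelity(E, Dc), 1, tolerance = 1e-9)
  # equals the direct-formula oracle on a non-trivial pair
  E2 <- classicalScaling(Dc, 1)
  ed <- as.matrix(dist(embeddingCoordinates(E2)))
  expect_equal(embeddingFidelity(E2, D),
               pearsonOracle(ed[upper.tri(ed)],
                             distanceValues(D)[upper.tri(ed)]),
               tolerance = 1e-12)
  const <- shapeDistanceMatrix(matrix(1, 4, 4) - diag(4))
  Ec <- classicalScaling(const, 3)
  expect_error(embeddingFidelity(Ec, const), "constant")
})

test_that("component-volume correlation flags volume-driven components", {
  set.seed(53)
  n <- 30
  vol <- rnorm(n, 3000, 300)
  C <- cbind(scale(vol, scale = FALSE), matrix(rnorm(n * 2), n))
  E <- new("ShapeEmbedding", coordinates = scale(C, scale = FALSE),
           eigenvalues = c(3, 2, 1), neighborsK = NA_integer_,
           fidelityR = NA_real_)
  res <- componentVolumeCorrelation(E, vol)
  expect_equal(res$r[1], 1, tolerance = 1e-9)
  # column orthogonalized against volume has r = 0
  x <- rnorm(n)
  xo <- residuals(lm(x ~ vol))
  Eo <- new("ShapeEmbedding",
            coordinates = scale(cbind(xo, rnorm(n)), scale = FALSE),
            eigenvalues = c(2, 1), neighborsK = NA_integer_,
            fidelityR = NA_real_)
  expect_lt(abs(componentVolumeCorrelation(Eo, vol)$r[1]), 1e-9)
  expect_error(componentVolumeCorrelation(E, vol[1:5]), "one volume")
})

test_that("with a global-scale effect only, the first component tracks volume", {
  hits <- vapply(1:50, function(s) {
    spec <- nullEffectSpec(300 + s,
                           groupSizes = c(NC = 20, MCI_s = 1, MCI_c = 1,
                                          AD = 20),
                           volumeEffect = cbind(c(1, 1, 1, 0.9), rep(1, 4)),
                           meshSubdivision = 1, subjectScaleSd = 0.05)
    co <- generateCohort(spec, structures = "hippocampus_L")
    D <- pairwiseDistances(cohortMeshes(co, "hippocampus_L"))
    E <- suppressWarnings(isomapEmbedding(D, k = 10, m = 8))
    r <- abs(componentVolumeCorrelation(E, cohortVolumes(co)[, 1])$r)
    which.max(r) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the default synthetic cohort embeds with high fidelity at 20 components", {
  co <- generateCohort(defaultCohortSpec(seed = 11),
                       structures = c("hippocampus_L", "hippocampus_R"))
  DL <- pairwiseDistances(cohortMeshes(co, "hippocampus_L"))
  DR <- pairwiseDistances(cohortMeshes(co, "hippocampus_R"))
  E <- suppressWarnings(isomapEmbedding(combineStructures(DL, DR),
                                        k = 10, m = 20))
  expect_identical(ncol(embeddingCoordinates(E)), 20L)
  expect_gte(fidelity(E), 0.9)
})
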