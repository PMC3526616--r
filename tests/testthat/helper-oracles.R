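# Fixtures built in code and independent oracles used across the suite.

# regular tetrahedron (the smallest closed triangulation)
tetrahedronMesh <- function(scale = 1) {
  V <- scale * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  T <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  surfaceMesh(V, T)
}

# unit cube split into 12 consistently outward-wound triangles
cubeMesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  T <- rbind(c(1, 4, 3), c(1, 3, 2), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  surfaceMesh(V, T)
}

# two disjoint tetrahedra in one mesh (chi additive over components)
twoTetrahedraMesh <- function() {
  t1 <- tetrahedronMesh()
  V <- rbind(vertices(t1), vertices(t1) + 10)
  T <- rbind(triangles(t1), triangles(t1) + 4L)
  surfaceMesh(V, T)
}

# O(n^3) all-pairs shortest paths; W has Inf for absent edges, 0 diagonal
floydWarshall <- function(W) {
  n <- nrow(W)
  D <- W
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# symmetric kNN adjacency built independently of the package's graph code
knnAdjacency <- function(M, k) {
  n <- nrow(M)
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(M[i, others])][seq_len(k)]
    for (j in nn) {
      W[i, j] <- M[i, j]
      W[j, i] <- M[i, j]
    }
  }
  W
}

# SMO solver for the soft-margin linear SVM dual on tiny instances; returns
# the optimal dual objective, which equals the primal optimum (strong
# duality), independent of libsvm
smoDualObjective <- function(X, y, C, sweeps = 20000, tol = 1e-14) {
  n <- nrow(X)
  K <- X %*% t(X)
  a <- rep(0, n)
  f <- function() drop(K %*% (a * y))
  for (s in seq_len(sweeps)) {
    biggest <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta <= 0) next
      Fi <- sum(K[i, ] * a * y) - y[i]
      Fj <- sum(K[j, ] * a * y) - y[j]
      ajNew <- a[j] + y[j] * (Fi - Fj) / eta
      if (y[i] != y[j]) {
        L <- max(0, a[j] - a[i]); H <- min(C, C + a[j] - a[i])
      } else {
        L <- max(0, a[i] + a[j] - C); H <- min(C, a[i] + a[j])
      }
      ajNew <- min(max(ajNew, L), H)
      d <- ajNew - a[j]
      if (abs(d) > biggest) biggest <- abs(d)
      a[i] <- a[i] - y[i] * y[j] * d
      a[j] <- ajNew
    }
    if (biggest < tol) break
  }
  sum(a) - 0.5 * drop(t(a * y) %*% K %*% (a * y))
}

# primal hinge objective of a fitted linear classifier
primalObjective <- function(model, X, y, C) {
  ypm <- ifelse(y == model$positive, 1, -1)
  margins <- ypm * (drop(X %*% model$weights) + model$bias)
  0.5 * sum(model$weights^2) + C * sum(pmax(0, 1 - margins))
}

# textbook pooled-variance two-sample t and its two-tailed p
pooledTOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), df = nx + ny - 2))
}

# direct-formula Pearson correlation
pearsonOracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# cohort spec with every planted effect switched off (one shared CSF
# distribution, unit volume scales, no bump); overrides via ... win
nullEffectSpec <- function(seed, ...) {
  args <- utils::modifyList(
    list(csfMeans = matrix(rep(c(205, 70, 25), each = 4), 4),
         csfSds = matrix(rep(c(55, 30, 10), each = 4), 4),
         volumeEffect = matrix(1, 4, 2),
         bumpAmplitude = c(NC = 0, MCI_s = 0, MCI_c = 0, AD = 0),
         seed = seed),
    list(...))
  do.call(cohortSpec, args)
}

# 2-SD planted CSF effects on independent markers at the default group sizes
twoSdEffectSpec <- function(seed, ...) {
  cohortSpec(csfMeans = rbind(NC = c(200, 70, 25), MCI_s = c(150, 100, 35),
                              MCI_c = c(100, 130, 45), AD = c(100, 130, 45)),
             csfSds = matrix(rep(c(50, 30, 10), each = 4), 4),
             csfCorr = diag(3), seed = seed, ...)
}
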