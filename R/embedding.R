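## ISOMAP: k-nearest-neighbour graph geodesics followed by classical scaling
## of the double-centered squared-distance kernel, plus embedding-fidelity
## and component-volume diagnostics.

#' Graph geodesic distances over a k-nearest-neighbour graph
#'
#' Builds the symmetric kNN graph (edge (i,j) exists iff j is among i's k
#' nearest neighbours or vice versa, weighted by the input distance) and
#' returns all-pairs shortest-path distances (Dijkstra).
#'
#' @param D A \linkS4class{ShapeDistanceMatrix}.
#' @param k neighbour count, >= 1.
#' @return A \linkS4class{ShapeDistanceMatrix} of geodesic distances.
#' @export
geodesicDistances <- function(D, k) {
  stopifnot(is(D, "ShapeDistanceMatrix"))
  M <- D@values
  n <- nrow(M)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  k <- min(k, n - 1L)
  el <- NULL
  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    js <- others[order(M[i, others])[seq_len(k)]]
    el <- rbind(el, cbind(i, js))
  }
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[!duplicated(el), , drop = FALSE]
  g <- igraph::make_graph(t(el), n = n, directed = FALSE)
  w <- M[el]
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop(sprintf(
      "kNN graph disconnected at k = %d (component sizes: %s); use a larger k",
      k, paste(comp$csize, collapse = ", ")), call. = FALSE)
  G <- igraph::distances(g, weights = w, algorithm = "dijkstra")
  dimnames(G) <- NULL
  shapeDistanceMatrix(G, D@subjectIds)
}

#' Classical scaling (metric MDS) of a distance matrix
#'
#' Eigendecomposition of B = -1/2 J (D o D) J with J = I - 11'/n the
#' centering matrix. Coordinates are the top-m eigenvectors scaled by the
#' square roots of their eigenvalues; negative eigenvalues (non-Euclidean
#' input) are clamped to zero for coordinates but kept in the eigenvalue
#' slot for diagnostics. Exact for Euclidean-realizable D at sufficient m.
#' Each eigenvector's sign is fixed so its largest-magnitude entry is
#' positive (determinism).
#'
#' @param D A \linkS4class{ShapeDistanceMatrix}.
#' @param m number of components, 1 <= m <= n - 1.
#' @return A \linkS4class{ShapeEmbedding} (fidelity not yet filled).
#' @export
classicalScaling <- function(D, m) {
  stopifnot(is(D, "ShapeDistanceMatrix"))
  n <- nrow(D@values)
  if (m < 1 || m > n - 1) stop("m must lie in 1..n-1", call. = FALSE)
  D2 <- D@values^2
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(D2))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values[seq_len(m)]
  Vc <- e$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    peak <- which.max(abs(Vc[, j]))
    if (Vc[peak, j] < 0) Vc[, j] <- -Vc[, j]
  }
  coords <- Vc %*% diag(sqrt(pmax(lam, 0)), m, m)
  rownames(coords) <- D@subjectIds
  colnames(coords) <- sprintf("C%d", seq_len(m))
  new("ShapeEmbedding", coordinates = coords, eigenvalues = lam,
      neighborsK = NA_integer_, fidelityR = NA_real_)
}

#' ISOMAP embedding of a shape distance matrix
#'
#' Geodesic distances on the kNN graph followed by classical scaling. If the
#' graph is disconnected at the requested k, k is doubled (with a warning)
#' until it connects. The fidelity slot is filled with the Pearson
#' correlation between the embedded Euclidean distances and the *input*
#' metric distances, the quantity quoted to justify a 20-component
#' representation of corresponded shapes.
#'
#' @param D A \linkS4class{ShapeDistanceMatrix}.
#' @param k neighbour count (default 10).
#' @param m number of components to retain (default 20).
#' @return A \linkS4class{ShapeEmbedding}.
#' @export
isomapEmbedding <- function(D, k = 10, m = 20) {
  stopifnot(is(D, "ShapeDistanceMatrix"))
  n <- nrow(D@values)
  m <- min(m, n - 1L)
  kUse <- min(k, n - 1L)
  repeat {
    G <- tryCatch(geodesicDistances(D, kUse), error = function(e) e)
    if (!inherits(G, "error")) break
    if (kUse >= n - 1L) stop(G)
    kUse <- min(2L * kUse, n - 1L)
    warning("kNN graph disconnected; doubling k to ", kUse, call. = FALSE)
  }
  E <- classicalScaling(G, m)
  E@neighborsK <- as.integer(kUse)
  E@fidelityR <- embeddingFidelity(E, D)
  E
}

#' Fidelity of an embedding against a distance matrix
#'
#' Pearson correlation between the upper-triangle entries of the embedded
#' Euclidean distance matrix and of D. Scale-invariant; 1 when the embedding
#' realizes D exactly.
#'
#' @param E A \linkS4class{ShapeEmbedding}.
#' @param D A \linkS4class{ShapeDistanceMatrix} over the same subjects.
#' @return Pearson r.
#' @export
embeddingFidelity <- function(E, D) {
  stopifnot(is(E, "ShapeEmbedding"), is(D, "ShapeDistanceMatrix"))
  if (nrow(E@coordinates) != nrow(D@values))
    stop("embedding and distance matrix cover different subjects", call. = FALSE)
  ed <- as.matrix(stats::dist(E@coordinates))
  x <- .upperTriangle(ed)
  y <- .upperTriangle(D@values)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant distances", call. = FALSE)
  stats::cor(x, y)
}

#' Correlation of each embedding component with structure volume
#'
#' Pearson r and two-tailed p per component against a per-subject volume,
#' the diagnostic separating globally volume-driven components from
#' volume-orthogonal local shape components.
#'
#' @param E A \linkS4class{ShapeEmbedding}.
#' @param volumes numeric per-subject volumes (mm^3), in embedding row order.
#' @return data.frame with columns component, r, p.
#' @export
componentVolumeCorrelation <- function(E, volumes) {
  stopifnot(is(E, "ShapeEmbedding"))
  C <- E@coordinates
  if (length(volumes) != nrow(C))
    stop("one volume per embedded subject required", call. = FALSE)
  if (nrow(C) < 3L) stop("need at least 3 subjects", call. = FALSE)
  res <- lapply(seq_len(ncol(C)), function(j) {
    ct <- stats::cor.test(C[, j], volumes)
    data.frame(component = j, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' Write an embedding as CSV with a JSON sidecar
#'
#' Coordinates go to \code{path} (subjects x components); eigenvalues,
#' neighbour count and fidelity go to \code{paste0(path, ".json")}.
#'
#' @param E A \linkS4class{ShapeEmbedding}.
#' @param path output CSV path.
#' @return Invisibly, the CSV path.
#' @export
writeEmbedding <- function(E, path) {
  stopifnot(is(E, "ShapeEmbedding"))
  df <- data.frame(subject_id = rownames(E@coordinates), E@coordinates,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(eigenvalues = E@eigenvalues,
               neighbors_k = E@neighborsK,
               fidelity_r = E@fidelityR)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
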