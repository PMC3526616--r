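## First-order approximation of the diffeomorphic metric distance between
## corresponded shapes. At the identity, the LDDMM landmark geodesic distance
## linearizes to the RKHS momentum form d^2 = t(Delta) K^-1 Delta, with Delta
## the stacked corresponded vertex displacement and K the Gaussian kernel
## Gram matrix on the reference shape's vertices, applied identically per
## coordinate. A displacement that is smooth on the kernel scale is cheap; a
## rough one is expensive -- exactly the geometry LDDMM induces near the
## identity.

.kernelGram <- function(X, sigma) {
  exp(-as.matrix(stats::dist(X))^2 / (2 * sigma^2))
}

.kernelSolve <- function(K, Delta) {
  tryCatch(solve(K, Delta),
           error = function(e)
             stop("kernel Gram matrix is numerically singular; ",
                  "use a positive ridge in metricParams()", call. = FALSE))
}

.oneSidedSquaredDistance <- function(Xa, Xb, sigma, ridge) {
  K <- .kernelGram(Xa, sigma)
  if (ridge > 0) diag(K) <- diag(K) + ridge
  Delta <- Xb - Xa
  p <- .kernelSolve(K, Delta)
  max(sum(Delta * p), 0)
}

#' Default metric parameters for a set of meshes
#'
#' Kernel width 5 times the mean edge length of the reference mesh -- wide
#' enough that anatomically smooth deformations are cheap, narrow enough to
#' resolve localized shape change -- with ridge 1e-6 on the unit kernel
#' diagonal for conditioning.
#'
#' @param mesh reference \linkS4class{SurfaceMesh}.
#' @return A \linkS4class{MetricParams}.
#' @export
defaultMetricParams <- function(mesh) {
  metricParams(kernelSigma = 5 * meshStatistics(mesh)$meanEdgeLength,
               ridge = 1e-6)
}

#' @describeIn firstOrderDistance on landmark/vertex matrices (points in rows)
#' @export
setMethod("firstOrderDistance", signature("matrix", "matrix"),
          function(a, b, params, symmetrize = TRUE) {
  stopifnot(is(params, "MetricParams"))
  if (!all(dim(a) == dim(b)))
    stop("configurations must be corresponded (identical dimensions)",
         call. = FALSE)
  d2 <- .oneSidedSquaredDistance(a, b, params@kernelSigma, params@ridge)
  if (symmetrize) {
    d2b <- .oneSidedSquaredDistance(b, a, params@kernelSigma, params@ridge)
    d2 <- (d2 + d2b) / 2
  }
  sqrt(d2)
})

#' @describeIn firstOrderDistance on corresponded surface meshes
#' @export
setMethod("firstOrderDistance", signature("SurfaceMesh", "SurfaceMesh"),
          function(a, b, params, symmetrize = TRUE) {
  if (!identical(a@triangles, b@triangles))
    stop("meshes must share identical connectivity (atlas correspondence)",
         call. = FALSE)
  if (missing(params)) params <- defaultMetricParams(a)
  firstOrderDistance(a@vertices, b@vertices, params, symmetrize = symmetrize)
})

#' @describeIn rigidAlign on corresponded point matrices
#' @export
setMethod("rigidAlign", signature("matrix", "matrix"),
          function(moving, fixed) {
  if (!all(dim(moving) == dim(fixed)))
    stop("corresponded point sets must have identical dimensions",
         call. = FALSE)
  mc <- colMeans(moving)
  fc <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2L, mc), sweep(fixed, 2L, fc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(moving, 2L, mc) %*% t(R), 2L, fc, `+`)
})

#' @describeIn rigidAlign on corresponded surface meshes
#' @export
setMethod("rigidAlign", signature("SurfaceMesh", "SurfaceMesh"),
          function(moving, fixed) {
  if (!identical(moving@triangles, fixed@triangles))
    stop("meshes must share identical connectivity", call. = FALSE)
  surfaceMesh(rigidAlign(moving@vertices, fixed@vertices),
              moving@triangles, moving@structureTag, validate = FALSE)
})

#' Pairwise first-order diffeomorphic metric distances
#'
#' Assembles the symmetric distance matrix over a list of corresponded
#' meshes. Every mesh is first rigidly aligned (rotation + translation, no
#' scaling) to the first mesh; each one-sided solve factorizes the reference
#' mesh's kernel once and is applied to all other subjects, and the two
#' one-sided squared distances are averaged so the matrix is exactly
#' symmetric.
#'
#' @param meshes named list of \linkS4class{SurfaceMesh} with common
#'   connectivity (>= 2 meshes); names become subject ids.
#' @param params \linkS4class{MetricParams}; default
#'   \code{\link{defaultMetricParams}} of the first mesh.
#' @param align rigidly align all meshes to the first before measuring
#'   (default TRUE; a near-no-op for synthetic cohorts generated in a common
#'   frame, it matters for imported data).
#' @return A \linkS4class{ShapeDistanceMatrix}.
#' @export
pairwiseDistances <- function(meshes, params = NULL, align = TRUE) {
  n <- length(meshes)
  if (n < 2L) stop("need at least 2 meshes", call. = FALSE)
  tri0 <- meshes[[1L]]@triangles
  for (j in seq_len(n))
    if (!identical(meshes[[j]]@triangles, tri0))
      stop("mesh ", j, " does not share the common connectivity", call. = FALSE)
  if (is.null(params)) params <- defaultMetricParams(meshes[[1L]])
  ids <- if (!is.null(names(meshes))) names(meshes)
         else sprintf("S%03d", seq_len(n))
  Xs <- lapply(meshes, function(m) m@vertices)
  if (align)
    Xs <- c(Xs[1L], lapply(Xs[-1L], rigidAlign, fixed = Xs[[1L]]))
  V <- nrow(Xs[[1L]])
  Big <- do.call(cbind, Xs)                      # V x 3n
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    K <- .kernelGram(Xs[[i]], params@kernelSigma)
    if (params@ridge > 0) diag(K) <- diag(K) + params@ridge
    ch <- tryCatch(chol(K),
                   error = function(e)
                     stop("kernel Gram matrix is numerically singular for subject ",
                          ids[i], "; use a positive ridge", call. = FALSE))
    Delta <- Big - Big[, rep((3L * i - 2L):(3L * i), n)]
    P <- backsolve(ch, forwardsolve(t(ch), Delta))
    cs <- colSums(Delta * P)
    d2[i, ] <- cs[seq(1L, 3L * n, 3L)] + cs[seq(2L, 3L * n, 3L)] +
               cs[seq(3L, 3L * n, 3L)]
  }
  D <- sqrt(pmax((d2 + t(d2)) / 2, 0))
  diag(D) <- 0
  shapeDistanceMatrix(D, ids)
}

#' Combine left and right structure distances into one bilateral matrix
#'
#' Entrywise root-sum-square: d = sqrt(dL^2 + dR^2), the distance induced by
#' concatenating the two structures' displacement spaces, so one embedding
#' can characterize bilateral shape.
#'
#' @param left,right \linkS4class{ShapeDistanceMatrix} objects over the same
#'   subjects in the same order.
#' @return A \linkS4class{ShapeDistanceMatrix}.
#' @export
combineStructures <- function(left, right) {
  stopifnot(is(left, "ShapeDistanceMatrix"), is(right, "ShapeDistanceMatrix"))
  if (!identical(left@subjectIds, right@subjectIds))
    stop("subject ids / order differ between the two matrices", call. = FALSE)
  shapeDistanceMatrix(sqrt(left@values^2 + right@values^2), left@subjectIds)
}
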