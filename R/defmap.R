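## Vertex-wise signed surface-deformation group-difference maps. Warm (+) =
## outward deformation in the first-named group relative to the second,
## cool (-) = inward; p-values from per-vertex pooled-variance Student t on
## the per-subject normal components.

#' Vertex-wise signed deformation difference between two groups
#'
#' Projects each subject's corresponded vertex positions onto the base
#' (atlas) mesh's outward vertex normals and compares the two groups per
#' vertex: displacement is the normal component of (mean_a - mean_b)
#' position, positive where the first group's surface sits outward of the
#' second's. Swapping groups negates every displacement exactly. The
#' per-vertex p comes from a pooled-variance Student t on the subjects'
#' normal components (NA where the pooled variance is zero, e.g. noise-free
#' identical groups).
#'
#' @param meshesA,meshesB lists of \linkS4class{SurfaceMesh} for the two
#'   groups, sharing the base connectivity.
#' @param base the atlas \linkS4class{SurfaceMesh} defining vertices and
#'   outward normals.
#' @param contrast labels of the two groups, former first.
#' @return A \linkS4class{DeformationMap}.
#' @export
vertexGroupDifference <- function(meshesA, meshesB, base,
                                  contrast = c("A", "B")) {
  stopifnot(is(base, "SurfaceMesh"))
  if (!length(meshesA) || !length(meshesB))
    stop("both groups must be nonempty", call. = FALSE)
  tri0 <- base@triangles
  for (m in c(meshesA, meshesB))
    if (!identical(m@triangles, tri0))
      stop("all meshes must share the base connectivity", call. = FALSE)
  N <- vertexNormals(base)
  normalComp <- function(m) rowSums(m@vertices * N)
  SA <- vapply(meshesA, normalComp, numeric(nrow(N)))   # V x nA
  SB <- vapply(meshesB, normalComp, numeric(nrow(N)))
  nA <- ncol(SA); nB <- ncol(SB)
  mA <- rowMeans(SA); mB <- rowMeans(SB)
  disp <- mA - mB
  vA <- apply(SA, 1L, stats::var)
  vB <- apply(SB, 1L, stats::var)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tstat <- ifelse(se > 0, disp / se, NA_real_)
  p <- ifelse(is.na(tstat), NA_real_,
              2 * stats::pt(-abs(tstat), df = nA + nB - 2))
  new("DeformationMap", displacement = disp, statistic = tstat,
      pValue = p, contrast = as.character(contrast),
      structureTag = base@structureTag)
}

#' Write a deformation map as per-vertex CSV
#'
#' Columns: vertex (1-based), displacement_mm (signed, + = outward in the
#' former group), t, p.
#'
#' @param map A \linkS4class{DeformationMap}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeDeformationMapCsv <- function(map, path) {
  stopifnot(is(map, "DeformationMap"))
  utils::write.csv(
    data.frame(vertex = seq_along(map@displacement),
               displacement_mm = map@displacement,
               t = map@statistic, p = map@pValue),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a deformation map as an ASCII PLY with scalar vertex properties
#'
#' The base mesh's geometry with extra per-vertex float properties
#' \code{displacement} and \code{pvalue}, renderable in standard mesh
#' viewers.
#'
#' @param map A \linkS4class{DeformationMap}.
#' @param base the atlas \linkS4class{SurfaceMesh} the map lives on.
#' @param path output PLY path.
#' @return Invisibly, the path.
#' @export
writeDeformationMapPly <- function(map, base, path) {
  stopifnot(is(map, "DeformationMap"), is(base, "SurfaceMesh"))
  if (length(map@displacement) != nrow(base@vertices))
    stop("map length must equal the base mesh vertex count", call. = FALSE)
  V <- base@vertices
  Tm <- base@triangles - 1L
  p <- ifelse(is.na(map@pValue), 1, map@pValue)
  txt <- c("ply", "format ascii 1.0",
           sprintf("comment deformation map %s vs %s on %s",
                   map@contrast[1], map@contrast[2], map@structureTag),
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           "property float displacement", "property float pvalue",
           sprintf("element face %d", nrow(Tm)),
           "property list uchar int vertex_indices",
           "end_header",
           sprintf("%.10g %.10g %.10g %.10g %.10g",
                   V[, 1], V[, 2], V[, 3], map@displacement, p),
           sprintf("3 %d %d %d", Tm[, 1], Tm[, 2], Tm[, 3]))
  writeLines(txt, path)
  invisible(path)
}
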