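#' @import methods
NULL

#' Vertex coordinates of a surface mesh
#'
#' @param x A \linkS4class{SurfaceMesh}.
#' @return Numeric matrix, one row per vertex, columns x/y/z in mm.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' Triangle connectivity of a surface mesh
#'
#' @param x A \linkS4class{SurfaceMesh}.
#' @return Integer matrix of 1-based vertex index triples, one row per triangle.
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))

#' Anatomical structure tag
#'
#' @param x A \linkS4class{SurfaceMesh}.
#' @return Character scalar, one of \code{hippocampus_L}, \code{hippocampus_R},
#'   \code{ventricle_L}, \code{ventricle_R}, \code{synthetic}.
#' @export
setGeneric("structureTag", function(x) standardGeneric("structureTag"))

#' Subject identifiers carried by an object
#'
#' @param x A \linkS4class{ShapeDistanceMatrix}, \linkS4class{ShapeCohort},
#'   \linkS4class{ShapeEmbedding} or \linkS4class{FeatureSet}.
#' @return Character vector of subject ids, in the object's row order.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Pairwise distance values
#'
#' @param x A \linkS4class{ShapeDistanceMatrix}.
#' @return Symmetric nonnegative numeric matrix with zero diagonal.
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' Embedding coordinates
#'
#' @param x A \linkS4class{ShapeEmbedding}.
#' @return Numeric matrix, subjects by components, columns ordered by
#'   nonincreasing eigenvalue and centered to zero mean.
#' @export
setGeneric("embeddingCoordinates", function(x) standardGeneric("embeddingCoordinates"))

#' Eigenvalues behind an embedding
#'
#' Raw eigenvalues of the double-centered kernel matrix, including any negative
#' values retained for diagnostics (coordinates use their nonnegative clamp).
#'
#' @param x A \linkS4class{ShapeEmbedding}.
#' @return Numeric vector, nonincreasing.
#' @export
setGeneric("embeddingEigenvalues", function(x) standardGeneric("embeddingEigenvalues"))

#' Embedding fidelity (Pearson r)
#'
#' @param x A \linkS4class{ShapeEmbedding}.
#' @return Pearson correlation between embedded Euclidean distances and the
#'   distance matrix the embedding was computed from, or NA if not yet filled.
#' @export
setGeneric("fidelity", function(x) standardGeneric("fidelity"))

#' First-order diffeomorphic metric distance between two corresponded shapes
#'
#' @param a,b Two \linkS4class{SurfaceMesh} objects sharing connectivity, or
#'   two numeric landmark matrices (points in rows) of equal dimension.
#' @param params A \linkS4class{MetricParams} object; see \code{\link{metricParams}}.
#' @param symmetrize Average the two one-sided squared distances (default TRUE)
#'   so the result is exactly symmetric in its arguments.
#' @return Nonnegative numeric distance (dimensionless).
#' @export
setGeneric("firstOrderDistance",
           function(a, b, params, symmetrize = TRUE) standardGeneric("firstOrderDistance"))

#' Rigid alignment of one corresponded shape onto another
#'
#' Least-squares rotation + translation (no scaling: overall size is a signal
#' in this analysis, not a nuisance) over corresponded vertices.
#'
#' @param moving,fixed Two \linkS4class{SurfaceMesh} objects with identical
#'   connectivity, or two corresponded point matrices.
#' @return The moving object, rigidly transformed onto fixed.
#' @export
setGeneric("rigidAlign", function(moving, fixed) standardGeneric("rigidAlign"))
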