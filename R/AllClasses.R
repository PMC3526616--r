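## Central S4 containers. Validity methods enforce the geometric and
## bookkeeping invariants the pipeline relies on; everything downstream may
## assume a validated object.

.STRUCTURE_TAGS <- c("hippocampus_L", "hippocampus_R",
                     "ventricle_L", "ventricle_R", "synthetic")
.GROUPS <- c("NC", "MCI_s", "MCI_c", "AD")
.CSF_MARKERS <- c("abeta42", "t_tau", "p_tau")
.FEATURE_SETS <- c("Hp_volumes", "Hp_shapes", "LV_volumes", "LV_shapes",
                   "CSF", "CSF+volumes", "CSF+shapes")

#' SurfaceMesh: a closed triangulated anatomical surface
#'
#' Vertices (mm) and triangle connectivity of one closed structure surface.
#' All subjects of a cohort share one connectivity per structure (atlas
#' correspondence). Validity requires a closed, consistently oriented
#' 2-manifold triangulation with no degenerate triangles.
#'
#' @slot vertices numeric matrix, n x 3, coordinates in mm.
#' @slot triangles integer matrix, m x 3, 1-based vertex indices.
#' @slot structureTag character scalar naming the structure.
#' @export
setClass("SurfaceMesh",
         representation(vertices = "matrix",
                        triangles = "matrix",
                        structureTag = "character"))

## half-edge bookkeeping shared by validity, Euler characteristic and stats
.halfEdges <- function(tri) {
  rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
}

.edgeKeys <- function(he, nV) {
  (pmin(he[, 1L], he[, 2L]) - 1) * as.double(nV) + pmax(he[, 1L], he[, 2L])
}

.triangleAreas <- function(V, tri) {
  a <- V[tri[, 2L], , drop = FALSE] - V[tri[, 1L], , drop = FALSE]
  b <- V[tri[, 3L], , drop = FALSE] - V[tri[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

.validSurfaceMesh <- function(object) {
  V <- object@vertices
  tri <- object@triangles
  if (!is.numeric(V) || ncol(V) != 3L)
    return("vertices must be a numeric matrix with 3 columns")
  if (any(!is.finite(V)))
    return("vertex coordinates must be finite")
  if (!is.numeric(tri) || ncol(tri) != 3L || nrow(tri) < 1L)
    return("triangles must be an index matrix with 3 columns")
  if (length(object@structureTag) != 1L ||
      !object@structureTag %in% .STRUCTURE_TAGS)
    return(sprintf("structureTag must be one of: %s",
                   paste(.STRUCTURE_TAGS, collapse = ", ")))
  nV <- nrow(V)
  if (any(tri < 1L) || any(tri > nV))
    return("triangle refers to a vertex index outside 1..nV")
  if (any(tri[, 1L] == tri[, 2L] | tri[, 2L] == tri[, 3L] |
          tri[, 1L] == tri[, 3L]))
    return("degenerate triangle: repeated vertex index")
  areas <- .triangleAreas(V, tri)
  if (any(areas < 1e-12))
    return("degenerate triangle: area below 1e-12 mm^2")
  he <- .halfEdges(tri)
  dkey <- (he[, 1L] - 1) * as.double(nV) + he[, 2L]
  if (anyDuplicated(dkey))
    return("inconsistent orientation: a directed edge appears twice")
  cnt <- table(.edgeKeys(he, nV))
  if (any(cnt != 2L))
    return("not a closed 2-manifold: every edge must be shared by exactly 2 triangles")
  TRUE
}

setValidity("SurfaceMesh", .validSurfaceMesh)

#' Construct a SurfaceMesh
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param triangles m x 3 matrix of 1-based vertex indices.
#' @param structureTag one of \code{hippocampus_L}, \code{hippocampus_R},
#'   \code{ventricle_L}, \code{ventricle_R}, \code{synthetic}.
#' @param validate run the full closed-manifold validity check (default TRUE).
#'   Generators that deform a validated mesh without touching connectivity may
#'   skip it.
#' @return A \linkS4class{SurfaceMesh}.
#' @examples
#' m <- surfaceMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)),
#'                  rbind(c(1,3,2), c(1,2,4), c(2,3,4), c(1,4,3)))
#' eulerCharacteristic(m)
#' @export
surfaceMesh <- function(vertices, triangles, structureTag = "synthetic",
                        validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (validate)
    return(new("SurfaceMesh", vertices = vertices, triangles = triangles,
               structureTag = structureTag))
  # fast path for generators that deform a validated mesh without touching
  # connectivity: mutate a cached valid prototype, skipping the O(F) manifold
  # re-check that new() would trigger
  obj <- .meshPrototype()
  obj@vertices <- vertices
  obj@triangles <- triangles
  obj@structureTag <- structureTag
  obj
}

.meshPrototypeCache <- new.env(parent = emptyenv())

.meshPrototype <- function() {
  if (is.null(.meshPrototypeCache$proto)) {
    V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    T <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(2L, 3L, 4L), c(1L, 4L, 3L))
    storage.mode(V) <- "double"
    .meshPrototypeCache$proto <- new("SurfaceMesh", vertices = V,
                                     triangles = T,
                                     structureTag = "synthetic")
  }
  .meshPrototypeCache$proto
}

#' @describeIn vertices vertex coordinates of the mesh
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)

#' @describeIn triangles triangle index matrix of the mesh
#' @export
setMethod("triangles", "SurfaceMesh", function(x) x@triangles)

#' @describeIn structureTag structure tag of the mesh
#' @export
setMethod("structureTag", "SurfaceMesh", function(x) x@structureTag)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh [%s]: %d vertices, %d triangles\n",
              object@structureTag, nrow(object@vertices),
              nrow(object@triangles)))
})

#' MetricParams: kernel parameters of the shape metric
#'
#' @slot kernelSigma Gaussian kernel width in mm (> 0).
#' @slot ridge dimensionless Tikhonov regularizer added to the kernel Gram
#'   diagonal (>= 0).
#' @export
setClass("MetricParams",
         representation(kernelSigma = "numeric", ridge = "numeric"))

setValidity("MetricParams", function(object) {
  if (length(object@kernelSigma) != 1L || !is.finite(object@kernelSigma) ||
      object@kernelSigma <= 0)
    return("kernelSigma must be a single positive number (mm)")
  if (length(object@ridge) != 1L || !is.finite(object@ridge) ||
      object@ridge < 0)
    return("ridge must be a single nonnegative number")
  TRUE
})

#' Parameters of the first-order diffeomorphic metric
#'
#' The metric evaluates d^2 = t(Delta) K^-1 Delta with K the Gaussian kernel
#' Gram matrix on the first mesh's vertices. A wider kernel penalizes
#' non-smooth displacement fields more strongly; the ridge keeps the solve
#' well-posed when vertices (near-)coincide on the kernel scale.
#'
#' @param kernelSigma Gaussian kernel width, mm.
#' @param ridge regularizer added to the Gram diagonal; default 1e-6 relative
#'   to the unit kernel diagonal.
#' @return A \linkS4class{MetricParams}.
#' @export
metricParams <- function(kernelSigma, ridge = 1e-6) {
  new("MetricParams", kernelSigma = as.numeric(kernelSigma),
      ridge = as.numeric(ridge))
}

#' ShapeDistanceMatrix: pairwise shape distances over subjects
#'
#' @slot values symmetric nonnegative numeric matrix, zero diagonal.
#' @slot subjectIds ordered subject identifiers (row/column order).
#' @export
setClass("ShapeDistanceMatrix",
         representation(values = "matrix", subjectIds = "character"))

setValidity("ShapeDistanceMatrix", function(object) {
  v <- object@values
  n <- nrow(v)
  if (ncol(v) != n) return("values must be square")
  if (length(object@subjectIds) != n)
    return("subjectIds length must match matrix dimension")
  if (anyDuplicated(object@subjectIds)) return("duplicate subject ids")
  if (any(!is.finite(v))) return("distances must be finite")
  if (any(v < 0)) return("distances must be nonnegative")
  if (any(abs(diag(v)) > 0)) return("diagonal must be exactly zero")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
    return("values must be symmetric")
  TRUE
})

#' Construct a ShapeDistanceMatrix
#'
#' @param values square symmetric nonnegative matrix with zero diagonal.
#' @param subjectIds subject identifiers in row order; defaults to the
#'   matrix's rownames or S1..Sn.
#' @return A \linkS4class{ShapeDistanceMatrix}.
#' @export
shapeDistanceMatrix <- function(values, subjectIds = NULL) {
  values <- as.matrix(values)
  if (is.null(subjectIds))
    subjectIds <- if (!is.null(rownames(values))) rownames(values)
                  else sprintf("S%03d", seq_len(nrow(values)))
  dimnames(values) <- list(subjectIds, subjectIds)
  new("ShapeDistanceMatrix", values = values,
      subjectIds = as.character(subjectIds))
}

#' @describeIn distanceValues the distance matrix itself
#' @export
setMethod("distanceValues", "ShapeDistanceMatrix", function(x) x@values)

#' @describeIn subjectIds subject order of a distance matrix
#' @export
setMethod("subjectIds", "ShapeDistanceMatrix", function(x) x@subjectIds)

setMethod("show", "ShapeDistanceMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("ShapeDistanceMatrix: %d subjects; distances %.4g .. %.4g (median %.4g)\n",
              nrow(object@values), min(v), max(v), stats::median(v)))
})

setMethod("dim", "ShapeDistanceMatrix", function(x) dim(x@values))

#' ShapeEmbedding: low-dimensional coordinates of shapes
#'
#' Per-subject coordinates on the leading components of classical scaling /
#' ISOMAP, with the eigenvalues of the centered kernel matrix and the Pearson
#' fidelity of the embedding against the distance matrix it came from.
#'
#' @slot coordinates numeric matrix, subjects x components.
#' @slot eigenvalues raw eigenvalues, nonincreasing (negatives kept for
#'   diagnostics; coordinates use their nonnegative clamp).
#' @slot neighborsK k of the neighborhood graph (NA for plain classical scaling).
#' @slot fidelityR Pearson r between embedded and input distances (NA until filled).
#' @export
setClass("ShapeEmbedding",
         representation(coordinates = "matrix", eigenvalues = "numeric",
                        neighborsK = "integer", fidelityR = "numeric"))

setValidity("ShapeEmbedding", function(object) {
  m <- ncol(object@coordinates)
  if (length(object@eigenvalues) != m)
    return("one eigenvalue per coordinate column required")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be nonincreasing")
  ctr <- colMeans(object@coordinates)
  if (any(abs(ctr) > 1e-6 * (1 + max(abs(object@coordinates)))))
    return("coordinate columns must be centered")
  if (!is.na(object@fidelityR) &&
      (object@fidelityR < -1 - 1e-12 || object@fidelityR > 1 + 1e-12))
    return("fidelityR must lie in [-1, 1]")
  TRUE
})

#' @describeIn embeddingCoordinates coordinates of a shape embedding
#' @export
setMethod("embeddingCoordinates", "ShapeEmbedding", function(x) x@coordinates)

#' @describeIn embeddingEigenvalues eigenvalues of a shape embedding
#' @export
setMethod("embeddingEigenvalues", "ShapeEmbedding", function(x) x@eigenvalues)

#' @describeIn fidelity fidelity of a shape embedding
#' @export
setMethod("fidelity", "ShapeEmbedding", function(x) x@fidelityR)

#' @describeIn subjectIds subject order of an embedding
#' @export
setMethod("subjectIds", "ShapeEmbedding", function(x) rownames(x@coordinates))

setMethod("show", "ShapeEmbedding", function(object) {
  cat(sprintf("ShapeEmbedding: %d subjects x %d components (k = %s, fidelity r = %s)\n",
              nrow(object@coordinates), ncol(object@coordinates),
              ifelse(is.na(object@neighborsK), "-", object@neighborsK),
              ifelse(is.na(object@fidelityR), "-",
                     sprintf("%.3f", object@fidelityR))))
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Encodes the statistical structure the analysis assumes: per-group CSF
#' distributions, per-group global volume effects, a volume-neutral localized
#' shape deformation (paired outward/inward bumps), per-subject size jitter
#' and vertex measurement noise. See \code{\link{cohortSpec}}.
#'
#' @slot groupSizes named integer vector (NC, MCI_s, MCI_c, AD).
#' @slot csfMeans,csfSds 4 x 3 matrices (groups x markers), pg/mL.
#' @slot csfCorr 3 x 3 within-subject marker correlation matrix.
#' @slot volumeEffect 4 x 2 matrix of linear scale factors
#'   (groups x c(hippocampus, ventricle)).
#' @slot bumpAmplitude named numeric per group, mm (0 = no bump).
#' @slot bumpWidth angular width of the Gaussian bump profile, radians.
#' @slot bumpStructures structures carrying the bump pair.
#' @slot vertexNoiseSd i.i.d. per-vertex Gaussian jitter, mm.
#' @slot subjectScaleSd sd of per-subject lognormal global size jitter.
#' @slot ageMean,ageSd named numeric per group, years.
#' @slot meshSubdivision icosphere subdivision level of the base meshes.
#' @slot hippocampusAxes,ventricleAxes ellipsoid semi-axes, mm.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec",
         representation(groupSizes = "integer",
                        csfMeans = "matrix", csfSds = "matrix",
                        csfCorr = "matrix",
                        volumeEffect = "matrix",
                        bumpAmplitude = "numeric", bumpWidth = "numeric",
                        bumpStructures = "character",
                        vertexNoiseSd = "numeric", subjectScaleSd = "numeric",
                        ageMean = "numeric", ageSd = "numeric",
                        meshSubdivision = "integer",
                        hippocampusAxes = "numeric", ventricleAxes = "numeric",
                        seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (!identical(names(object@groupSizes), .GROUPS))
    return("groupSizes must be named NC, MCI_s, MCI_c, AD (in that order)")
  if (any(object@groupSizes < 0L)) return("group sizes must be >= 0")
  if (sum(object@groupSizes) == 0L) return("at least one group must be non-empty")
  if (!all(dim(object@csfMeans) == c(4L, 3L)) ||
      !all(dim(object@csfSds) == c(4L, 3L)))
    return("csfMeans and csfSds must be 4 groups x 3 markers")
  if (any(object@csfSds <= 0)) return("all CSF SDs must be > 0")
  if (!all(dim(object@csfCorr) == c(3L, 3L)) ||
      !isTRUE(all.equal(object@csfCorr, t(object@csfCorr))))
    return("csfCorr must be a symmetric 3 x 3 matrix")
  if (!all(dim(object@volumeEffect) == c(4L, 2L)))
    return("volumeEffect must be 4 groups x 2 structure classes")
  if (any(object@volumeEffect <= 0)) return("volume scale factors must be > 0")
  if (object@bumpWidth <= 0) return("bump width must be > 0")
  if (object@vertexNoiseSd < 0 || object@subjectScaleSd < 0)
    return("noise SDs must be >= 0")
  if (any(object@ageSd <= 0)) return("age SDs must be > 0")
  if (object@meshSubdivision < 1L) return("meshSubdivision must be >= 1")
  if (any(object@hippocampusAxes <= 0) || any(object@ventricleAxes <= 0))
    return("ellipsoid semi-axes must be positive")
  TRUE
})

setMethod("show", "CohortSpec", function(object) {
  gs <- object@groupSizes
  cat(sprintf("CohortSpec: NC %d, MCI_s %d, MCI_c %d, AD %d (total %d); seed %d\n",
              gs["NC"], gs["MCI_s"], gs["MCI_c"], gs["AD"], sum(gs),
              object@seed))
})

#' ShapeCohort: a simulated (or imported) study cohort
#'
#' Per-subject diagnostic labels, age, CSF triplet, corresponded surface
#' meshes and derived volumes. All meshes of one structure share identical
#' connectivity (atlas correspondence).
#'
#' @slot subjects data.frame with columns subject_id, group, age, abeta42,
#'   t_tau, p_tau.
#' @slot meshes named list (structure tag -> list of SurfaceMesh per subject).
#' @slot volumes numeric matrix, subjects x structures, mm^3.
#' @slot spec the \linkS4class{CohortSpec} that generated the cohort (or NULL).
#' @export
setClass("ShapeCohort",
         representation(subjects = "data.frame", meshes = "list",
                        volumes = "matrix", spec = "ANY"))

setValidity("ShapeCohort", function(object) {
  req <- c("subject_id", "group", "age", .CSF_MARKERS)
  if (!all(req %in% names(object@subjects)))
    return(sprintf("subjects must have columns: %s", paste(req, collapse = ", ")))
  if (!all(object@subjects$group %in% .GROUPS))
    return("unknown diagnostic group label")
  n <- nrow(object@subjects)
  for (tag in names(object@meshes)) {
    ms <- object@meshes[[tag]]
    if (length(ms) != n)
      return(sprintf("structure %s: one mesh per subject required", tag))
    tri0 <- triangles(ms[[1L]])
    for (m in ms)
      if (!identical(triangles(m), tri0))
        return(sprintf("structure %s: connectivity differs across subjects", tag))
  }
  if (length(object@meshes)) {
    if (!all(dim(object@volumes) == c(n, length(object@meshes))))
      return("volumes must be subjects x structures")
    for (tag in names(object@meshes)) {
      v <- vapply(object@meshes[[tag]], meshVolume, numeric(1))
      if (any(abs(v - object@volumes[, tag]) > 1e-6 * (1 + abs(v))))
        return(sprintf("structure %s: stored volumes disagree with meshes", tag))
    }
  }
  TRUE
})

#' @describeIn subjectIds subject ids of a cohort
#' @export
setMethod("subjectIds", "ShapeCohort", function(x) x@subjects$subject_id)

#' Per-subject table of a cohort
#'
#' @param cohort A \linkS4class{ShapeCohort}.
#' @return data.frame with id, group, age and the CSF triplet.
#' @export
subjectTable <- function(cohort) cohort@subjects

#' Diagnostic group labels, optionally collapsed to NC/MCI/AD
#'
#' MCI stable and converter subjects form one baseline MCI diagnostic group;
#' the 4-level labels keep the two-year outcome for conversion analyses.
#'
#' @param cohort A \linkS4class{ShapeCohort}.
#' @param collapseMci collapse MCI_s/MCI_c to MCI (default TRUE).
#' @return Character vector of labels, one per subject.
#' @export
diagnosticGroups <- function(cohort, collapseMci = TRUE) {
  g <- cohort@subjects$group
  if (collapseMci) g[g %in% c("MCI_s", "MCI_c")] <- "MCI"
  g
}

#' Meshes of one structure across the cohort
#'
#' @param cohort A \linkS4class{ShapeCohort}.
#' @param structure structure tag, e.g. "hippocampus_L".
#' @return Named list of \linkS4class{SurfaceMesh}, one per subject.
#' @export
cohortMeshes <- function(cohort, structure) {
  if (!structure %in% names(cohort@meshes))
    stop("cohort has no meshes for structure: ", structure)
  cohort@meshes[[structure]]
}

#' Structure volumes across the cohort
#'
#' @param cohort A \linkS4class{ShapeCohort}.
#' @return Numeric matrix, subjects x structures, mm^3.
#' @export
cohortVolumes <- function(cohort) cohort@volumes

#' One subject's full record
#'
#' @param cohort A \linkS4class{ShapeCohort}.
#' @param i subject index or id.
#' @return List with id, group, age, csf, meshes, volumes.
#' @export
subjectRecord <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort@subjects$subject_id)
  s <- cohort@subjects[i, ]
  list(id = s$subject_id, group = s$group, age = s$age,
       csf = unlist(s[.CSF_MARKERS]),
       meshes = lapply(cohort@meshes, `[[`, i),
       volumes = if (length(cohort@meshes)) cohort@volumes[i, ] else numeric(0))
}

setMethod("show", "ShapeCohort", function(object) {
  tab <- table(factor(object@subjects$group, levels = .GROUPS))
  cat(sprintf("ShapeCohort: %d subjects (NC %d, MCI_s %d, MCI_c %d, AD %d)\n",
              nrow(object@subjects), tab["NC"], tab["MCI_s"], tab["MCI_c"],
              tab["AD"]))
  if (length(object@meshes))
    cat(sprintf("  structures: %s\n", paste(names(object@meshes), collapse = ", ")))
})

#' SelectionResult: t-test feature screening for one group contrast
#'
#' @slot contrast ordered pair of group labels.
#' @slot statistic,pValue named per-feature pooled-variance Student t and
#'   two-tailed p.
#' @slot selected indices (into the tested features) with p < alpha.
#' @slot alpha significance level used.
#' @export
setClass("SelectionResult",
         representation(contrast = "character", statistic = "numeric",
                        pValue = "numeric", selected = "integer",
                        alpha = "numeric"))

setValidity("SelectionResult", function(object) {
  if (length(object@contrast) != 2L) return("contrast must name two groups")
  if (length(object@statistic) != length(object@pValue))
    return("statistic and pValue must align")
  if (any(object@pValue < 0 | object@pValue > 1, na.rm = TRUE))
    return("p-values must lie in [0, 1]")
  if (length(object@selected) &&
      (min(object@selected) < 1L || max(object@selected) > length(object@pValue)))
    return("selected indices out of range")
  TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s vs %s], alpha = %g: %d/%d selected%s\n",
              object@contrast[1], object@contrast[2], object@alpha,
              length(object@selected), length(object@pValue),
              if (length(object@selected))
                paste0(" (", paste(names(object@pValue)[object@selected],
                                   collapse = ", "), ")")
              else ""))
})

#' Indices selected by a feature screen
#'
#' @param x A \linkS4class{SelectionResult}.
#' @return Integer indices of features with p below the screen's alpha.
#' @export
selectedFeatures <- function(x) x@selected

#' FeatureSet: a classifier input matrix
#'
#' @slot name one of the marker-set names (Hp/LV volumes or shapes, CSF and
#'   combinations).
#' @slot matrix numeric subjects x features matrix, z-scored.
#' @slot featureNames column labels.
#' @export
setClass("FeatureSet",
         representation(name = "character", matrix = "matrix",
                        featureNames = "character"))

setValidity("FeatureSet", function(object) {
  if (any(!is.finite(object@matrix))) return("feature matrix has missing values")
  if (length(object@featureNames) != ncol(object@matrix))
    return("featureNames must match matrix columns")
  if (is.null(rownames(object@matrix)))
    return("feature matrix rows must be named by subject id")
  TRUE
})

#' @describeIn subjectIds subject ids of a feature set
#' @export
setMethod("subjectIds", "FeatureSet", function(x) rownames(x@matrix))

#' Feature matrix of a FeatureSet
#'
#' @param x A \linkS4class{FeatureSet}.
#' @return Numeric subjects x features matrix.
#' @export
featureMatrix <- function(x) x@matrix

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet '%s': %d subjects x %d features (%s)\n",
              object@name, nrow(object@matrix), ncol(object@matrix),
              paste(object@featureNames, collapse = ", ")))
})

#' ClassifierReport: one marker set x one contrast evaluation
#'
#' Mean accuracy/sensitivity/specificity over balanced-subsample trials with
#' the 95\% confidence interval of the mean accuracy (one report corresponds
#' to one cell of a classification table).
#'
#' @slot contrast ordered group pair; sensitivity refers to the more impaired
#'   group.
#' @slot featureSet marker-set name.
#' @slot accuracy,ciLow,ciHigh,sensitivity,specificity proportions in [0, 1].
#' @slot nTrials,seed evaluation protocol bookkeeping.
#' @slot trials numeric matrix (trial x accuracy/sensitivity/specificity)
#'   kept for paired classifier comparisons.
#' @export
setClass("ClassifierReport",
         representation(contrast = "character", featureSet = "character",
                        accuracy = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", sensitivity = "numeric",
                        specificity = "numeric", nTrials = "integer",
                        seed = "integer", trials = "matrix"))

setValidity("ClassifierReport", function(object) {
  p <- c(object@accuracy, object@sensitivity, object@specificity,
         object@ciLow, object@ciHigh)
  if (any(p < -1e-12 | p > 1 + 1e-12)) return("proportions must lie in [0, 1]")
  if (object@ciLow > object@accuracy + 1e-12 ||
      object@ciHigh < object@accuracy - 1e-12)
    return("confidence interval must contain the mean accuracy")
  TRUE
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf(
    "ClassifierReport [%s vs %s | %s]: %.1f%% (CI: %.1f%%~%.1f%%), sens %.1f%%, spec %.1f%% (%d trials)\n",
    object@contrast[1], object@contrast[2], object@featureSet,
    100 * object@accuracy, 100 * object@ciLow, 100 * object@ciHigh,
    100 * object@sensitivity, 100 * object@specificity, object@nTrials))
})

#' Per-trial accuracies of a classifier evaluation
#'
#' @param x A \linkS4class{ClassifierReport} or
#'   \linkS4class{ConversionReport}.
#' @return Numeric vector of per-trial accuracies (paired by trial seed).
#' @export
trialAccuracies <- function(x) x@trials[, "accuracy"]

#' ConversionReport: MCI-to-AD conversion prediction summary
#'
#' @slot featureSet marker-set name.
#' @slot accuracy,ciLow,ciHigh overall correct fraction over MCI subjects.
#' @slot sensitivity fraction of converters predicted AD-like.
#' @slot specificity fraction of non-converters predicted NC-like.
#' @slot nConverters,nNonconverters MCI split of the cohort.
#' @slot nTrials,seed protocol bookkeeping.
#' @slot trials per-trial accuracy/sensitivity/specificity matrix.
#' @export
setClass("ConversionReport",
         representation(featureSet = "character", accuracy = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        sensitivity = "numeric", specificity = "numeric",
                        nConverters = "integer", nNonconverters = "integer",
                        nTrials = "integer", seed = "integer",
                        trials = "matrix"))

setValidity("ConversionReport", function(object) {
  p <- c(object@accuracy, object@sensitivity, object@specificity)
  if (any(p < -1e-12 | p > 1 + 1e-12)) return("proportions must lie in [0, 1]")
  TRUE
})

setMethod("show", "ConversionReport", function(object) {
  cat(sprintf(
    "ConversionReport [%s]: accuracy %.1f%% (CI: %.1f%%~%.1f%%), sens %.1f%%, spec %.1f%% (%d converters / %d non-converters)\n",
    object@featureSet, 100 * object@accuracy, 100 * object@ciLow,
    100 * object@ciHigh, 100 * object@sensitivity, 100 * object@specificity,
    object@nConverters, object@nNonconverters))
})

#' DeformationMap: vertex-wise signed group shape difference
#'
#' Signed normal displacement between two group mean surfaces on the atlas
#' vertices: positive = outward deformation in the first-named group relative
#' to the second, with a per-vertex pooled-t statistic and two-tailed p.
#'
#' @slot displacement numeric per-vertex signed displacement, mm.
#' @slot statistic numeric per-vertex Student t.
#' @slot pValue numeric per-vertex two-tailed p (NA where variance degenerate).
#' @slot contrast ordered pair of group labels (former, latter).
#' @slot structureTag structure the map lives on.
#' @export
setClass("DeformationMap",
         representation(displacement = "numeric", statistic = "numeric",
                        pValue = "numeric", contrast = "character",
                        structureTag = "character"))

setValidity("DeformationMap", function(object) {
  n <- length(object@displacement)
  if (length(object@statistic) != n || length(object@pValue) != n)
    return("displacement, statistic and pValue must have one value per vertex")
  if (length(object@contrast) != 2L) return("contrast must name two groups")
  TRUE
})

setMethod("show", "DeformationMap", function(object) {
  cat(sprintf(
    "DeformationMap [%s vs %s, %s]: %d vertices; displacement %.3g .. %.3g mm\n",
    object@contrast[1], object@contrast[2], object@structureTag,
    length(object@displacement), min(object@displacement),
    max(object@displacement)))
})
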