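## Synthetic cohort generator. Produces SubjectRecords with the statistical
## structure the downstream analysis assumes: group-dependent CSF
## distributions, global structure-volume effects shared by the impaired
## groups, and a volume-neutral localized shape deformation that separates
## MCI converters / AD from stable MCI without touching volume.

.icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  V <- V / sqrt(rowSums(V^2))
  Tm <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(V = V, T = Tm)
}

.subdivideSphere <- function(V, Tm) {
  nV <- nrow(V)
  env <- new.env(hash = TRUE)
  verts <- vector("list", nrow(Tm) * 3L)
  nNew <- 0L
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- env[[key]]
    if (!is.null(hit)) return(hit)
    nNew <<- nNew + 1L
    m <- V[i, ] + V[j, ]
    verts[[nNew]] <<- m / sqrt(sum(m^2))
    env[[key]] <- nV + nNew
    nV + nNew
  }
  newT <- matrix(0L, nrow(Tm) * 4L, 3L)
  for (f in seq_len(nrow(Tm))) {
    a <- Tm[f, 1L]; b <- Tm[f, 2L]; c <- Tm[f, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newT[4L * f - 3L, ] <- c(a, ab, ca)
    newT[4L * f - 2L, ] <- c(b, bc, ab)
    newT[4L * f - 1L, ] <- c(c, ca, bc)
    newT[4L * f, ] <- c(ab, bc, ca)
  }
  list(V = rbind(V, do.call(rbind, verts[seq_len(nNew)])), T = newT)
}

#' Generate a closed genus-0 ellipsoidal base mesh
#'
#' Subdivided icosahedron projected to the unit sphere, then scaled to the
#' requested semi-axes. Deterministic for fixed arguments; triangles are
#' wound consistently outward. The vertex count is 10 * 4^s + 2 at
#' subdivision s.
#'
#' @param subdivision subdivision level, >= 1.
#' @param semiAxes ellipsoid semi-axes in mm (length 3, all > 0).
#' @param structureTag tag attached to the mesh.
#' @return A \linkS4class{SurfaceMesh}.
#' @examples
#' m <- generateBaseMesh(2)
#' nrow(vertices(m))  # 162
#' @export
generateBaseMesh <- function(subdivision, semiAxes = c(1, 1, 1),
                             structureTag = "synthetic") {
  if (length(subdivision) != 1L || subdivision < 1 ||
      subdivision != round(subdivision))
    stop("subdivision must be an integer >= 1", call. = FALSE)
  if (length(semiAxes) != 3L || any(semiAxes <= 0))
    stop("semiAxes must be three positive lengths (mm)", call. = FALSE)
  ico <- .icosahedron()
  for (i in seq_len(subdivision)) ico <- .subdivideSphere(ico$V, ico$T)
  V <- sweep(ico$V, 2L, semiAxes, `*`)
  m <- surfaceMesh(V, ico$T, structureTag = structureTag)
  # enforce outward winding (positive signed volume)
  sv <- {
    tri <- m@triangles
    v1 <- V[tri[, 1], ]; v2 <- V[tri[, 2], ]; v3 <- V[tri[, 3], ]
    sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
        v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
        v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  }
  if (sv < 0)
    m <- surfaceMesh(V, ico$T[, c(1L, 3L, 2L)], structureTag = structureTag)
  m
}

#' Deform a mesh: global scaling, localized bumps, vertex jitter
#'
#' Vertices are scaled about the centroid by \code{globalScale}, then
#' displaced along their outward normals by Gaussian-profile bumps
#' (amplitude * exp(-theta^2 / (2 width^2)), theta the angle from the bump
#' center seen from the centroid), then perturbed by i.i.d. Gaussian jitter.
#' Connectivity is untouched, so atlas correspondence is preserved.
#'
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @param globalScale linear scale factor about the centroid.
#' @param bumps list of bumps, each \code{list(center = vertex index,
#'   amplitude = mm, width = radians)}; negative amplitude deforms inward.
#' @param noiseSd sd of the per-coordinate vertex jitter, mm.
#' @param seed optional integer; when given the jitter is drawn in a private
#'   RNG stream, leaving the caller's RNG state untouched.
#' @return A deformed \linkS4class{SurfaceMesh} (same connectivity).
#' @export
applyDeformation <- function(mesh, globalScale = 1, bumps = list(),
                             noiseSd = 0, seed = NULL) {
  stopifnot(is(mesh, "SurfaceMesh"))
  V <- mesh@vertices
  ctr <- colMeans(V)
  X <- sweep(sweep(V, 2L, ctr), 1L, rep(globalScale, nrow(V)), `*`)
  X <- sweep(X, 2L, ctr, `+`)
  if (length(bumps)) {
    scaled <- surfaceMesh(X, mesh@triangles, mesh@structureTag,
                          validate = FALSE)
    N <- vertexNormals(scaled)
    dirs <- sweep(X, 2L, colMeans(X))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    for (b in bumps) {
      if (is.null(b$center) || b$center < 1 || b$center > nrow(V))
        stop("bump center vertex out of range", call. = FALSE)
      if (is.null(b$width) || b$width <= 0)
        stop("bump width must be > 0", call. = FALSE)
      cosang <- pmin(1, pmax(-1, drop(dirs %*% dirs[b$center, ])))
      theta <- acos(cosang)
      profile <- b$amplitude * exp(-theta^2 / (2 * b$width^2))
      X <- X + profile * N
    }
  }
  if (noiseSd > 0) {
    draw <- function() matrix(stats::rnorm(length(X), 0, noiseSd),
                              nrow(X), 3L)
    X <- X + if (is.null(seed)) draw() else withSeed(seed, draw())
  }
  surfaceMesh(X, mesh@triangles, mesh@structureTag, validate = FALSE)
}

#' Default synthetic cohort specification
#'
#' The study conditions the generator emulates: group sizes NC 72, MCI-s 86,
#' MCI-c 25, AD 35; CSF distributions with all three markers shifted in MCI
#' and AD relative to NC but tau measures plateauing by MCI so that only
#' Abeta42 separates MCI from AD; hippocampal shrinkage and ventricular
#' expansion shared by the MCI and AD groups; and a volume-neutral paired
#' outward/inward hippocampal bump carried by AD and MCI converters only.
#' MCI converters draw their CSF from the AD distribution, stable MCI from
#' the (intermediate) MCI distribution, so baseline markers carry conversion
#' signal.
#'
#' @param seed master seed for the cohort.
#' @param ... named CohortSpec slots to override (see \code{\link{cohortSpec}}).
#' @return A \linkS4class{CohortSpec}.
#' @export
defaultCohortSpec <- function(seed = 1L, ...) {
  cohortSpec(seed = seed, ...)
}

#' Construct a cohort specification
#'
#' All arguments default to the study conditions described in
#' \code{\link{defaultCohortSpec}}. CSF parameters are in pg/mL; the marker
#' order is (abeta42, t_tau, p_tau) and the group order (NC, MCI_s, MCI_c,
#' AD). MCI_c rows default to the AD distribution.
#'
#' @param groupSizes named counts for NC, MCI_s, MCI_c, AD.
#' @param csfMeans,csfSds 4 x 3 matrices, groups x markers.
#' @param csfCorr 3 x 3 within-subject marker correlation (t-tau and p-tau
#'   are strongly correlated in CSF assays).
#' @param volumeEffect 4 x 2 matrix of linear scale factors, groups x
#'   c(hippocampus, ventricle).
#' @param bumpAmplitude named per-group bump amplitude, mm.
#' @param bumpWidth angular bump width, radians.
#' @param bumpStructures structures carrying the paired bumps.
#' @param vertexNoiseSd i.i.d. vertex jitter sd, mm (default 0: corresponded
#'   atlas-injected surfaces are smooth by construction).
#' @param subjectScaleSd sd of per-subject lognormal size jitter.
#' @param ageMean,ageSd per-group age distributions, years.
#' @param meshSubdivision icosphere subdivision of the base meshes.
#' @param hippocampusAxes,ventricleAxes ellipsoid semi-axes, mm.
#' @param seed master seed.
#' @return A validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(groupSizes = c(NC = 72L, MCI_s = 86L, MCI_c = 25L,
                                      AD = 35L),
                       csfMeans = NULL, csfSds = NULL, csfCorr = NULL,
                       volumeEffect = NULL,
                       bumpAmplitude = c(NC = 0, MCI_s = 0, MCI_c = 0.6,
                                         AD = 0.6),
                       bumpWidth = 0.6,
                       bumpStructures = c("hippocampus_L", "hippocampus_R"),
                       vertexNoiseSd = 0, subjectScaleSd = 0.05,
                       ageMean = c(NC = 75.2, MCI_s = 74, MCI_c = 73.5,
                                   AD = 74.6),
                       ageSd = c(NC = 5.2, MCI_s = 7.7, MCI_c = 6.9,
                                 AD = 9.3),
                       meshSubdivision = 2L,
                       hippocampusAxes = c(17.5, 8, 6),
                       ventricleAxes = c(30, 15, 10.6),
                       seed = 1L) {
  if (is.null(csfMeans))
    csfMeans <- rbind(NC    = c(205, 70, 25),
                      MCI_s = c(170, 115, 38),
                      MCI_c = c(115, 115, 38),
                      AD    = c(115, 115, 38))
  if (is.null(csfSds))
    csfSds <- rbind(NC    = c(55, 30, 10),
                    MCI_s = c(50, 45, 13),
                    MCI_c = c(45, 45, 13),
                    AD    = c(45, 45, 13))
  if (is.null(csfCorr))
    csfCorr <- rbind(c(1, -0.15, -0.15),
                     c(-0.15, 1, 0.95),
                     c(-0.15, 0.95, 1))
  if (is.null(volumeEffect))
    volumeEffect <- rbind(NC    = c(1, 1),
                          MCI_s = c(0.95, 1.06),
                          MCI_c = c(0.95, 1.06),
                          AD    = c(0.95, 1.06))
  dimnames(csfMeans) <- dimnames(csfSds) <- list(.GROUPS, .CSF_MARKERS)
  dimnames(csfCorr) <- list(.CSF_MARKERS, .CSF_MARKERS)
  dimnames(volumeEffect) <- list(.GROUPS, c("hippocampus", "ventricle"))
  # unnamed length-4 vectors (e.g. from JSON configs) follow the group order
  byGroup <- function(x) {
    if (is.null(names(x))) stats::setNames(x, .GROUPS) else x[.GROUPS]
  }
  groupSizes <- byGroup(groupSizes)
  bumpAmplitude <- byGroup(bumpAmplitude)
  ageMean <- byGroup(ageMean)
  ageSd <- byGroup(ageSd)
  gs <- as.integer(groupSizes)
  names(gs) <- .GROUPS
  obj <- new("CohortSpec", groupSizes = gs,
             csfMeans = csfMeans, csfSds = csfSds, csfCorr = csfCorr,
             volumeEffect = volumeEffect,
             bumpAmplitude = bumpAmplitude[.GROUPS],
             bumpWidth = bumpWidth, bumpStructures = bumpStructures,
             vertexNoiseSd = vertexNoiseSd, subjectScaleSd = subjectScaleSd,
             ageMean = ageMean[.GROUPS], ageSd = ageSd[.GROUPS],
             meshSubdivision = as.integer(meshSubdivision),
             hippocampusAxes = hippocampusAxes,
             ventricleAxes = ventricleAxes, seed = as.integer(seed))
  validObject(obj)
  obj
}

.structureClass <- function(tag) {
  ifelse(grepl("^hippocampus", tag), "hippocampus", "ventricle")
}

## antipodal paired bump centers: the +x apex and its antipode, chosen on the
## unit-sphere parameterization so the outward and inward bump profiles are
## mirror images and the net enclosed-volume change cancels by symmetry
.bumpCenters <- function(base) {
  dirs <- sweep(vertices(base), 2L, colMeans(vertices(base)))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  c1 <- which.max(dirs[, 1L])
  c2 <- which.min(drop(dirs %*% dirs[c1, ]))
  c(c1, c2)
}

#' Generate a synthetic cohort of subject records
#'
#' Draws each subject from a private RNG substream derived from the master
#' seed, so records are reproducible and adding a subject never perturbs the
#' others. CSF triplets come from per-group correlated Gaussians; meshes are
#' produced by \code{\link{applyDeformation}} with the group's volume scale,
#' a per-subject lognormal size jitter, the group's paired volume-neutral
#' bumps and optional vertex noise.
#'
#' @param spec A \linkS4class{CohortSpec}.
#' @param structures structure tags to generate meshes for; defaults to both
#'   hippocampi and both ventricles. Pass \code{character(0)} for a
#'   CSF/label-only cohort (fast, no meshes).
#' @return A validated \linkS4class{ShapeCohort}.
#' @examples
#' co <- generateCohort(defaultCohortSpec(seed = 7), structures = character(0))
#' table(subjectTable(co)$group)
#' @export
generateCohort <- function(spec,
                           structures = c("hippocampus_L", "hippocampus_R",
                                          "ventricle_L", "ventricle_R")) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  gs <- spec@groupSizes
  n <- sum(gs)
  groups <- rep(names(gs), gs)
  ids <- sprintf("S%03d", seq_len(n))
  csfChol <- chol(spec@csfCorr)

  bases <- list()
  centers <- list()
  for (tag in structures) {
    cls <- .structureClass(tag)
    axes <- if (cls == "hippocampus") spec@hippocampusAxes else spec@ventricleAxes
    if (is.null(bases[[cls]])) {
      bases[[cls]] <- generateBaseMesh(spec@meshSubdivision, axes,
                                       structureTag = tag)
      centers[[cls]] <- .bumpCenters(bases[[cls]])
    }
  }

  age <- numeric(n)
  csf <- matrix(0, n, 3L, dimnames = list(NULL, .CSF_MARKERS))
  meshes <- stats::setNames(
    replicate(length(structures), vector("list", n), simplify = FALSE),
    structures)

  for (i in seq_len(n)) {
    g <- groups[i]
    withSeed(.subjectSeed(spec@seed, i), {
      age[i] <- stats::rnorm(1, spec@ageMean[g], spec@ageSd[g])
      z <- drop(stats::rnorm(3) %*% csfChol)
      csf[i, ] <- spec@csfMeans[g, ] + z * spec@csfSds[g, ]
      sscale <- exp(stats::rnorm(1, 0, spec@subjectScaleSd))
      for (tag in structures) {
        cls <- .structureClass(tag)
        amp <- spec@bumpAmplitude[g]
        bumps <- if (tag %in% spec@bumpStructures && amp != 0) {
          cc <- centers[[cls]]
          list(list(center = cc[1], amplitude = amp, width = spec@bumpWidth),
               list(center = cc[2], amplitude = -amp, width = spec@bumpWidth))
        } else list()
        base <- bases[[cls]]
        m <- applyDeformation(base,
                              globalScale = spec@volumeEffect[g, cls] * sscale,
                              bumps = bumps,
                              noiseSd = spec@vertexNoiseSd)
        m@structureTag <- tag
        meshes[[tag]][[i]] <- m
      }
    })
  }

  subjects <- data.frame(subject_id = ids, group = groups, age = age,
                         csf, stringsAsFactors = FALSE)
  vols <- if (length(structures)) {
    vapply(structures,
           function(tag) vapply(meshes[[tag]], meshVolume, numeric(1)),
           numeric(n))
  } else matrix(numeric(0), n, 0L)
  if (length(structures)) {
    dimnames(vols) <- list(ids, structures)
    for (tag in structures) names(meshes[[tag]]) <- ids
  }
  obj <- new("ShapeCohort", subjects = subjects,
             meshes = meshes[structures], volumes = vols, spec = spec)
  validObject(obj)
  obj
}

#' Write the cohort manifest (and optionally meshes) to disk
#'
#' The manifest is a CSV with columns subject_id, group, age, abeta42,
#' t_tau, p_tau plus one volume column per structure; meshes go to
#' \code{<subject_id>_<structure_tag>.off} next to it when requested.
#'
#' @param cohort A \linkS4class{ShapeCohort}.
#' @param dir output directory (created if needed).
#' @param writeMeshes also write one OFF file per subject per structure.
#' @return Invisibly, the manifest path.
#' @export
writeCohortManifest <- function(cohort, dir, writeMeshes = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- cohort@subjects
  if (ncol(cohort@volumes)) {
    vols <- as.data.frame(cohort@volumes)
    names(vols) <- paste0("volume_", names(vols))
    df <- cbind(df, vols)
  }
  manifest <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(df, manifest, row.names = FALSE)
  if (writeMeshes) {
    for (tag in names(cohort@meshes))
      for (id in names(cohort@meshes[[tag]]))
        writeMesh(cohort@meshes[[tag]][[id]],
                  file.path(dir, sprintf("%s_%s.off", id, tag)))
  }
  invisible(manifest)
}
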