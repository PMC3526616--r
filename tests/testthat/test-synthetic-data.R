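test_that("base meshes follow the icosphere vertex-count formula and converge to the ellipsoid", {
  for (s in 1:3) {
    m <- generateBaseMesh(s)
    expect_identical(nrow(vertices(m)), as.integer(10 * 4^s + 2))
    expect_identical(eulerCharacteristic(m), 2L)
  }
  expect_equal(meshVolume(generateBaseMesh(4)), 4 * pi / 3, tolerance = 5e-3)
  expect_error(generateBaseMesh(0), "subdivision")
  expect_error(generateBaseMesh(2, c(1, -1, 1)), "positive")
  # deterministic for fixed arguments
  expect_identical(vertices(generateBaseMesh(2, c(3, 2, 1))),
                   vertices(generateBaseMesh(2, c(3, 2, 1))))
})

test_that("applyDeformation is the identity at neutral settings and obeys the scaling law", {
  m <- generateBaseMesh(2, c(17.5, 8, 6))
  expect_equal(vertices(applyDeformation(m)), vertices(m), tolerance = 1e-14)
  for (s in c(0.9, 1.2)) {
    ms <- applyDeformation(m, globalScale = s)
    expect_equal(meshVolume(ms), s^3 * meshVolume(m), tolerance = 1e-9)
    expect_identical(triangles(ms), triangles(m))
  }
})

test_that("a single bump displaces the center vertex by exactly its amplitude", {
  m <- generateBaseMesh(2, c(17.5, 8, 6))
  a <- 0.7
  mb <- applyDeformation(m, bumps = list(list(center = 11, amplitude = a,
                                              width = 0.5)))
  disp <- sqrt(rowSums((vertices(mb) - vertices(m))^2))
  expect_equal(max(disp), a, tolerance = 1e-9)
  expect_identical(which.max(disp), 11L)
  expect_error(applyDeformation(m, bumps = list(list(center = 0, amplitude = 1,
                                                     width = 0.5))),
               "out of range")
  expect_error(applyDeformation(m, bumps = list(list(center = 1, amplitude = 1,
                                                     width = 0))),
               "width")
})

test_that("seeded jitter is reproducible and leaves the caller's RNG stream untouched", {
  m <- generateBaseMesh(1)
  a <- applyDeformation(m, noiseSd = 0.1, seed = 7)
  b <- applyDeformation(m, noiseSd = 0.1, seed = 7)
  expect_identical(vertices(a), vertices(b))
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(applyDeformation(m, noiseSd = 0.1, seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("the default cohort reproduces the study composition and is seed-reproducible", {
  co <- generateCohort(defaultCohortSpec(seed = 5), structures = character(0))
  tab <- table(subjectTable(co)$group)
  expect_identical(as.integer(tab[c("NC", "MCI_s", "MCI_c", "AD")]),
                   c(72L, 86L, 25L, 35L))
  expect_identical(nrow(subjectTable(co)), 218L)
  expect_identical(sum(diagnosticGroups(co) == "MCI"), 111L)

  co2 <- generateCohort(defaultCohortSpec(seed = 5), structures = character(0))
  expect_identical(subjectTable(co), subjectTable(co2))
  expect_error(generateCohort(cohortSpec(groupSizes = c(NC = 0, MCI_s = 0,
                                                        MCI_c = 0, AD = 0))),
               "non-empty")
})

test_that("generated meshes share connectivity and per-subject streams are stable under cohort growth", {
  spec <- defaultCohortSpec(seed = 9,
                            groupSizes = c(NC = 6, MCI_s = 5, MCI_c = 3, AD = 4))
  co <- generateCohort(spec, structures = c("hippocampus_L", "ventricle_R"))
  msL <- cohortMeshes(co, "hippocampus_L")
  for (m in msL) expect_identical(triangles(m), triangles(msL[[1]]))
  expect_equal(unname(cohortVolumes(co)[3, "hippocampus_L"]),
               meshVolume(msL[[3]]), tolerance = 1e-9)
  # growing a group appends subjects without perturbing records before it
  spec2 <- defaultCohortSpec(seed = 9,
                             groupSizes = c(NC = 6, MCI_s = 5, MCI_c = 3,
                                            AD = 7))
  co2 <- generateCohort(spec2, structures = c("hippocampus_L", "ventricle_R"))
  expect_identical(subjectTable(co)[1:18, ], subjectTable(co2)[1:18, ])
  expect_identical(vertices(cohortMeshes(co2, "hippocampus_L")[[10]]),
                   vertices(msL[[10]]))
})

test_that("the planted MCI-vs-AD bump is volume-orthogonal", {
  co <- generateCohort(defaultCohortSpec(seed = 3, subjectScaleSd = 1e-9),
                      structures = "hippocampus_L")
  v <- cohortVolumes(co)[, 1]
  g <- diagnosticGroups(co)
  expect_lt(abs(mean(v[g == "AD"]) - mean(v[g == "MCI"])) / mean(v[g == "MCI"]),
            0.01)
})

test_that("with all effects zero, group volume differences are pure sampling noise", {
  pvals <- vapply(1:40, function(r) {
    co <- generateCohort(nullEffectSpec(700 + r,
                                        groupSizes = c(NC = 12, MCI_s = 1,
                                                       MCI_c = 1, AD = 12),
                                        meshSubdivision = 1),
                         structures = "hippocampus_L")
    v <- cohortVolumes(co)[, 1]
    g <- diagnosticGroups(co)
    twoSampleT(v[g == "NC"], v[g == "AD"])$p.value
  }, numeric(1))
  # null p-values are uniform: KS against U(0,1) and unbiased rejection rate
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.2)
})

test_that("the default cohort plants the CSF marker pattern: all three markers for NC contrasts, Abeta42 alone for MCI vs AD", {
  hits <- vapply(1:100, function(r) {
    co <- generateCohort(defaultCohortSpec(seed = 1000 + r),
                         structures = character(0))
    identical(unname(selectedFeatures(selectCsfMarkers(co, c("NC", "AD")))), 1:3) &&
      identical(unname(selectedFeatures(selectCsfMarkers(co, c("NC", "MCI")))), 1:3) &&
      identical(unname(selectedFeatures(selectCsfMarkers(co, c("MCI", "AD")))), 1L)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the cohort manifest round-trips subject data and optionally writes meshes", {
  co <- generateCohort(defaultCohortSpec(
    seed = 2, groupSizes = c(NC = 3, MCI_s = 2, MCI_c = 2, AD = 2),
    meshSubdivision = 1), structures = "hippocampus_L")
  dir <- withr::local_tempdir()
  writeCohortManifest(co, dir, writeMeshes = TRUE)
  df <- read.csv(file.path(dir, "cohort_manifest.csv"))
  expect_identical(nrow(df), 9L)
  expect_true(all(c("subject_id", "group", "abeta42", "t_tau", "p_tau",
                    "volume_hippocampus_L") %in% names(df)))
  m <- readMesh(file.path(dir, "S001_hippocampus_L.off"))
  expect_identical(triangles(m), triangles(cohortMeshes(co, "hippocampus_L")[[1]]))
})
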