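test_that("OFF and PLY files round-trip meshes bit-identically in vertex order", {
  tet <- tetrahedronMesh()
  off <- withr::local_tempfile(fileext = ".off")
  writeMesh(tet, off)
  hdr <- readLines(off, n = 2)
  expect_identical(hdr[1], "OFF")
  expect_identical(hdr[2], "4 4 0")
  back <- readMesh(off)
  expect_identical(triangles(back), triangles(tet))
  expect_equal(vertices(back), vertices(tet), tolerance = 1e-9)

  ico <- generateBaseMesh(2, c(3, 2, 1))
  ply <- withr::local_tempfile(fileext = ".ply")
  writeMesh(ico, ply)
  back2 <- readMesh(ply)
  expect_identical(triangles(back2), triangles(ico))
  expect_equal(vertices(back2), vertices(ico), tolerance = 1e-8)

  # second round trip is the identity on the serialized values
  off2 <- withr::local_tempfile(fileext = ".off")
  writeMesh(back, off2)
  expect_identical(readLines(off), readLines(off2))
})

test_that("mesh readers reject malformed and non-manifold files informatively", {
  bad <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 0",
               "0 0 zero", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 1 2 3", "3 0 3 2"), bad)
  expect_error(readMesh(bad), "line 3")

  # a face referencing vertex index V (0-based) is out of range
  oob <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 0",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 1 2", "3 0 3 1", "3 0 2 3", "3 1 3 4"), oob)
  expect_error(readMesh(oob), "vertex index")

  # open surface (one face dropped): every edge must be shared by 2 faces
  open <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 3 0",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 1 2 3"), open)
  expect_error(readMesh(open), "2 triangles")

  expect_error(readMesh(withr::local_tempfile(fileext = ".off")), "not found")
  expect_error(writeMesh(tetrahedronMesh(),
                         file.path(tempdir(), "noext.xyz"), "auto"),
               "format")
})

test_that("writeMesh refuses degenerate output and surfaceMesh validates geometry", {
  tet <- tetrahedronMesh()
  expect_error(surfaceMesh(matrix(0, 0, 3), matrix(integer(0), 0, 3)),
               "triangles")
  empty <- surfaceMesh(matrix(0, 0, 3), matrix(integer(0), 0, 3),
                       validate = FALSE)
  expect_error(writeMesh(empty, tempfile(fileext = ".off")), "empty")
  expect_error(surfaceMesh(vertices(tet), rbind(c(1, 1, 2))), "repeated")
  V <- rbind(vertices(tet), c(1, 1, 1) + 1e-14)  # coincident -> zero area
  expect_error(surfaceMesh(V, rbind(triangles(tet), c(1, 5, 2))),
               "area|degenerate|manifold")
  # flipping one face breaks orientation consistency
  T2 <- triangles(tet)
  T2[1, ] <- T2[1, c(1, 3, 2)]
  expect_error(surfaceMesh(vertices(tet), T2), "orientation")
})

test_that("Euler characteristic is V - E + F and additive over components", {
  expect_identical(eulerCharacteristic(tetrahedronMesh()), 2L)
  expect_identical(eulerCharacteristic(cubeMesh()), 2L)
  expect_identical(eulerCharacteristic(twoTetrahedraMesh()), 4L)
})

test_that("closed genus-0 triangulations satisfy F = 2V - 4, matching the printed atlas specifications", {
  # printed (vertices, triangles) pairs of the four atlas surfaces
  expect_identical(closedTriangulationFaceCount(1184), 2364L)
  expect_identical(closedTriangulationFaceCount(1231), 2458L)
  expect_identical(closedTriangulationFaceCount(3485), 6966L)
  expect_identical(closedTriangulationFaceCount(3947), 7890L)
  expect_identical(closedTriangulationFaceCount(4), 4L)
  expect_error(closedTriangulationFaceCount(3), ">= 4")
  # with E = 3F/2, chi = V - E + F = 2 for all four printed pairs
  for (v in c(1184, 1231, 3485, 3947)) {
    f <- closedTriangulationFaceCount(v)
    expect_identical(v - 3 * f / 2 + f, 2)
  }
})

test_that("mesh volume is exact on the cube, converges on the sphere, and respects rigid motion and scaling", {
  expect_equal(meshVolume(cubeMesh()), 1, tolerance = 1e-12)

  sph <- generateBaseMesh(4, c(10, 10, 10))
  expect_equal(meshVolume(sph), 4 / 3 * pi * 1000, tolerance = 5e-3)

  m <- generateBaseMesh(2, c(3, 2, 1))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- surfaceMesh(vertices(m) %*% t(R) + rep(c(5, -2, 1), each = nrow(vertices(m))),
                       triangles(m))
  expect_equal(meshVolume(moved), meshVolume(m), tolerance = 1e-9)
  for (s in c(0.5, 2, 3.7)) {
    scaled <- surfaceMesh(vertices(m) * s, triangles(m))
    expect_equal(meshVolume(scaled), s^3 * meshVolume(m), tolerance = 1e-9)
  }
  # orientation-independence: reversing all windings leaves |volume| unchanged
  flipped <- surfaceMesh(vertices(m), triangles(m)[, c(1, 3, 2)])
  expect_equal(meshVolume(flipped), meshVolume(m), tolerance = 1e-12)

  open <- surfaceMesh(vertices(m), triangles(m)[-1, , drop = FALSE],
                      validate = FALSE)
  expect_error(meshVolume(open), "closed")
})

test_that("mesh statistics equal a brute-force loop and follow the scaling law", {
  tet <- tetrahedronMesh(1 / (2 * sqrt(2)))  # unit edge length
  st <- meshStatistics(tet)
  expect_equal(st$meanEdgeLength, 1, tolerance = 1e-12)
  expect_equal(st$meanTriangleArea, sqrt(3) / 4, tolerance = 1e-12)

  m <- generateBaseMesh(2, c(4, 3, 2))
  st <- meshStatistics(m)
  # independent summation oracle
  V <- vertices(m); T <- triangles(m)
  areas <- numeric(nrow(T))
  for (f in seq_len(nrow(T))) {
    a <- V[T[f, 2], ] - V[T[f, 1], ]
    b <- V[T[f, 3], ] - V[T[f, 1], ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    areas[f] <- 0.5 * sqrt(sum(cr^2))
  }
  seen <- character(0); lens <- numeric(0)
  for (f in seq_len(nrow(T))) for (e in list(1:2, 2:3, c(3, 1))) {
    key <- paste(sort(T[f, e]), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      lens <- c(lens, sqrt(sum((V[T[f, e[1]], ] - V[T[f, e[2]], ])^2)))
    }
  }
  expect_equal(st$meanTriangleArea, mean(areas), tolerance = 1e-12)
  expect_equal(st$meanEdgeLength, mean(lens), tolerance = 1e-12)

  s <- 2.5
  st2 <- meshStatistics(surfaceMesh(V * s, T))
  expect_equal(st2$meanTriangleArea, s^2 * st$meanTriangleArea, tolerance = 1e-12)
  expect_equal(st2$meanEdgeLength, s * st$meanEdgeLength, tolerance = 1e-12)
})

test_that("every generated closed mesh satisfies 3F = 2E and chi = 2", {
  for (s in 1:3) for (axes in list(c(1, 1, 1), c(17.5, 8, 6))) {
    m <- generateBaseMesh(s, axes)
    V <- nrow(vertices(m)); F <- nrow(triangles(m))
    E <- V + F - eulerCharacteristic(m)
    expect_identical(3 * F, 2 * E)
    expect_identical(eulerCharacteristic(m), 2L)
    expect_identical(F, closedTriangulationFaceCount(V))
  }
})
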