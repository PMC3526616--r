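test_that("feature assembly produces the documented columns, z-scored", {
  co <- generateCohort(defaultCohortSpec(
    seed = 4, groupSizes = c(NC = 8, MCI_s = 6, MCI_c = 4, AD = 6),
    meshSubdivision = 1), structures = c("hippocampus_L", "hippocampus_R",
                                         "ventricle_L", "ventricle_R"))
  csf <- assembleFeatures(co, "CSF")
  expect_identical(ncol(featureMatrix(csf)), 3L)
  expect_identical(csf@featureNames, c("abeta42", "t_tau", "p_tau"))
  hv <- assembleFeatures(co, "Hp_volumes")
  expect_identical(ncol(featureMatrix(hv)), 2L)
  lv <- assembleFeatures(co, "LV_volumes")
  expect_identical(ncol(featureMatrix(lv)), 2L)
  cv <- assembleFeatures(co, "CSF+volumes")
  expect_identical(ncol(featureMatrix(cv)), 7L)
  for (f in list(csf, hv, cv)) {
    X <- featureMatrix(f)
    expect_true(all(abs(colMeans(X)) < 1e-12))
    expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-12))
  }
  # reference-subject scaling: z-stats from those rows only
  ref <- subjectIds(co)[1:10]
  csfRef <- assembleFeatures(co, "CSF", referenceIds = ref)
  X <- featureMatrix(csfRef)
  expect_true(all(abs(colMeans(X[ref, ])) < 1e-12))
  expect_false(all(abs(colMeans(X)) < 1e-12))

  emptySel <- new("SelectionResult", contrast = c("MCI", "AD"),
                  statistic = c(C1 = 0), pValue = c(C1 = 0.9),
                  selected = integer(0), alpha = 0.05)
  dummyE <- new("ShapeEmbedding",
                coordinates = scale(matrix(rnorm(24 * 2), 24), scale = FALSE),
                eigenvalues = c(2, 1), neighborsK = NA_integer_,
                fidelityR = NA_real_)
  expect_error(assembleFeatures(co, "Hp_shapes",
                                embeddings = list(Hp = dummyE),
                                selections = list(Hp = emptySel)),
               "MCI vs AD")
  expect_error(assembleFeatures(co, "nope"), "unknown feature set")
})

test_that("the linear classifier solves tiny margin problems and matches a QP oracle", {
  # two 1-D points: boundary at the midpoint 0
  X1 <- matrix(c(-1, 1), 2)
  rownames(X1) <- c("a", "b")
  m1 <- trainLinearClassifier(X1, c("neg", "pos"), C = 1, positive = "pos")
  expect_equal(abs(m1$bias), 0, tolerance = 1e-6)
  expect_identical(unname(predict(m1, matrix(0.5))), "pos")
  expect_identical(unname(predict(m1, matrix(-0.5))), "neg")

  # separable blobs: perfect training accuracy at large C
  set.seed(73)
  Xb <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  yb <- rep(c("A", "B"), each = 20)
  mb <- trainLinearClassifier(Xb, yb, C = 100)
  expect_identical(mean(predict(mb, Xb) == yb), 1)

  # 6-point toy set: primal hinge objective equals the SMO dual optimum
  X6 <- rbind(c(0, 0), c(1, 0.5), c(0.3, 1), c(2, 2), c(2.5, 1.2), c(1.5, 2.4))
  y6 <- c(-1, -1, -1, 1, 1, 1)
  for (C in c(0.5, 1, 2)) {
    mod <- trainLinearClassifier(X6, ifelse(y6 > 0, "pos", "neg"), C = C,
                                 positive = "pos", tolerance = 1e-12)
    expect_equal(primalObjective(mod, X6, ifelse(y6 > 0, "pos", "neg"), C),
                 smoDualObjective(X6, y6, C, sweeps = 200000, tol = 1e-16),
                 tolerance = 1e-6)
  }
  expect_error(trainLinearClassifier(X6, rep("pos", 6)), "two classes")
})

test_that("LOO-CV is perfect on separated classes and obeys the balanced identity", {
  set.seed(79)
  X <- rbind(matrix(rnorm(30), 10), matrix(rnorm(30, 10), 10))
  y <- rep(c("NC", "AD"), each = 10)
  r <- looCv(X, y)
  expect_identical(unname(r), c(1, 1, 1))
  # equal class sizes: accuracy == (sensitivity + specificity) / 2 exactly
  Xn <- matrix(rnorm(60), 20)
  rn <- looCv(Xn, y)
  expect_equal(rn[["accuracy"]],
               (rn[["sensitivity"]] + rn[["specificity"]]) / 2,
               tolerance = 1e-12)
  expect_error(looCv(X[1:3, ], y[1:3]), "at least 4")
  expect_error(looCv(X, rep(c("NC", "AD", "MCI"), length.out = 20)),
               "two classes")
})

test_that("LOO accuracy on label-free features is centred near chance", {
  set.seed(83)
  acc <- replicate(60, {
    X <- matrix(rnorm(20 * 2), 20)
    looCv(X, rep(c("NC", "AD"), each = 10))[["accuracy"]]
  })
  expect_gt(mean(acc), 0.35)
  expect_lt(mean(acc), 0.6)
})

test_that("balanced subsampling uses the smallest diagnostic group and is seed-deterministic", {
  co <- generateCohort(defaultCohortSpec(
    seed = 6, groupSizes = c(NC = 8, MCI_s = 4, MCI_c = 2, AD = 5)),
    structures = character(0))
  lab <- diagnosticGroups(co)
  fs <- assembleFeatures(co, "CSF")
  rep1 <- balancedSubsampleEval(fs, lab, c("NC", "AD"), nTrials = 6, seed = 2)
  # common size = min(8, 6, 5) = 5 per group -> LOO over 10 subjects:
  # every trial accuracy is a multiple of 1/10
  expect_true(all(abs(trialAccuracies(rep1) * 10 -
                        round(trialAccuracies(rep1) * 10)) < 1e-12))
  rep2 <- balancedSubsampleEval(fs, lab, c("NC", "AD"), nTrials = 6, seed = 2)
  expect_identical(rep1@trials, rep2@trials)
  expect_true(rep1@ciLow <= rep1@accuracy && rep1@accuracy <= rep1@ciHigh)
  expect_true(all(rep1@trials >= 0 & rep1@trials <= 1))
  expect_error(balancedSubsampleEval(fs, lab, c("NC", "AD"), nTrials = 1),
               "nTrials")
  # percentile CI flag
  rp <- balancedSubsampleEval(fs, lab, c("NC", "AD"), nTrials = 6, seed = 2,
                              ciMethod = "percentile")
  expect_true(rp@ciLow <= rp@accuracy && rp@accuracy <= rp@ciHigh)
})

test_that("paired classifier comparison detects shifts and flags degenerate variance", {
  a <- c(0.7, 0.72, 0.68, 0.71, 0.69, 0.7, 0.73, 0.67)
  same <- compareClassifiers(a, a)
  expect_true(same$degenerate)
  expect_identical(same$p.value, 0)

  set.seed(89)
  b <- a + 0.05 + rnorm(8, 0, 0.002)
  cmp <- compareClassifiers(b, a)
  expect_false(cmp$degenerate)
  expect_lt(cmp$p.value, 0.001)
  # equals the paired-t oracle
  expect_equal(cmp$p.value, t.test(b - a)$p.value, tolerance = 1e-12)

  # independent same-distribution streams: rejection near nominal
  set.seed(97)
  pv <- replicate(200, {
    compareClassifiers(rnorm(20, 0.7, 0.03), rnorm(20, 0.7, 0.03))$p.value
  })
  expect_gt(mean(pv < 0.05), 0.005)
  expect_lt(mean(pv < 0.05), 0.12)
  expect_error(compareClassifiers(a, a[1:3]), "equal length")
})

test_that("adding shape components to CSF does not hurt NC-vs-AD accuracy (majority of seeds)", {
  wins <- 0L
  for (s in 1:5) {
    co <- generateCohort(defaultCohortSpec(seed = 5000 + s))
    lab <- diagnosticGroups(co)
    embs <- list()
    for (cls in c("hippocampus", "ventricle")) {
      DL <- pairwiseDistances(cohortMeshes(co, paste0(cls, "_L")))
      DR <- pairwiseDistances(cohortMeshes(co, paste0(cls, "_R")))
      embs[[if (cls == "hippocampus") "Hp" else "LV"]] <-
        suppressWarnings(isomapEmbedding(combineStructures(DL, DR)))
    }
    sels <- lapply(embs, selectComponents, labels = lab,
                   contrast = c("NC", "AD"))
    a <- balancedSubsampleEval(assembleFeatures(co, "CSF"), lab,
                               c("NC", "AD"), nTrials = 8, seed = s)
    b <- balancedSubsampleEval(
      assembleFeatures(co, "CSF+shapes", embeddings = embs, selections = sels),
      lab, c("NC", "AD"), nTrials = 8, seed = s)
    wins <- wins + (b@accuracy >= a@accuracy)
  }
  expect_gte(wins, 3L)
})
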