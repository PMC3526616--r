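## Linear maximum-margin classification under the paper-style evaluation
## protocol: repeated balanced random subsampling of the diagnostic groups to
## the smallest group's size, leave-one-out cross-validation within each
## trial, and accuracy/sensitivity/specificity with a confidence interval
## over trials.

.IMPAIRMENT <- c(NC = 1, MCI = 2, AD = 3)

## positive class = the more impaired group, so sensitivity refers to
## detecting disease
.positiveClass <- function(contrast) {
  contrast[which.max(.IMPAIRMENT[contrast])]
}

#' Assemble a classifier feature matrix for one marker set
#'
#' Builds the requested marker set from a cohort (CSF triplet, structure
#' volumes, selected bilateral shape components, or combinations) and
#' z-scores each column. Shape sets use only the components a
#' \linkS4class{SelectionResult} picked for the active contrast.
#'
#' @param cohort A \linkS4class{ShapeCohort}.
#' @param setName one of Hp_volumes, Hp_shapes, LV_volumes, LV_shapes, CSF,
#'   "CSF+volumes", "CSF+shapes".
#' @param embeddings named list with elements \code{Hp} and/or \code{LV}
#'   (\linkS4class{ShapeEmbedding} of the bilateral structure), required for
#'   shape sets.
#' @param selections named list with elements \code{Hp} and/or \code{LV}
#'   (\linkS4class{SelectionResult}), required for shape sets.
#' @param standardize z-score columns (default TRUE).
#' @param referenceIds subject ids whose rows define the z-scoring mean/SD
#'   (default: all subjects). Lets training-group statistics be applied to
#'   held-out subjects.
#' @return A \linkS4class{FeatureSet}.
#' @export
assembleFeatures <- function(cohort, setName, embeddings = NULL,
                             selections = NULL, standardize = TRUE,
                             referenceIds = NULL) {
  stopifnot(is(cohort, "ShapeCohort"))
  if (!setName %in% .FEATURE_SETS)
    stop("unknown feature set '", setName, "'; expected one of: ",
         paste(.FEATURE_SETS, collapse = ", "), call. = FALSE)
  ids <- cohort@subjects$subject_id

  volCols <- function(prefix) {
    want <- grep(paste0("^", prefix), colnames(cohort@volumes), value = TRUE)
    if (length(want) == 0)
      stop("cohort has no ", prefix, " meshes for a volume feature set",
           call. = FALSE)
    cohort@volumes[, want, drop = FALSE]
  }
  shapeCols <- function(key) {
    if (is.null(embeddings[[key]]) || is.null(selections[[key]]))
      stop("shape feature set needs embeddings$", key, " and selections$",
           key, call. = FALSE)
    sel <- selections[[key]]
    if (length(sel@selected) == 0L)
      stop(sprintf("no significant %s shape components for contrast %s vs %s",
                   key, sel@contrast[1], sel@contrast[2]), call. = FALSE)
    C <- embeddings[[key]]@coordinates[, sel@selected, drop = FALSE]
    colnames(C) <- paste0(key, "_", colnames(C))
    C
  }
  csfCols <- function() as.matrix(cohort@subjects[, .CSF_MARKERS])

  X <- switch(setName,
    "CSF" = csfCols(),
    "Hp_volumes" = volCols("hippocampus"),
    "LV_volumes" = volCols("ventricle"),
    "Hp_shapes" = shapeCols("Hp"),
    "LV_shapes" = shapeCols("LV"),
    "CSF+volumes" = cbind(csfCols(), volCols("hippocampus"),
                          volCols("ventricle")),
    "CSF+shapes" = cbind(csfCols(), shapeCols("Hp"), shapeCols("LV")))
  rownames(X) <- ids
  if (standardize) {
    ref <- if (is.null(referenceIds)) seq_len(nrow(X))
           else match(referenceIds, ids)
    mu <- colMeans(X[ref, , drop = FALSE])
    sdv <- apply(X[ref, , drop = FALSE], 2L, stats::sd)
    if (any(sdv == 0))
      stop("constant feature column cannot be z-scored: ",
           paste(colnames(X)[sdv == 0], collapse = ", "), call. = FALSE)
    X <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  }
  new("FeatureSet", name = setName, matrix = X, featureNames = colnames(X))
}

#' Train a soft-margin linear maximum-margin classifier
#'
#' Linear support vector machine (C-classification, libsvm via e1071) on
#' already-scaled features. The decision rule is sign(w'x + b) with the
#' positive side assigned to \code{positive}.
#'
#' @param X numeric feature matrix (subjects x features).
#' @param y class labels (two classes present).
#' @param C soft-margin penalty (default 1 on z-scored features).
#' @param positive label treated as the positive class (default: second
#'   sorted level).
#' @param ... further arguments passed to \code{e1071::svm} (e.g.
#'   \code{tolerance}).
#' @return Object of class \code{linearShapeClassifier} with elements
#'   \code{weights}, \code{bias}, \code{positive}, \code{negative} and the
#'   underlying fit.
#' @export
trainLinearClassifier <- function(X, y, C = 1, positive = NULL, ...) {
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    stop("exactly two classes required for training", call. = FALSE)
  if (is.null(positive)) positive <- lev[2L]
  negative <- setdiff(lev, positive)
  yf <- factor(y, levels = c(negative, positive))
  fit <- e1071::svm(x = X, y = yf, type = "C-classification",
                    kernel = "linear", cost = C, scale = FALSE, ...)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value toward the first class it encounters;
  # derive the orientation from a training prediction and flip so positive
  # scores mean the positive (more impaired) class
  pred1 <- as.character(stats::predict(fit, X[1, , drop = FALSE]))
  score1 <- sum(w * X[1, ]) + b
  if ((score1 > 0 && pred1 != positive) || (score1 < 0 && pred1 == positive)) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b, positive = positive,
                 negative = negative, C = C, fit = fit),
            class = "linearShapeClassifier")
}

#' @rdname trainLinearClassifier
#' @param object a fitted \code{linearShapeClassifier}.
#' @param newdata feature matrix to classify.
#' @param ... ignored.
#' @export
predict.linearShapeClassifier <- function(object, newdata, ...) {
  score <- drop(as.matrix(newdata) %*% object$weights) + object$bias
  ifelse(score > 0, object$positive, object$negative)
}

#' Leave-one-out cross-validation of the linear classifier
#'
#' n train/test splits each holding out one subject. Sensitivity is the
#' correct fraction among the positive (more impaired) class, specificity
#' among the negative class; with equal class sizes, accuracy equals their
#' mean exactly.
#'
#' @param X feature matrix.
#' @param y two-class labels (both classes with >= 2 members, n >= 4).
#' @param C soft-margin penalty.
#' @param positive positive-class label (default: the more impaired of the
#'   two diagnostic labels when recognizable, else second sorted level).
#' @return Named numeric: accuracy, sensitivity, specificity.
#' @export
looCv <- function(X, y, C = 1, positive = NULL) {
  y <- as.character(y)
  n <- length(y)
  if (n < 4L) stop("need at least 4 subjects for LOO-CV", call. = FALSE)
  lev <- sort(unique(y))
  if (length(lev) != 2L || min(table(y)) < 2L)
    stop("two classes with at least 2 members each required", call. = FALSE)
  if (is.null(positive))
    positive <- if (all(lev %in% names(.IMPAIRMENT))) .positiveClass(lev)
                else lev[2L]
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- trainLinearClassifier(X[-i, , drop = FALSE], y[-i], C = C,
                                 positive = positive)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  pos <- y == positive
  c(accuracy = mean(pred == y),
    sensitivity = mean(pred[pos] == y[pos]),
    specificity = mean(pred[!pos] == y[!pos]))
}

.meanCi <- function(x, method = c("normal", "percentile")) {
  method <- match.arg(method)
  m <- mean(x)
  if (method == "normal") {
    half <- 1.96 * stats::sd(x) / sqrt(length(x))
    c(mean = m, lo = max(0, m - half), hi = min(1, m + half))
  } else {
    q <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
    c(mean = m, lo = min(q[1], m), hi = max(q[2], m))
  }
}

#' Balanced-subsampling leave-one-out evaluation of one marker set
#'
#' The evaluation protocol for unequal diagnostic groups: per trial, each
#' contrast group is subsampled without replacement to the common size (the
#' smallest diagnostic group across NC/MCI/AD in the cohort, so both
#' two-group contrasts and the three-group design use equal sizes), LOO-CV
#' is run within the trial, and accuracy/sensitivity/specificity are
#' averaged over trials with a 95\% confidence interval on the mean
#' accuracy.
#'
#' @param features A \linkS4class{FeatureSet} (or plain matrix with subject
#'   rownames).
#' @param labels diagnostic labels (NC/MCI/AD) aligned to the feature rows.
#' @param contrast ordered pair of groups to classify.
#' @param nTrials number of balanced subsampling trials (>= 2; the reference
#'   protocol uses 100).
#' @param C soft-margin penalty.
#' @param seed integer seed; trial RNG streams derive from it, so reports
#'   are reproducible and trials are paired across marker sets evaluated
#'   with the same seed.
#' @param ciMethod "normal" (mean +/- 1.96 SD/sqrt(n)) or "percentile".
#' @return A \linkS4class{ClassifierReport}.
#' @export
balancedSubsampleEval <- function(features, labels, contrast, nTrials = 100,
                                  C = 1, seed = 1L,
                                  ciMethod = c("normal", "percentile")) {
  ciMethod <- match.arg(ciMethod)
  X <- if (is(features, "FeatureSet")) features@matrix else as.matrix(features)
  setName <- if (is(features, "FeatureSet")) features@name else "custom"
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("one label per feature row required", call. = FALSE)
  if (nTrials < 2) stop("nTrials must be >= 2", call. = FALSE)
  sizes <- table(labels[labels %in% names(.IMPAIRMENT)])
  target <- min(sizes)
  if (any(table(labels)[contrast] < target))
    stop("contrast groups must each have at least the common subsample size",
         call. = FALSE)
  positive <- .positiveClass(contrast)
  idxByGroup <- lapply(contrast, function(g) which(labels == g))
  trials <- matrix(NA_real_, nTrials, 3L,
                   dimnames = list(NULL, c("accuracy", "sensitivity",
                                           "specificity")))
  for (t in seq_len(nTrials)) {
    take <- withSeed(.subjectSeed(seed, t), {
      unlist(lapply(idxByGroup, function(ix) sample(ix, target)))
    })
    trials[t, ] <- looCv(X[take, , drop = FALSE], labels[take], C = C,
                         positive = positive)
  }
  ci <- .meanCi(trials[, "accuracy"], ciMethod)
  new("ClassifierReport", contrast = contrast, featureSet = setName,
      accuracy = unname(ci["mean"]), ciLow = unname(ci["lo"]),
      ciHigh = unname(ci["hi"]),
      sensitivity = mean(trials[, "sensitivity"]),
      specificity = mean(trials[, "specificity"]),
      nTrials = as.integer(nTrials), seed = as.integer(seed),
      trials = trials)
}

#' Paired comparison of two classifier evaluations
#'
#' Paired two-tailed Student t-test on per-trial accuracy differences of two
#' evaluations run with the same trial seeds. Zero-variance differences are
#' reported as p = 0 with a degenerate-variance flag rather than an error.
#'
#' @param a,b \linkS4class{ClassifierReport}s (or per-trial accuracy
#'   vectors) with equal trial counts, paired by trial.
#' @return List: p.value, statistic (NA when degenerate), degenerate flag.
#' @export
compareClassifiers <- function(a, b) {
  xa <- if (is(a, "ClassifierReport")) trialAccuracies(a) else as.numeric(a)
  xb <- if (is(b, "ClassifierReport")) trialAccuracies(b) else as.numeric(b)
  if (length(xa) != length(xb))
    stop("per-trial accuracies must have equal length (paired trials)",
         call. = FALSE)
  d <- xa - xb
  if (stats::sd(d) == 0)
    return(list(p.value = 0, statistic = NA_real_, degenerate = TRUE))
  ht <- stats::t.test(xa, xb, paired = TRUE)
  list(p.value = ht$p.value, statistic = unname(ht$statistic),
       degenerate = FALSE)
}
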