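## MCI-to-AD conversion prediction: a classifier trained on the extreme
## groups (NC vs AD) at baseline is applied to the MCI converters and
## non-converters. Feature selection and z-scoring statistics are computed
## on the NC + AD training subjects only, then applied to the MCI subjects,
## so held-out subjects never inform scaling.

#' Predict MCI-to-AD conversion from a classifier trained on NC vs AD
#'
#' Per trial, NC is subsampled without replacement to the AD group size
#' (balanced training; disable with \code{balanced = FALSE} to train on all
#' NC + AD), the linear classifier is trained on NC vs AD, and every MCI
#' subject is classified. Sensitivity is the mean fraction of converters
#' (MCI_c) labeled AD-like, specificity the mean fraction of non-converters
#' (MCI_s) labeled NC-like; accuracy is the overall correct fraction, with a
#' 95\% confidence interval over trials. Shape feature sets use components
#' selected for the NC-vs-AD contrast on the NC + AD subjects.
#'
#' @param cohort A \linkS4class{ShapeCohort} containing NC, AD, MCI_c and
#'   MCI_s subjects.
#' @param setName marker-set name (see \code{\link{assembleFeatures}}).
#' @param embeddings,alpha embeddings for shape sets and the selection
#'   alpha; selection is restricted to NC + AD subjects.
#' @param nTrials number of balanced training subsamples (default 100).
#' @param C soft-margin penalty.
#' @param seed integer seed for the trial streams.
#' @param balanced subsample NC to the AD size per trial (default TRUE).
#' @param ciMethod "normal" or "percentile".
#' @return A \linkS4class{ConversionReport}.
#' @export
predictConversion <- function(cohort, setName = "CSF", embeddings = NULL,
                              alpha = 0.05, nTrials = 100, C = 1, seed = 1L,
                              balanced = TRUE,
                              ciMethod = c("normal", "percentile")) {
  stopifnot(is(cohort, "ShapeCohort"))
  ciMethod <- match.arg(ciMethod)
  g4 <- cohort@subjects$group
  for (g in c("NC", "AD", "MCI_c", "MCI_s"))
    if (!any(g4 == g))
      stop("cohort is missing group ", g, call. = FALSE)
  ids <- cohort@subjects$subject_id
  trainIds <- ids[g4 %in% c("NC", "AD")]

  selections <- NULL
  if (setName %in% c("Hp_shapes", "LV_shapes", "CSF+shapes")) {
    if (is.null(embeddings))
      stop("shape feature sets need embeddings", call. = FALSE)
    trainRows <- match(trainIds, ids)
    selections <- lapply(embeddings, function(E) {
      Ctr <- E@coordinates[trainRows, , drop = FALSE]
      .screenMatrix(Ctr, g4[trainRows], c("NC", "AD"), alpha, "none",
                    colnames(Ctr))
    })
  }
  fs <- assembleFeatures(cohort, setName, embeddings = embeddings,
                         selections = selections, standardize = TRUE,
                         referenceIds = trainIds)
  X <- fs@matrix

  ncIdx <- which(g4 == "NC")
  adIdx <- which(g4 == "AD")
  mciIdx <- which(g4 %in% c("MCI_s", "MCI_c"))
  isConv <- g4[mciIdx] == "MCI_c"
  nC <- sum(isConv)
  nS <- sum(!isConv)

  trials <- matrix(NA_real_, nTrials, 3L,
                   dimnames = list(NULL, c("accuracy", "sensitivity",
                                           "specificity")))
  for (t in seq_len(nTrials)) {
    ncUse <- if (balanced) {
      withSeed(.subjectSeed(seed, t), sample(ncIdx, length(adIdx)))
    } else ncIdx
    tr <- c(ncUse, adIdx)
    fit <- trainLinearClassifier(X[tr, , drop = FALSE],
                                 ifelse(g4[tr] == "AD", "AD", "NC"),
                                 C = C, positive = "AD")
    pred <- predict(fit, X[mciIdx, , drop = FALSE])
    sens <- mean(pred[isConv] == "AD")
    spec <- mean(pred[!isConv] == "NC")
    trials[t, ] <- c((sens * nC + spec * nS) / (nC + nS), sens, spec)
  }
  ci <- .meanCi(trials[, "accuracy"], ciMethod)
  new("ConversionReport", featureSet = setName,
      accuracy = unname(ci["mean"]), ciLow = unname(ci["lo"]),
      ciHigh = unname(ci["hi"]),
      sensitivity = mean(trials[, "sensitivity"]),
      specificity = mean(trials[, "specificity"]),
      nConverters = as.integer(nC), nNonconverters = as.integer(nS),
      nTrials = as.integer(nTrials), seed = as.integer(seed),
      trials = trials)
}
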