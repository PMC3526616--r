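## Pooled-variance Student t-tests on embedding components and CSF markers;
## features entering a classifier are the components with significant group
## differences for the contrast at hand.

#' Two-sample pooled-variance Student t-test
#'
#' Classic Student t with df = nx + ny - 2 (pooled variance, not Welch) and
#' two-tailed p, delegated to \code{stats::t.test(var.equal = TRUE)}.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return Named list: statistic (t), p.value.
#' @export
twoSampleT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  sp <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
        (length(x) + length(y) - 2)
  if (sp == 0)
    stop("zero pooled variance: t statistic undefined", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

.screenMatrix <- function(X, labels, contrast, alpha, adjust, featureNames) {
  if (!all(contrast %in% labels))
    stop("contrast group absent from labels: ",
         paste(setdiff(contrast, unique(labels)), collapse = ", "),
         call. = FALSE)
  ia <- labels == contrast[1L]
  ib <- labels == contrast[2L]
  tt <- vapply(seq_len(ncol(X)), function(j) {
    r <- twoSampleT(X[ia, j], X[ib, j])
    c(r$statistic, r$p.value)
  }, numeric(2))
  stat <- stats::setNames(tt[1L, ], featureNames)
  p <- stats::setNames(tt[2L, ], featureNames)
  pAdj <- if (adjust == "fdr") stats::p.adjust(p, "BH") else p
  new("SelectionResult", contrast = contrast, statistic = stat, pValue = p,
      selected = which(pAdj < alpha), alpha = alpha)
}

#' Select embedding components separating two diagnostic groups
#'
#' Tests every component with a pooled-variance Student t restricted to the
#' two contrast groups; selected components are those with p < alpha. No
#' multiple-testing correction by default, matching per-component reporting
#' of significant shape components; an FDR (Benjamini-Hochberg) switch is
#' available.
#'
#' @param E A \linkS4class{ShapeEmbedding}.
#' @param labels group label per embedded subject (row order of E).
#' @param contrast ordered pair of group labels.
#' @param alpha two-tailed significance level (default 0.05).
#' @param adjust "none" (default) or "fdr".
#' @return A \linkS4class{SelectionResult}.
#' @export
selectComponents <- function(E, labels, contrast, alpha = 0.05,
                             adjust = c("none", "fdr")) {
  stopifnot(is(E, "ShapeEmbedding"))
  adjust <- match.arg(adjust)
  C <- E@coordinates
  if (length(labels) != nrow(C))
    stop("one label per embedded subject required", call. = FALSE)
  .screenMatrix(C, labels, contrast, alpha, adjust, colnames(C))
}

#' Screen CSF markers for a group contrast
#'
#' Same pooled-t screen as \code{\link{selectComponents}}, applied to the
#' three CSF markers (Abeta42, t-tau, p-tau) of a cohort; used for the
#' marker-pattern column of a Table-3-style report.
#'
#' @param cohort A \linkS4class{ShapeCohort}.
#' @param contrast ordered pair of diagnostic groups (NC / MCI / AD).
#' @param alpha significance level.
#' @param adjust "none" or "fdr".
#' @return A \linkS4class{SelectionResult} over the three markers.
#' @export
selectCsfMarkers <- function(cohort, contrast, alpha = 0.05,
                             adjust = c("none", "fdr")) {
  stopifnot(is(cohort, "ShapeCohort"))
  adjust <- match.arg(adjust)
  X <- as.matrix(cohort@subjects[, .CSF_MARKERS])
  labels <- diagnosticGroups(cohort)
  .screenMatrix(X, labels, contrast, alpha, adjust, .CSF_MARKERS)
}
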