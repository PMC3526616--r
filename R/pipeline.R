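## End-to-end orchestration: simulate -> distances -> embed -> select ->
## classify -> convert -> map, with a JSON-serializable config, deterministic
## seeding and Table 1-4 style CSV artifacts in an output directory.

#' Default pipeline configuration
#'
#' Returns the configuration list \code{\link{runPipeline}} consumes, with
#' every stage at its reference setting: the default synthetic cohort, metric
#' kernel width 5 mean edge lengths (ridge 1e-6), ISOMAP with k = 10
#' neighbours and 20 components, selection at alpha = 0.05, linear SVM with
#' C = 1 evaluated over 100 balanced subsampling trials, all seven marker
#' sets and all three group contrasts.
#'
#' @param seed master seed propagated to every stochastic stage.
#' @return Named list of stage settings.
#' @export
pipelineConfig <- function(seed = 1L) {
  list(seed = as.integer(seed),
       cohort = list(),                    # overrides for cohortSpec()
       structures = c("hippocampus_L", "hippocampus_R",
                      "ventricle_L", "ventricle_R"),
       metric = list(kernelSigma = NULL, ridge = 1e-6),
       isomap = list(k = 10L, m = 20L),
       alpha = 0.05,
       classifier = list(C = 1, nTrials = 100L),
       featureSets = .FEATURE_SETS,
       contrasts = list(c("NC", "AD"), c("NC", "MCI"), c("MCI", "AD")),
       conversionSets = c("Hp_volumes", "Hp_shapes", "LV_volumes",
                          "LV_shapes", "CSF", "CSF+volumes", "CSF+shapes"),
       mapContrasts = list(c("MCI", "NC"), c("AD", "MCI")),
       writeMeshes = FALSE)
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.classifierRow <- function(report, contrast, setName) {
  data.frame(feature_set = setName,
             contrast = paste(contrast, collapse = " vs "),
             accuracy = report@accuracy, ci_low = report@ciLow,
             ci_high = report@ciHigh, sensitivity = report@sensitivity,
             specificity = report@specificity,
             cell = sprintf("%.1f%% (CI: %.1f%%~%.1f%%) Sens = %.1f%%, Spec = %.1f%%",
                            100 * report@accuracy, 100 * report@ciLow,
                            100 * report@ciHigh, 100 * report@sensitivity,
                            100 * report@specificity),
             stringsAsFactors = FALSE)
}

#' Run the full biomarker analysis pipeline
#'
#' Executes every stage on a (simulated) cohort and writes the stage
#' artifacts to \code{outputDir}: the cohort manifest, one bilateral
#' distance matrix and embedding per structure class, a selection report
#' (which shape components and CSF markers separate each contrast), a
#' classification report (accuracy/sensitivity/specificity with CI per
#' marker set and contrast), a conversion report, and signed deformation
#' maps. Outputs are byte-identical for identical config + seed. Any stage
#' failure aborts with the stage name; artifacts of completed stages are
#' kept.
#'
#' @param config partial configuration; unspecified entries fall back to
#'   \code{\link{pipelineConfig}}. May also be a path to a JSON file with
#'   the same structure.
#' @param outputDir directory for artifacts (created if needed).
#' @param quiet suppress stage log messages.
#' @return Invisibly, a list with the in-memory stage results and artifact
#'   paths.
#' @export
runPipeline <- function(config = list(), outputDir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- .mergeConfig(pipelineConfig(), config)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null")
  cfgHash <- .hashString(as.character(cfgJson))
  paths <- character(0)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say(sprintf("stage %-10s done (%.1f s)", name,
                proc.time()[["elapsed"]] - t0))
    r
  }

  cohort <- stage("simulate", {
    spec <- do.call(cohortSpec, c(cfg$cohort, list(seed = cfg$seed)))
    co <- generateCohort(spec, structures = cfg$structures)
    paths["manifest"] <- writeCohortManifest(co, outputDir,
                                              writeMeshes = cfg$writeMeshes)
    co
  })
  labels <- diagnosticGroups(cohort)

  classes <- unique(.structureClass(cfg$structures))
  keyOf <- c(hippocampus = "Hp", ventricle = "LV")
  distances <- stage("distances", {
    out <- list()
    for (cls in classes) {
      tags <- cfg$structures[.structureClass(cfg$structures) == cls]
      params <- if (is.null(cfg$metric$kernelSigma))
        defaultMetricParams(cohortMeshes(cohort, tags[1])[[1]])
      else metricParams(cfg$metric$kernelSigma, cfg$metric$ridge)
      Ds <- lapply(tags, function(tg)
        pairwiseDistances(cohortMeshes(cohort, tg), params))
      D <- if (length(Ds) == 2L) combineStructures(Ds[[1]], Ds[[2]])
           else Ds[[1]]
      f <- file.path(outputDir, sprintf("distances_%s.csv", cls))
      writeDistanceMatrix(D, f)
      paths[paste0("distances_", cls)] <- f
      out[[keyOf[cls]]] <- D
    }
    out
  })

  embeddings <- stage("embed", {
    out <- lapply(distances, function(D)
      isomapEmbedding(D, k = cfg$isomap$k, m = cfg$isomap$m))
    for (key in names(out)) {
      f <- file.path(outputDir, sprintf("embedding_%s.csv", key))
      writeEmbedding(out[[key]], f)
      paths[paste0("embedding_", key)] <- f
    }
    out
  })

  selections <- stage("select", {
    out <- list()
    rows <- NULL
    for (ct in cfg$contrasts) {
      key <- paste(ct, collapse = "_vs_")
      out[[key]] <- lapply(embeddings, selectComponents, labels = labels,
                           contrast = ct, alpha = cfg$alpha)
      out[[key]]$CSF <- selectCsfMarkers(cohort, ct, alpha = cfg$alpha)
      for (mk in names(out[[key]])) {
        sel <- out[[key]][[mk]]
        rows <- rbind(rows, data.frame(
          marker_set = mk, contrast = paste(ct, collapse = " vs "),
          selected = paste(names(sel@pValue)[sel@selected], collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
    f <- file.path(outputDir, "selection_report.csv")
    utils::write.csv(rows, f, row.names = FALSE)
    paths["selection"] <- f
    out
  })

  classification <- stage("classify", {
    rows <- NULL
    reports <- list()
    for (ct in cfg$contrasts) {
      key <- paste(ct, collapse = "_vs_")
      for (fsName in cfg$featureSets) {
        rep <- tryCatch({
          fs <- assembleFeatures(cohort, fsName, embeddings = embeddings,
                                 selections = selections[[key]])
          balancedSubsampleEval(fs, labels, ct,
                                nTrials = cfg$classifier$nTrials,
                                C = cfg$classifier$C, seed = cfg$seed)
        }, error = function(e) e)
        if (inherits(rep, "error")) {
          say(sprintf("  %s / %s skipped: %s", fsName, key,
                      conditionMessage(rep)))
          next
        }
        reports[[paste(key, fsName)]] <- rep
        rows <- rbind(rows, .classifierRow(rep, ct, fsName))
      }
    }
    f <- file.path(outputDir, "classification_report.csv")
    utils::write.csv(rows, f, row.names = FALSE)
    paths["classification"] <- f
    reports
  })

  conversion <- stage("convert", {
    rows <- NULL
    reports <- list()
    for (fsName in cfg$conversionSets) {
      rep <- tryCatch(
        predictConversion(cohort, fsName, embeddings = embeddings,
                          alpha = cfg$alpha,
                          nTrials = cfg$classifier$nTrials,
                          C = cfg$classifier$C, seed = cfg$seed),
        error = function(e) e)
      if (inherits(rep, "error")) {
        say(sprintf("  conversion %s skipped: %s", fsName,
                    conditionMessage(rep)))
        next
      }
      reports[[fsName]] <- rep
      rows <- rbind(rows, data.frame(
        marker_set = fsName, accuracy = rep@accuracy, ci_low = rep@ciLow,
        ci_high = rep@ciHigh, sensitivity = rep@sensitivity,
        specificity = rep@specificity, stringsAsFactors = FALSE))
    }
    f <- file.path(outputDir, "conversion_report.csv")
    utils::write.csv(rows, f, row.names = FALSE)
    paths["conversion"] <- f
    reports
  })

  maps <- stage("map", {
    out <- list()
    g4 <- cohort@subjects$group
    grpIdx <- function(g) if (g == "MCI") which(g4 %in% c("MCI_s", "MCI_c"))
                          else which(g4 == g)
    for (tag in cfg$structures) {
      ms <- cohortMeshes(cohort, tag)
      base <- ms[[1]]
      for (ct in cfg$mapContrasts) {
        map <- vertexGroupDifference(ms[grpIdx(ct[1])], ms[grpIdx(ct[2])],
                                     base, contrast = ct)
        nm <- sprintf("defmap_%s_%s_vs_%s", tag, ct[1], ct[2])
        f <- file.path(outputDir, paste0(nm, ".csv"))
        writeDeformationMapCsv(map, f)
        paths[nm] <- f
        out[[nm]] <- map
      }
    }
    out
  })

  meta <- list(config = cfg, config_hash = cfgHash,
               generated_artifacts = as.list(paths))
  metaPath <- file.path(outputDir, "run_metadata.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths["metadata"] <- metaPath
  say("all stages complete; ", length(paths), " artifacts in ", outputDir)
  invisible(list(config = cfg, configHash = cfgHash, cohort = cohort,
                 distances = distances, embeddings = embeddings,
                 selections = selections, classification = classification,
                 conversion = conversion, maps = maps, paths = paths))
}
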