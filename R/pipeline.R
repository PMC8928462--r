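# run `expr`, aborting with the stage name on failure and logging timing
withStage <- function(stage, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
  cat(sprintf("%s: %.2fs\n", stage, proc.time()[["elapsed"]] - t0),
      file = log, append = TRUE)
  res
}

#' Run the full CAD pipeline on a synthetic cohort
#'
#' Generates a phantom cohort, obtains lesion masks (ground truth, or a
#' trained segmenter when \code{segmentation$useGroundTruth} is FALSE),
#' extracts the 61 features, runs the SVM under the 5-part rotation,
#' simulates the configured readers, and writes the result bundle:
#' cohort.csv, images/, features.csv, scores.csv, table2.csv (per-method
#' diagnostics), comparisons.csv (chi-square), table3.csv (CAD by
#' subtype), resolved_config.yaml and log.txt. Reruns with an identical
#' config reproduce identical CSVs.
#'
#' @param config list from \code{\link{readRunConfig}}.
#' @return invisibly, a list with the in-memory results (cohort, features,
#'   scores, table2, table3).
#' @export
runPipeline <- function(config = readRunConfig()) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outdir, "log.txt")
  cat(sprintf("seed: %d\nconfig md5: %s\n", config$seed,
              substr(digestConfig(config), 1, 12)), file = log)
  yaml::write_yaml(config, file.path(outdir, "resolved_config.yaml"))

  ph <- config$phantom
  cohort <- withStage("phantom", log,
    makeCohort(ph$nPCR, ph$nNonPCR, unlist(ph$subtypeCounts),
               classEffect = ph$classEffect, seed = config$seed,
               imageSize = ph$imageSize, dir = outdir))
  utils::write.csv(cohortTable(cohort), file.path(outdir, "cohort.csv"),
                   row.names = FALSE)

  masks <- NULL
  sg <- config$segmentation
  if (!isTRUE(sg$useGroundTruth)) {
    masks <- withStage("segmentation", log, {
      cases <- cohortCases(cohort)
      nTrain <- max(2L, round(0.3 * length(cases)))
      trainIdx <- withLocalSeed(config$seed + 1L,
                                sample(seq_along(cases), nTrain))
      model <- trainSegmenter(cases[trainIdx], segTrainConfig(
        learningRate = sg$learningRate, epochs = sg$epochs,
        weightDecay = sg$weightDecay, encoderDepth = sg$encoderDepth,
        baseChannels = sg$baseChannels, seed = config$seed))
      lapply(cases, function(cs)
        segmentLesion(model, cs, threshold = sg$threshold))
    })
  }

  gcfg <- glcmConfig(config$glcm$levels, config$glcm$distances,
                     config$glcm$angles)
  features <- withStage("features", log,
                        extractFeatures(cohort, masks = masks,
                                        config = gcfg))
  writeFeatureCSV(features, file.path(outdir, "features.csv"))

  scheme <- makeSplits(cohort, seed = config$seed)
  scores <- withStage("classifier", log,
    runRotations(features, scheme, costGrid = config$svm$costGrid,
                 kernel = config$svm$kernel,
                 classWeights = isTRUE(config$svm$classWeights)))
  utils::write.csv(scores[, c("case_id", "score", "call")],
                   file.path(outdir, "scores.csv"), row.names = FALSE)

  ev <- withStage("evaluation", log, {
    truth <- scores$label == "pCR"
    cad <- decisionSet(scores$call, truth, score = scores$score,
                       subtype = scores$subtype, caseId = scores$case_id)
    sets <- list(cad = cad)
    rd <- config$eval$readers
    for (i in seq_along(rd)) {
      nm <- names(rd)[i]
      sets[[nm]] <- simulateReader(truth, rd[[i]][1], rd[[i]][2],
                                   seed = config$seed + 100L + i,
                                   subtype = scores$subtype,
                                   caseId = scores$case_id)
      if (isTRUE(config$eval$fusion))
        sets[[paste0(nm, "_cad")]] <- fuseOr(sets[[nm]], cad)
    }
    t2 <- do.call(rbind, lapply(names(sets), function(nm)
      cbind(method = nm, summaryRow(confusionMetrics(sets[[nm]])))))
    cmp <- do.call(rbind, lapply(setdiff(names(sets), "cad"), function(nm)
      do.call(rbind, lapply(c("sensitivity", "specificity", "accuracy"),
        function(met) {
          h <- tryCatch(compareProportions(sets[[nm]], sets$cad, met),
                        zeroMarginError = function(e)
                          list(statistic = NA_real_, p.value = NA_real_))
          data.frame(method = nm, versus = "cad", metric = met,
                     statistic = h$statistic, p_value = h$p.value)
        }))))
    t3list <- subgroupSummary(cad)
    t3 <- do.call(rbind, lapply(names(t3list), function(st)
      cbind(subtype = st, summaryRow(t3list[[st]]))))
    list(table2 = t2, comparisons = cmp, table3 = t3)
  })
  utils::write.csv(ev$table2, file.path(outdir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$comparisons, file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$table3, file.path(outdir, "table3.csv"),
                   row.names = FALSE)
  invisible(list(cohort = cohort, features = features, scores = scores,
                 table2 = ev$table2, table3 = ev$table3))
}

# stable hash of the resolved config for the run log
digestConfig <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # 31-bit polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
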