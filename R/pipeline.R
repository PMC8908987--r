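#' Default pipeline configuration
#'
#' All descriptor defaults are the operating points carried through the
#' classification stage: HOG 5x5x5 blocks, 3x3x3 cells, dodecahedron
#' with full binning; ALBP 5 views, 3 levels, average resampling; PSCSS
#' gap 15 px, 5 views; MGRF 32 levels and 1000 histogram bins; SPHARM
#' order 70; the 40 mm VOI at 1 mm isotropic spacing; 70/30 stratified
#' split; stage networks trained 100 + 100 epochs at learning rate 0.01.
#'
#' @param ... named overrides of any nested entry, e.g.
#'   `pipelineConfig(albp = list(nViews = 3))`.
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    voi = list(sideMM = 40, spacingMM = 1),
    albp = list(nViews = 5, RMax = 3, scheme = "average_n"),
    hog = list(nBlocks = 5, cellSize = 3, solid = "dodecahedron",
               binning = "full"),
    mgrf = list(Q = 32, nBins = 1000),
    pscss = list(nViews = 5, gap = 15, sigmas = c(1, 2, 4, 8, 16)),
    spharm = list(maxOrder = 70),
    descriptors = c("albp", "hog", "mgrf", "pscss", "spharm", "geometric"),
    classifier = list(epochs = 100, lr = 0.01, fusionHidden = 4),
    split = list(trainFrac = 0.70),
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round-trip preserving all effective parameters.
#'
#' @param config from [pipelineConfig()].
#' @param path JSON path.
#' @return `writePipelineConfig()` returns `path` invisibly;
#'   `readPipelineConfig()` the restored config.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(config, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Consensus malignancy label from radiologist grades
#'
#' Grades are integers 1-5 (1 weakest, 5 strongest evidence of
#' malignancy). The mean grade decides the label: `>= 3.5` malignant,
#' `<= 1.5` benign, anything between is excluded from training and
#' evaluation.
#'
#' @param grades integer vector of per-reader grades (1-5, non-empty).
#' @return `"malignant"`, `"benign"` or `"excluded"`.
#' @export
labelFromGrades <- function(grades) {
  stopIfNot(length(grades) >= 1, "grade list must be non-empty")
  stopIfNot(all(grades >= 1 & grades <= 5), "grades must lie in 1..5")
  m <- mean(grades)
  if (m >= 3.5) "malignant" else if (m <= 1.5) "benign" else "excluded"
}

#' Compute all six descriptors for one nodule
#'
#' Runs the configured descriptor modules on a record. The MGRF
#' descriptor needs the field model trained on the benign training
#' nodules, so `mgrfModel` must be supplied whenever `"mgrf"` is among
#' the configured descriptors. A failing stage yields `NULL` for that
#' descriptor (with a warning) and the remaining stages still run.
#'
#' @param record a [NoduleRecord-class].
#' @param config from [pipelineConfig()].
#' @param mgrfModel a trained [MGRFModel-class] (or `NULL`).
#' @return Named list of descriptor vectors (`albp`, `hog`, `mgrf`,
#'   `pscss`, `spharm`, `geometric` under the defaults).
#' @export
extractAllFeatures <- function(record, config = pipelineConfig(),
                               mgrfModel = NULL) {
  voi <- record@voi; mask <- record@mask
  res <- list()
  run <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      warning("descriptor ", nm, " failed: ", conditionMessage(e))
      NULL
    })
  }
  for (d in config$descriptors) {
    res[[d]] <- switch(d,
      albp = run("albp", multiviewALBP(voi, mask,
        nViews = config$albp$nViews, RMax = config$albp$RMax,
        scheme = config$albp$scheme)),
      hog = run("hog", hog3dDescriptor(voi,
        nBlocks = config$hog$nBlocks, cellSize = config$hog$cellSize,
        solid = config$hog$solid, binning = config$hog$binning)),
      mgrf = run("mgrf", {
        if (is.null(mgrfModel))
          stop("mgrf descriptor requires a trained model")
        e <- gibbsEnergyImage(voi, mask, mgrfModel)
        energyHistogram(e, mask, nBins = config$mgrf$nBins,
                        range = mgrfModel@energyRange)
      }),
      pscss = run("pscss", pscssDescriptor(mask,
        nViews = config$pscss$nViews, gap = config$pscss$gap,
        sigmas = config$pscss$sigmas)),
      spharm = run("spharm", spharmDescriptor(mask,
        maxOrder = config$spharm$maxOrder)),
      geometric = run("geometric", geometricDescriptor(mask)),
      stop("unknown descriptor: ", d))
  }
  res
}

#' Feature table for a cohort
#'
#' @param records list of [NoduleRecord-class].
#' @param config from [pipelineConfig()].
#' @param mgrfModel trained [MGRFModel-class] if `"mgrf"` is configured.
#' @param verbose print per-stage progress.
#' @return Named list of feature matrices (samples x entries), one per
#'   descriptor.
#' @export
cohortFeatures <- function(records, config = pipelineConfig(),
                           mgrfModel = NULL, verbose = FALSE) {
  out <- stats::setNames(vector("list", length(config$descriptors)),
                         config$descriptors)
  t0 <- proc.time()[3]
  feats <- lapply(seq_along(records), function(i) {
    f <- extractAllFeatures(records[[i]], config, mgrfModel)
    if (verbose && i %% 25 == 0)
      message(sprintf("  features %d/%d (%.1f s)", i, length(records),
                      proc.time()[3] - t0))
    f
  })
  for (d in config$descriptors)
    out[[d]] <- do.call(rbind, lapply(feats, `[[`, d))
  out
}

#' Run the full two-stage classification experiment
#'
#' Stratified 70/30 split, MGRF training on the benign training nodules,
#' descriptor extraction, one stacked-autoencoder classifier per
#' descriptor, probability fusion, and per-descriptor plus fused test
#' reports.
#'
#' @param records labelled cohort (list of [NoduleRecord-class]).
#' @param config from [pipelineConfig()].
#' @param verbose print progress.
#' @return List with `reports` (named [EvalReport-class] list, one per
#'   descriptor plus `"fused"`), `testProb` (matrix of test
#'   probabilities), `split`, `models`, `config`.
#' @export
runExperiment <- function(records, config = pipelineConfig(),
                          verbose = FALSE) {
  labels <- vapply(records, noduleLabel, "")
  stopIfNot(length(unique(labels)) == 2, "cohort must contain both classes")
  seed <- config$seed
  split <- splitTrainTest(labels, config$split$trainFrac, seed = seed)
  mgrfModel <- NULL
  if ("mgrf" %in% config$descriptors) {
    trBenign <- records[intersect(split$train, which(labels == "benign"))]
    if (verbose) message("training MGRF on ", length(trBenign),
                         " benign nodules")
    mgrfModel <- trainMGRF(trBenign, Q = config$mgrf$Q)
  }
  if (verbose) message("extracting features for ", length(records),
                       " records")
  feats <- cohortFeatures(records, config, mgrfModel, verbose = verbose)
  trainProb <- list(); testProb <- list(); models <- list()
  for (i in seq_along(config$descriptors)) {
    d <- config$descriptors[i]
    if (verbose) message("training classifier: ", d)
    cfg <- buildStackedSAE(ncol(feats[[d]]),
                           seed = deriveSeed(seed, 1000 + i),
                           epochs = config$classifier$epochs,
                           lr = config$classifier$lr)
    tr <- trainDescriptorClassifier(feats[[d]][split$train, , drop = FALSE],
                                    labels[split$train], cfg)
    models[[d]] <- tr$model
    trainProb[[d]] <- tr$prob
    testProb[[d]] <- predictProb(tr$model,
                                 feats[[d]][split$test, , drop = FALSE])
  }
  trainP <- do.call(cbind, trainProb)
  testP <- do.call(cbind, testProb)
  colnames(trainP) <- colnames(testP) <- config$descriptors
  if (verbose) message("training fusion network")
  fu <- fuseProbabilities(trainP, labels[split$train],
                          seed = deriveSeed(seed, 2000),
                          hidden = config$classifier$fusionHidden,
                          epochs = config$classifier$epochs,
                          lr = config$classifier$lr)
  models$fused <- fu$model
  fusedTest <- predictProb(fu$model, testP)
  reports <- list()
  for (d in config$descriptors)
    reports[[d]] <- evaluateClassifier(testP[, d], labels[split$test])
  reports$fused <- evaluateClassifier(fusedTest, labels[split$test])
  list(reports = reports,
       testProb = cbind(testP, fused = fusedTest),
       split = split, models = models, config = config)
}

#' One-line summary table of an experiment
#'
#' @param experiment result of [runExperiment()].
#' @return `data.frame` with one row per descriptor plus the fused
#'   system (AC/SN/SP/PR in percent, AUC in `[0, 1]`).
#' @export
experimentSummary <- function(experiment) {
  rows <- lapply(names(experiment$reports), function(nm) {
    r <- experiment$reports[[nm]]
    data.frame(descriptor = nm, accuracy = r@accuracy,
               sensitivity = r@sensitivity, specificity = r@specificity,
               precision = r@precision, auc = r@auc)
  })
  do.call(rbind, rows)
}
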