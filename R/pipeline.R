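# End-to-end pipeline: simulate -> preprocess -> detect -> crop -> train ->
# TTA predict -> explain -> evaluate, with a JSON report carrying the seed
# and a config hash for reproducibility.

unionBoxes <- function(boxes) {
  boxes <- Filter(Negate(is.null), boxes)
  if (length(boxes) == 0) return(NULL)
  boundingBox(min(vapply(boxes, function(b) b@xMin, numeric(1))),
              min(vapply(boxes, function(b) b@yMin, numeric(1))),
              max(vapply(boxes, function(b) b@xMax, numeric(1))),
              max(vapply(boxes, function(b) b@yMax, numeric(1))))
}

#' Preprocess and detect one view
#'
#' Canonicalizes the view to the shared frame, applies the homomorphic
#' speckle filter (its cutoff adapted to the detected outline scale), and
#' runs the detector in the canonical frame.
#'
#' @param image raw view matrix, [0,255].
#' @param detector detector function for this view.
#' @param filterCutoff base homomorphic cutoff (fraction of Nyquist).
#' @return list(canonical, filtered, transform, detections).
#' @export
preprocessView <- function(image, detector = NULL, filterCutoff = 0.25) {
  cano <- canonicalize(image)
  # adaptive cutoff: the canonical frame fixes the outline scale, so the
  # canonical cutoff applies directly after warping
  filtered <- homomorphicFilter(cano$image, cutoff = filterCutoff)
  detections <- if (is.null(detector)) list() else detector(filtered)
  list(canonical = cano$image, filtered = filtered,
       transform = cano$transform, detections = detections)
}

# The ROI deliberately spans the CC and its adjacent indirect landmarks
# (cavum margins, ventricular walls), which carry the discriminative signal
# when the band itself is absent. In the sagittal view the CC detection (or,
# when absent, the canonical CC location) is unioned with the detected
# landmarks; the axial ROI is the landmark union.
roiBoxForView <- function(view, detections, detector, imageShape) {
  byStructure <- function(s) {
    for (d in detections) if (d@structure == s) return(d@box)
    NULL
  }
  canonical <- attr(detector, "canonicalBoxes")
  if (view == "sagittal") {
    cc <- byStructure("cc")
    if (is.null(cc)) cc <- canonical[["cc"]]   # where the CC should be
    b <- unionBoxes(list(cc, byStructure("cavum_septi_pellucidi"),
                         byStructure("lateral_ventricle_anterior_horn")))
  } else {
    b <- unionBoxes(list(byStructure("cavum_septi_pellucidi"),
                         byStructure("lateral_ventricle_anterior_horn")))
    if (is.null(b))
      b <- unionBoxes(canonical[c("cavum_septi_pellucidi",
                                  "lateral_ventricle_anterior_horn")])
  }
  b
}

#' Prepare the classifier input pair for one case
#'
#' Runs per-view preprocessing and detection, selects the ROI box (the CC
#' detection in the sagittal view — or, when absent, the canonical CC
#' location, so agenesis cases are cropped where the CC should be; the
#' cavum/ventricle landmark union in the axial view), applies dynamic
#' boundary expansion, crops, and letterboxes to the classifier input size.
#'
#' @param case a \linkS4class{CasePair}.
#' @param detectors list(sagittal, axial) of detector functions.
#' @param inputSize classifier input side length.
#' @param expansion boundary expansion (3, 4, 5 or "auto").
#' @return list(sagittal, axial, rois, views) where \code{rois} holds the
#'   \linkS4class{ROI} objects and \code{views} the per-view preprocessing
#'   results (transforms and detections).
#' @export
prepareRoiPair <- function(case, detectors, inputSize = 256,
                           expansion = "auto") {
  out <- list(views = list(), rois = list())
  for (view in c("sagittal", "axial")) {
    pv <- preprocessView(caseImage(case, view), detectors[[view]])
    b <- roiBoxForView(view, pv$detections, detectors[[view]],
                       dim(pv$filtered))
    det <- new("Detection", box = b, confidence = 1, structure = "roi")
    roi <- cropRoi(pv$filtered, det, expansion, view = view,
                   caseId = case@caseId)
    out$views[[view]] <- pv
    out$rois[[view]] <- roi
    out[[view]] <- resizeLetterbox(roi@patch, inputSize)
  }
  out
}

#' Ground-truth boxes mapped into ROI coordinates
#'
#' Maps a case's ground-truth boxes through the view's canonicalizing
#' transform and the ROI crop/letterbox, yielding boxes comparable with
#' heatmaps on the classifier input grid.
#'
#' @param case a \linkS4class{CasePair}.
#' @param prepared output of \code{\link{prepareRoiPair}} for that case.
#' @param view "sagittal" or "axial".
#' @param structures structure names to map.
#' @param inputSize classifier input side length.
#' @return named list of \linkS4class{BoundingBox} (NULL where the structure
#'   is absent or outside the ROI).
#' @export
gtBoxesInRoi <- function(case, prepared, view, structures = NULL,
                         inputSize = 256) {
  boxes <- gtBoxes(case, view)
  if (is.null(structures)) structures <- names(boxes)
  pv <- prepared$views[[view]]
  roiBox <- prepared$rois[[view]]@sourceBox
  shape <- dim(pv$filtered)
  out <- list()
  for (s in structures) {
    b <- boxes[[s]]
    if (is.null(b)) { out[s] <- list(NULL); next }
    bc <- mapBoxThroughAffine(b, pv$transform, shape)
    out[[s]] <- mapBoxToRoi(bc, roiBox, inputSize)
  }
  out
}

fnvHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Full run configuration
#'
#' @param nCases phantom dataset size.
#' @param phantom a \linkS4class{PhantomConfig}.
#' @param network a \code{\link{networkConfig}}.
#' @param train a \code{\link{trainConfig}}.
#' @param augmentation an \code{\link{augmentationParams}}.
#' @param ttaK TTA variants per test case.
#' @param expansion ROI boundary expansion.
#' @param seed global pipeline seed (threads into generation, splitting,
#'   training and TTA).
#' @return nested configuration list of class \code{RunConfig}.
#' @export
runConfig <- function(nCases = 100, phantom = phantomConfig(),
                      network = networkConfig("tiny"),
                      train = trainConfig(maxEpochs = 3),
                      augmentation = augmentationParams(),
                      ttaK = 5, expansion = "auto", seed = 1L) {
  structure(list(nCases = nCases, phantom = phantom, network = network,
                 train = train, augmentation = augmentation, ttaK = ttaK,
                 expansion = expansion, seed = seed), class = "RunConfig")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a flat configuration file (YAML, or JSON by file extension) whose
#' keys override \code{\link{runConfig}} defaults: \code{n_cases},
#' \code{prevalence}, \code{backbone}, \code{input_size}, \code{max_epochs},
#' \code{batch_size}, \code{learning_rate}, \code{tta_k}, \code{expansion},
#' \code{seed}. Values round-trip losslessly through the file format.
#'
#' @param path configuration file path (.yaml/.yml or .json).
#' @return a \code{\link{runConfig}}.
#' @export
loadRunConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  pick <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  runConfig(
    nCases = pick("n_cases", 100),
    phantom = phantomConfig(prevalence = pick("prevalence", 0.2)),
    network = networkConfig(pick("backbone", "tiny"),
                            inputSize = pick("input_size", 256)),
    train = trainConfig(learningRate = pick("learning_rate", 1e-3),
                        batchSize = pick("batch_size", 32),
                        maxEpochs = pick("max_epochs", 10),
                        seed = pick("seed", 1)),
    ttaK = pick("tta_k", 5),
    expansion = pick("expansion", "auto"),
    seed = pick("seed", 1))
}

#' Run the full diagnostic pipeline on phantom data
#'
#' Executes simulate, preprocess, detect, train, TTA predict, explain and
#' evaluate; writes \code{report.json} and \code{predictions.csv} into
#' \code{outDir} (created if missing). Identical \code{(config, seed)} runs
#' produce identical reports.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory (optional; when NULL nothing is written).
#' @param verbose print stage progress.
#' @return the report as a list (invisibly written to JSON when
#'   \code{outDir} is given).
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL,
                        verbose = FALSE) {
  t0 <- Sys.time()
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(name, t) timings[[name]] <<- round(
    as.numeric(difftime(Sys.time(), t, units = "secs")), 2)

  t <- tic()
  say("simulate: %d cases", config$nCases)
  ds <- stage("simulate",
              generateDataset(config$phantom, config$nCases,
                              seed = deriveSeed(seed, 1)))
  toc("simulate", t)

  detectors <- list(
    sagittal = matchedFilterDetector("sagittal", config$phantom),
    axial = matchedFilterDetector("axial", config$phantom))
  for (v in names(detectors)) {
    cb <- attr(detectors[[v]], "canonicalBoxes")
    if (is.null(cb)) attr(detectors[[v]], "canonicalBoxes") <- list()
  }

  t <- tic()
  say("preprocess + detect + crop")
  prepared <- stage("preprocess_detect", lapply(ds$cases, prepareRoiPair,
                                                detectors = detectors,
                                                inputSize = config$network$inputSize,
                                                expansion = config$expansion))
  toc("preprocess_detect", t)

  # detection evaluation against generator ground truth (original frame)
  t <- tic()
  detEval <- stage("detect_eval", {
    predRows <- list(); gtRows <- list()
    for (i in seq_along(ds$cases)) {
      cs <- ds$cases[[i]]
      for (view in c("sagittal", "axial")) {
        pv <- prepared[[i]]$views[[view]]
        dets <- lapply(pv$detections, function(d) {
          d@box <- mapBoxThroughAffine(d@box, pv$transform,
                                       dim(caseImage(cs, view)),
                                       inverse = TRUE)
          d
        })
        pf <- detectionsToFrame(cs@caseId, dets)
        if (nrow(pf)) {
          pf$view <- view
          predRows[[length(predRows) + 1L]] <- pf
        }
        gb <- gtBoxes(cs, view)
        gb <- gb[names(gb) %in% c("cc", "cavum_septi_pellucidi",
                                  "lateral_ventricle_anterior_horn")]
        if (length(gb))
          gtRows[[length(gtRows) + 1L]] <- do.call(rbind, lapply(
            names(gb), function(s) data.frame(
              case_id = cs@caseId, structure = s, view = view,
              x_min = gb[[s]]@xMin, y_min = gb[[s]]@yMin,
              x_max = gb[[s]]@xMax, y_max = gb[[s]]@yMax,
              stringsAsFactors = FALSE)))
      }
    }
    evaluateDetection(do.call(rbind, predRows), do.call(rbind, gtRows))
  })
  toc("detect_eval", t)

  labels <- ds$manifest$label
  ids <- ds$manifest$case_id
  split <- stage("split", splitPatientLevel(ids, labels,
                                            config$train$splitFraction,
                                            seed = deriveSeed(seed, 2)))
  trainIdx <- match(split$train, ids); testIdx <- match(split$test, ids)
  weights <- computeClassWeights(sum(labels[trainIdx] == "normal"),
                                 sum(labels[trainIdx] == "agenesis"))

  t <- tic()
  say("train: %d cases", length(trainIdx))
  net <- adfnet(config$network, seed = deriveSeed(seed, 3))
  tcfg <- config$train; tcfg$seed <- deriveSeed(seed, 4)
  trained <- stage("train", trainAdfnet(net, prepared[trainIdx],
                                        labels[trainIdx], tcfg, weights))
  toc("train", t)

  t <- tic()
  say("predict (TTA x%d): %d cases", config$ttaK, length(testIdx))
  preds <- stage("predict", {
    rows <- lapply(seq_along(testIdx), function(j) {
      i <- testIdx[j]
      tta <- predictTta(trained$net, prepared[[i]], k = config$ttaK,
                        params = config$augmentation,
                        seed = deriveSeed(seed, 100000 + i))
      data.frame(case_id = ids[i], label = labels[i],
                 prob_normal = tta$aggregate@probNormal,
                 prob_agenesis = tta$aggregate@probAgenesis,
                 alpha = tta$aggregate@alphaUsed,
                 predicted = tta$aggregate@predictedLabel,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  toc("predict", t)

  t <- tic()
  rep <- stage("evaluate", {
    counts <- confusionCounts(preds$prob_agenesis, preds$label)
    metrics(counts, auc = rocAuc(preds$prob_agenesis, preds$label))
  })
  toc("evaluate", t)

  t <- tic()
  say("explain: Grad-CAM++ on agenesis test cases")
  explain <- stage("explain", {
    agIdx <- testIdx[labels[testIdx] == "agenesis"]
    perView <- list(sagittal = c(), axial = c())
    fracs <- c(); bandsAcc <- NULL; nMaps <- 0
    for (i in utils::head(agIdx, 10)) {
      caseFracs <- c()
      for (view in c("sagittal", "axial")) {
        rb <- prepared[[i]]$rois[[view]]@sourceBox
        hm <- gradCamPP(trained$net, prepared[[i]]$sagittal,
                        prepared[[i]]$axial, targetClass = "agenesis",
                        view = view,
                        contentBox = mapBoxToRoi(rb, rb,
                                                 config$network$inputSize))
        gtr <- gtBoxesInRoi(ds$cases[[i]], prepared[[i]], view,
                            c("third_ventricle",
                              "lateral_ventricle_anterior_horn"),
                            config$network$inputSize)
        f <- topDecileMass(hm, gtr, dilatePx = 5)
        perView[[view]] <- c(perView[[view]], f)
        caseFracs <- c(caseFracs, f)
        bf <- bandFractions(band(hm))
        bandsAcc <- if (is.null(bandsAcc)) bf else bandsAcc + bf
        nMaps <- nMaps + 1
      }
      fracs <- c(fracs, mean(caseFracs, na.rm = TRUE))
    }
    list(localization = mean(fracs, na.rm = TRUE),
         localization_sagittal = mean(perView$sagittal, na.rm = TRUE),
         localization_axial = mean(perView$axial, na.rm = TRUE),
         n = length(fracs),
         band_fractions = if (is.null(bandsAcc)) NULL
                          else as.list(bandsAcc / max(nMaps, 1)))
  })
  toc("explain", t)

  report <- list(
    config_hash = fnvHash(list(nCases = config$nCases, seed = seed,
                               backbone = config$network$backbone,
                               epochs = config$train$maxEpochs)),
    seed = seed,
    n_cases = config$nCases,
    n_train = length(trainIdx), n_test = length(testIdx),
    class_weights = weights,
    detection = detEval,
    history = trained$history,
    metrics = asMetricsRow(rep),
    mean_alpha = mean(preds$alpha),
    explain = explain,
    timings = timings,
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write.csv(preds, file.path(outDir, "predictions.csv"), row.names = FALSE)
  }
  report$predictions <- preds
  report$net <- trained$net
  invisible(report)
}
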