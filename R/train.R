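# Patient-level splitting, the training loop (Adam, class-weighted
# cross-entropy, early stopping), and TTA-aggregated inference.

#' Training configuration
#'
#' Defaults follow the reference settings: Adam with learning rate 1e-3 and
#' betas (0.9, 0.999), batch size 32, a 70/30 patient-level split.
#'
#' @param learningRate Adam step size.
#' @param adamBetas c(beta1, beta2).
#' @param batchSize samples per update.
#' @param maxEpochs maximum training epochs.
#' @param earlyStopPatience epochs without validation-loss improvement before
#'   stopping.
#' @param splitFraction train fraction for \code{\link{splitPatientLevel}}.
#' @param seed master seed for all training randomness.
#' @return config list of class \code{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 1e-3, adamBetas = c(0.9, 0.999),
                        batchSize = 32, maxEpochs = 10,
                        earlyStopPatience = 5, splitFraction = 0.7,
                        seed = 1L) {
  stopIfNot(splitFraction > 0 && splitFraction < 1,
            "splitFraction must be in (0,1)")
  stopIfNot(batchSize >= 1, "batchSize must be >= 1")
  structure(list(learningRate = learningRate, adamBetas = adamBetas,
                 batchSize = batchSize, maxEpochs = maxEpochs,
                 earlyStopPatience = earlyStopPatience,
                 splitFraction = splitFraction, seed = seed),
            class = "TrainConfig")
}

#' Stratified patient-level train/test split
#'
#' Produces disjoint sets covering all cases, stratified by label. The train
#' size is \code{round(fraction * n)} overall; per-class quotas are assigned
#' by largest-remainder apportionment (so e.g. 496 cases with 445/51 class
#' counts split at 0.7 into 347 = 311 + 36 training cases), then adjusted so
#' both classes appear on both sides.
#'
#' @param caseIds unique case identifiers.
#' @param labels class labels aligned with \code{caseIds}.
#' @param fraction train fraction.
#' @param seed split seed.
#' @return list(train, test) of case-id character vectors.
#' @export
splitPatientLevel <- function(caseIds, labels, fraction = 0.7, seed = 1L) {
  stopIfNot(!anyDuplicated(caseIds), "case ids must be unique")
  tab <- table(labels)
  if (any(tab < 2))
    stop("each class needs at least 2 cases to split", call. = FALSE)
  n <- length(caseIds)
  total <- round(fraction * n)
  quota <- fraction * as.numeric(tab)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  # both classes must appear on both sides
  base <- pmin(pmax(base, 1), as.numeric(tab) - 1)
  classes <- names(tab)
  train <- character(0)
  withSeed(seed, {
    for (i in seq_along(classes)) {
      ids <- caseIds[labels == classes[i]]
      train <- c(train, sample(ids, base[i]))
    }
  })
  list(train = sort(train), test = sort(setdiff(caseIds, train)))
}

evalLoss <- function(cfg, p, pairs, labels, weights, idx) {
  probs <- matrix(NA_real_, length(idx), 2)
  for (j in seq_along(idx)) {
    i <- idx[j]
    fw <- fullFwd(cfg, p, asInputArray(pairs[[i]]$sagittal, cfg),
                  asInputArray(pairs[[i]]$axial, cfg), train = FALSE)
    probs[j, ] <- fw$probs
  }
  weightedCeLoss(probs, labels[idx], weights)
}

#' Train an ADFNet on ROI pairs
#'
#' Mini-batch Adam on the class-weighted cross-entropy, with early stopping
#' monitored on a held-out 10 percent of the training cases (stratified).
#' All randomness (validation split, shuffling, dropout) flows from
#' \code{config$seed}; the parameters giving the best validation loss are
#' restored at the end.
#'
#' @param net an \linkS4class{ADFNet}; its parameters are updated in place.
#' @param pairs list of \code{list(sagittal, axial)} matrices at the
#'   classifier input size.
#' @param labels "normal"/"agenesis" per pair.
#' @param config a \code{\link{trainConfig}}.
#' @param weights class weights; default computed from the label counts via
#'   \code{\link{computeClassWeights}}.
#' @param valFraction held-out fraction of the training set for early
#'   stopping.
#' @param verbose print per-epoch losses.
#' @return list(net, history, valIds) with history a data.frame of per-epoch
#'   mean train and validation loss.
#' @export
trainAdfnet <- function(net, pairs, labels, config = trainConfig(),
                        weights = NULL, valFraction = 0.1, verbose = FALSE) {
  stopIfNot(length(pairs) == length(labels), "pairs/labels length mismatch")
  stopIfNot(all(c("normal", "agenesis") %in% labels),
            "training set must contain both classes")
  cfg <- net@config
  if (is.null(weights))
    weights <- computeClassWeights(sum(labels == "normal"),
                                   sum(labels == "agenesis"))
  ids <- as.character(seq_along(pairs))
  vs <- splitPatientLevel(ids, labels, 1 - valFraction,
                          seed = deriveSeed(config$seed, 777))
  trainIdx <- as.integer(vs$train); valIdx <- as.integer(vs$test)
  p <- net@params$p
  st <- adamInit(p)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, p = p, epoch = 0)
  wait <- 0
  withSeed(config$seed, {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample(trainIdx)
      epochLoss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = config$batchSize)) {
        batch <- ord[start:min(start + config$batchSize - 1, length(ord))]
        sumW <- sum(ifelse(labels[batch] == "agenesis",
                           weights$w_agenesis, weights$w_normal))
        gacc <- NULL
        batchLoss <- 0
        for (i in batch) {
          fw <- fullFwd(cfg, p, asInputArray(pairs[[i]]$sagittal, cfg),
                        asInputArray(pairs[[i]]$axial, cfg),
                        train = TRUE)
          y <- if (labels[i] == "agenesis") 2L else 1L
          w <- if (labels[i] == "agenesis") weights$w_agenesis else weights$w_normal
          onehot <- c(0, 0); onehot[y] <- 1
          fw$dlogits <- (w / sumW) * (fw$probs - onehot)
          batchLoss <- batchLoss - w * log(max(fw$probs[y], 1e-12))
          bw <- fullBwd(cfg, p, fw)
          gacc <- gradAdd(gacc, bw$grads)
        }
        if (!is.finite(batchLoss))
          stop("training aborted: non-finite loss in epoch ", epoch,
               call. = FALSE)
        upd <- adamStep(p, gacc, st, lr = config$learningRate,
                        beta1 = config$adamBetas[1],
                        beta2 = config$adamBetas[2])
        p <- upd$p; st <- upd$state
        epochLoss <- epochLoss + batchLoss / sumW; nb <- nb + 1
      }
      valLoss <- evalLoss(cfg, p, pairs, labels, weights, valIdx)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = epochLoss / nb,
                                  val_loss = valLoss))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        epochLoss / nb, valLoss))
      if (valLoss < best$loss - 1e-6) {
        best <- list(loss = valLoss, p = p, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$earlyStopPatience) break
      }
    }
  })
  net@params$p <- best$p
  list(net = net, history = history,
       valIds = valIdx, bestEpoch = best$epoch)
}

#' TTA-aggregated prediction for one case
#'
#' Generates \code{k} augmented variants of the view pair (shared geometric
#' and photometric draws across the two views of a variant), runs the
#' classifier in eval mode on each, and aggregates by the arithmetic mean of
#' the softmax vectors. The original images are never modified.
#'
#' @param net a trained \linkS4class{ADFNet}.
#' @param pair \code{list(sagittal, axial)} matrices at the classifier input
#'   size.
#' @param k number of variants (default 5).
#' @param params an \code{\link{augmentationParams}}.
#' @param seed TTA seed.
#' @return list of class \code{TTAResult}: \code{variantProbs} (k x 2
#'   matrix), \code{aggregate} (a \linkS4class{Prediction}), \code{k}.
#' @export
predictTta <- function(net, pair, k = 5, params = augmentationParams(),
                       seed = 1L) {
  stopIfNot(k >= 1, "argument error: k must be >= 1")
  probs <- matrix(NA_real_, k, 2)
  alphas <- numeric(k)
  for (i in seq_len(k)) {
    aug <- augmentPair(pair$sagittal, pair$axial, params,
                       seed = deriveSeed(seed, i))
    pred <- predictCase(net, aug$sagittal, aug$axial, mode = "eval")
    probs[i, ] <- c(pred@probNormal, pred@probAgenesis)
    alphas[i] <- pred@alphaUsed
  }
  agg <- colMeans(probs)
  structure(list(variantProbs = probs,
                 aggregate = new("Prediction", probNormal = agg[1],
                                 probAgenesis = agg[2],
                                 predictedLabel = c("normal", "agenesis")[which.max(agg)],
                                 alphaUsed = mean(alphas)),
                 k = k), class = "TTAResult")
}
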