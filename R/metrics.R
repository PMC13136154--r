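# Confusion-matrix metrics, ROC/AUC (tie-aware Mann-Whitney), class-wise
# sensitivity/specificity and balanced accuracy, and the clinician-AI
# collaborative score fusion. The positive class is agenesis throughout.

#' Confusion counts from probabilistic predictions
#'
#' Agenesis is the positive class; a case is predicted positive when
#' \code{probAgenesis >= threshold} (boundary inclusive toward agenesis, the
#' safer screening direction).
#'
#' @param probAgenesis numeric vector of agenesis probabilities.
#' @param labels "normal"/"agenesis", aligned.
#' @param threshold decision threshold (default 0.5).
#' @return list(tp, tn, fp, fn).
#' @export
confusionCounts <- function(probAgenesis, labels, threshold = 0.5) {
  stopIfNot(length(probAgenesis) == length(labels),
            "argument error: length mismatch")
  stopIfNot(length(labels) > 0, "argument error: empty input")
  predPos <- probAgenesis >= threshold
  actPos <- labels == "agenesis"
  list(tp = sum(predPos & actPos), tn = sum(!predPos & !actPos),
       fp = sum(predPos & !actPos), fn = sum(!predPos & actPos))
}

#' Derived classification metrics
#'
#' Accuracy, recall, precision and F1 from the confusion counts, plus
#' class-wise sensitivity (agenesis) = recall, specificity (normal) =
#' TN/(TN+FP), and balanced accuracy = their arithmetic mean. Metrics with a
#' zero denominator are reported as 0 and named in the \code{undefined} slot.
#'
#' @param counts list(tp, tn, fp, fn) (e.g. from
#'   \code{\link{confusionCounts}}).
#' @param auc optional AUC to carry in the report.
#' @return a \linkS4class{MetricsReport}.
#' @export
metrics <- function(counts, auc = NA_real_) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  stopIfNot(total > 0, "argument error: all-zero counts")
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(0) }
    num / den
  }
  acc <- (tp + tn) / total
  rec <- safe(tp, tp + fn, "recall")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (rec + prec == 0) { undef <- c(undef, "f1"); 0 } else
    2 * rec * prec / (rec + prec)
  spec <- safe(tn, tn + fp, "specificity_normal")
  new("MetricsReport", tp = tp, tn = tn, fp = fp, fn = fn, accuracy = acc,
      precision = prec, recall = rec, f1 = f1, auc = auc,
      sensitivityAgenesis = rec, specificityNormal = spec,
      balancedAccuracy = (rec + spec) / 2, undefined = undef)
}

#' Balanced accuracy from a sensitivity/specificity pair
#'
#' The arithmetic mean of class-wise sensitivity and specificity, on
#' whatever scale the inputs use (fractions or percent).
#'
#' @param sensitivity,specificity class-wise rates.
#' @return their mean.
#' @export
balancedAccuracy <- function(sensitivity, specificity)
  (sensitivity + specificity) / 2

#' ROC AUC (tie-aware Mann-Whitney)
#'
#' Equals the Mann-Whitney U statistic normalized by
#' \code{nPos * nNeg}, counting ties as one half — identical to trapezoidal
#' ROC integration for distinct scores and well-defined under ties.
#'
#' @param scores numeric scores (higher = more agenesis-like).
#' @param labels "normal"/"agenesis"; both classes must be present.
#' @return AUC in [0,1].
#' @export
rocAuc <- function(scores, labels) {
  pos <- labels == "agenesis"
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' A clinician's reading of one case
#'
#' @param diagnosis "normal" or "agenesis".
#' @param confidence subjective certainty in [0,1].
#' @return list of class \code{ClinicianReading}.
#' @export
clinicianReading <- function(diagnosis = c("normal", "agenesis"),
                             confidence) {
  diagnosis <- match.arg(diagnosis)
  stopIfNot(confidence >= 0 && confidence <= 1,
            "argument error: confidence must be in [0,1]")
  structure(list(diagnosis = diagnosis, confidence = confidence),
            class = "ClinicianReading")
}

#' Collaboration mode
#'
#' The AI-dominant mode for junior readers weights the AI probability 0.7
#' against 0.3 clinician confidence; the balanced mode for senior readers
#' weights them 0.5/0.5.
#'
#' @param mode "junior" or "senior".
#' @return list(mode, aiWeight, clinicianWeight) of class \code{CollabMode}.
#' @export
collabMode <- function(mode = c("junior", "senior")) {
  mode <- match.arg(mode)
  aiWeight <- if (mode == "junior") 0.7 else 0.5
  structure(list(mode = mode, aiWeight = aiWeight,
                 clinicianWeight = 1 - aiWeight), class = "CollabMode")
}

#' Clinician-AI collaborative score fusion
#'
#' The clinician's reading is converted to an agenesis probability
#' (\code{confidence} if the diagnosis is agenesis, else
#' \code{1 - confidence}) and fused with the AI probability:
#' \code{fused = aiWeight * aiProb + (1 - aiWeight) * pClinician}. The
#' decision is agenesis when the fused score reaches 0.5 (boundary
#' inclusive).
#'
#' @param aiProbAgenesis AI agenesis probability in [0,1].
#' @param reading a \code{\link{clinicianReading}}.
#' @param mode a \code{\link{collabMode}}.
#' @return list(score, decision, pClinician).
#' @export
collabScore <- function(aiProbAgenesis, reading, mode = collabMode("junior")) {
  stopIfNot(aiProbAgenesis >= 0 && aiProbAgenesis <= 1,
            "argument error: aiProbAgenesis must be in [0,1]")
  pC <- if (reading$diagnosis == "agenesis") reading$confidence
        else 1 - reading$confidence
  fused <- mode$aiWeight * aiProbAgenesis + mode$clinicianWeight * pC
  list(score = fused,
       decision = if (fused >= 0.5) "agenesis" else "normal",
       pClinician = pC)
}

#' Simulate clinician-AI collaboration
#'
#' A simulation harness for reader-study-style comparisons: per case, AI and
#' clinician are independently correct with their stated accuracies and emit
#' calibrated confidences (drawn uniformly in [0.7, 1] for the asserted
#' class), the readings are fused per mode, and accuracies of AI-alone,
#' clinician-alone and the fused decision are reported.
#'
#' @param nCases number of simulated cases.
#' @param aiAccuracy,clinicianAccuracy accuracies in (0.5, 1].
#' @param mode a \code{\link{collabMode}}.
#' @param prevalence fraction of agenesis cases.
#' @param seed simulation seed.
#' @return data.frame(group, accuracy, ai_weight, clinician_weight) with rows
#'   ai_alone, clinician_alone, fused.
#' @export
simulateCollaboration <- function(nCases, aiAccuracy, clinicianAccuracy,
                                  mode = collabMode("senior"),
                                  prevalence = 0.5, seed = 1L) {
  stopIfNot(aiAccuracy > 0.5 && aiAccuracy <= 1 &&
            clinicianAccuracy > 0.5 && clinicianAccuracy <= 1,
            "accuracies must be in (0.5, 1]")
  withSeed(seed, {
    truth <- ifelse(runif(nCases) < prevalence, "agenesis", "normal")
    aiCorrect <- runif(nCases) < aiAccuracy
    clCorrect <- runif(nCases) < clinicianAccuracy
    conf <- runif(nCases, 0.7, 1)      # AI confidence for its asserted class
    clConf <- runif(nCases, 0.7, 1)
    aiLabel <- ifelse(aiCorrect, truth,
                      ifelse(truth == "normal", "agenesis", "normal"))
    clLabel <- ifelse(clCorrect, truth,
                      ifelse(truth == "normal", "agenesis", "normal"))
    aiProb <- ifelse(aiLabel == "agenesis", conf, 1 - conf)
    fusedLabel <- character(nCases)
    for (i in seq_len(nCases)) {
      res <- collabScore(aiProb[i],
                         clinicianReading(clLabel[i], clConf[i]), mode)
      fusedLabel[i] <- res$decision
    }
    data.frame(
      group = c("ai_alone", "clinician_alone", "fused"),
      accuracy = c(mean(aiLabel == truth), mean(clLabel == truth),
                   mean(fusedLabel == truth)),
      ai_weight = mode$aiWeight, clinician_weight = mode$clinicianWeight,
      stringsAsFactors = FALSE)
  })
}
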