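test_that("confusion counting treats agenesis as the positive class", {
  probs <- c(0.9, 0.8, 0.7, rep(0.1, 7))
  labels <- c(rep("agenesis", 3), rep("normal", 7))
  cc <- confusionCounts(probs, labels)
  expect_equal(cc, list(tp = 3, tn = 7, fp = 0, fn = 0))
  flipped <- confusionCounts(1 - probs, labels)
  expect_equal(flipped, list(tp = 0, tn = 0, fp = 7, fn = 3))
  allPos <- confusionCounts(probs, labels, threshold = 0)
  expect_equal(allPos$tn + allPos$fn, 0)
  expect_error(confusionCounts(probs, labels[1:3]), "length")
})

test_that("derived metrics match hand arithmetic and flag zero denominators", {
  r <- metrics(list(tp = 9, tn = 85, fp = 3, fn = 3))
  expect_equal(r@accuracy, 0.94)
  expect_equal(r@precision, 0.75)
  expect_equal(r@recall, 0.75)
  expect_equal(r@f1, 0.75)
  perfect <- metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  for (slot in c("accuracy", "precision", "recall", "f1",
                 "sensitivityAgenesis", "specificityNormal",
                 "balancedAccuracy"))
    expect_equal(slot(perfect, slot), 1.0)
  noPos <- metrics(list(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(all(c("recall", "precision") %in% noPos@undefined))
  expect_error(metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "all-zero")
})

test_that("metrics agree with brute-force recounts on random prediction sets", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    probs <- runif(n)
    labels <- sample(c("normal", "agenesis"), n, replace = TRUE)
    r <- metrics(confusionCounts(probs, labels))
    o <- recountMetrics(probs, labels)
    expect_equal(c(r@tp, r@tn, r@fp, r@fn),
                 unname(o[c("tp", "tn", "fp", "fn")]))
    expect_equal(r@accuracy, unname(o["accuracy"]))
    expect_equal(r@f1, unname(o["f1"]))
    expect_equal(r@balancedAccuracy, unname(o["balanced"]))
    expect_identical(r@balancedAccuracy,
                     (r@sensitivityAgenesis + r@specificityNormal) / 2)
  }
})

test_that("balanced accuracy recovers the reference cohort class-wise summaries", {
  # reference values are rounded half-up to 4 decimals; assert to half an ulp
  expect_lt(abs(balancedAccuracy(0.9762, 0.9655) - 0.9709), 5e-5 + 1e-12)
  expect_lt(abs(balancedAccuracy(0.9750, 0.9808) - 0.9779), 5e-5 + 1e-12)
})

test_that("AUC equals exhaustive pair counting and respects ties", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1),
                      c("agenesis", "agenesis", "normal", "normal")), 1.0)
  expect_equal(rocAuc(rep(0.5, 6),
                      c("agenesis", "normal", "agenesis",
                        "normal", "normal", "normal")), 0.5)
  set.seed(32)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    labels <- c("agenesis", "normal",
                sample(c("normal", "agenesis"), n - 2, replace = TRUE))
    scores <- round(runif(n), 1)            # coarse grid forces ties
    expect_equal(rocAuc(scores, labels), pairAuc(scores, labels),
                 tolerance = 1e-15)
    # invariance under strictly monotone transforms
    expect_equal(rocAuc(exp(3 * scores), labels), rocAuc(scores, labels))
  }
  expect_error(rocAuc(c(1, 2), c("normal", "normal")), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(33)
  scores <- runif(40)
  labels <- sample(c("normal", "agenesis"), 40, replace = TRUE,
                   prob = c(0.7, 0.3))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(labels, levels = c("normal", "agenesis")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(rocAuc(scores, labels), ref, tolerance = 1e-12)
})

test_that("collaborative fusion follows the junior/senior mode weighting", {
  junior <- collabMode("junior"); senior <- collabMode("senior")
  expect_equal(junior$aiWeight + junior$clinicianWeight, 1)
  r <- collabScore(0.9, clinicianReading("agenesis", 0.5), junior)
  expect_equal(r$score, 0.78)
  expect_equal(r$decision, "agenesis")
  r2 <- collabScore(0.6, clinicianReading("agenesis", 0.4), senior)
  expect_equal(r2$score, 0.5)
  expect_equal(r2$decision, "agenesis")       # boundary inclusive
  # convexity fixed point
  r3 <- collabScore(0.3, clinicianReading("agenesis", 0.3), senior)
  expect_equal(r3$score, 0.3)
  expect_error(collabScore(1.4, clinicianReading("normal", 0.5)), "aiProb")
  expect_error(clinicianReading("normal", 1.2), "confidence")
})

test_that("fused score is monotone and mode shifts weight to the clinician", {
  reading <- clinicianReading("agenesis", 0.8)
  s <- vapply(seq(0, 1, 0.1), function(p)
    collabScore(p, reading, collabMode("junior"))$score, numeric(1))
  expect_true(all(diff(s) > 0))
  jr <- collabScore(0.2, reading, collabMode("junior"))
  sr <- collabScore(0.2, reading, collabMode("senior"))
  expect_gt(abs(jr$score - jr$pClinician), abs(sr$score - sr$pClinician))
})

test_that("a perfect confident clinician dominates balanced-mode fusion", {
  set.seed(34)
  n <- 200
  truth <- sample(c("normal", "agenesis"), n, replace = TRUE)
  # AI correct-class probability bounded away from extreme wrong values
  aiProb <- ifelse(truth == "agenesis", runif(n, 0.5, 1), runif(n, 0, 0.5))
  ok <- vapply(seq_len(n), function(i) {
    d <- collabScore(aiProb[i], clinicianReading(truth[i], 1),
                     collabMode("senior"))$decision
    d == truth[i]
  }, logical(1))
  expect_true(all(ok))
})

test_that("collaboration simulation reports calibrated group accuracies", {
  tab <- simulateCollaboration(4000, 0.9, 0.9, collabMode("senior"), seed = 2)
  expect_setequal(tab$group, c("ai_alone", "clinician_alone", "fused"))
  expect_equal(unique(tab$ai_weight + tab$clinician_weight), 1)
  expect_equal(tab$accuracy[tab$group == "ai_alone"], 0.9,
               tolerance = 0.03)
  t2 <- simulateCollaboration(4000, 0.9, 0.9, collabMode("senior"), seed = 2)
  expect_identical(tab, t2)
  expect_error(simulateCollaboration(100, 0.4, 0.9), "accuracies")
})
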