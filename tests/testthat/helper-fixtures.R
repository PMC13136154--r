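# Shared fixtures: everything is generated in code at test time.

# Zero-pose config: anatomy rendered in the canonical frame (no similarity
# jitter), handy when a test needs exact geometry.
canonicalConfig <- function(...) {
  phantomConfig(poseRotationLimit = 0, poseTranslationLimit = 0, ...)
}

# A small desk-scale network for engine tests (input 32x32 keeps a forward
# pass in the millisecond range).
deskNet <- function(inputSize = 32, seed = 5) {
  adfnet(networkConfig("tiny", inputSize = inputSize), seed = seed)
}

randPatch <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n, 0, 255), n, n)
}

# Brute-force IoU by rasterizing both boxes on a pixel grid and counting.
rasterIou <- function(p, g) {
  w <- max(p@xMax, g@xMax) + 1
  h <- max(p@yMax, g@yMax) + 1
  mp <- matrix(FALSE, h, w); mg <- matrix(FALSE, h, w)
  mp[(p@yMin + 1):p@yMax, (p@xMin + 1):p@xMax] <- TRUE
  mg[(g@yMin + 1):g@yMax, (g@xMin + 1):g@xMax] <- TRUE
  sum(mp & mg) / sum(mp | mg)
}

randomBox <- function(maxC = 60) {
  x <- sort(sample(0:maxC, 2)); y <- sort(sample(0:maxC, 2))
  if (x[1] == x[2]) x[2] <- x[2] + 1
  if (y[1] == y[2]) y[2] <- y[2] + 1
  boundingBox(x[1], y[1], x[2], y[2])
}

# Brute-force AUC by exhaustive pair counting (ties count one half).
pairAuc <- function(scores, labels) {
  pos <- which(labels == "agenesis"); neg <- which(labels == "normal")
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force metric recount straight from prediction/label vectors.
recountMetrics <- function(probA, labels, threshold = 0.5) {
  pred <- ifelse(probA >= threshold, "agenesis", "normal")
  tp <- sum(pred == "agenesis" & labels == "agenesis")
  tn <- sum(pred == "normal" & labels == "normal")
  fp <- sum(pred == "agenesis" & labels == "normal")
  fn <- sum(pred == "normal" & labels == "agenesis")
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  c(tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / length(labels), recall = rec, precision = prec,
    f1 = if (rec + prec > 0) 2 * rec * prec / (rec + prec) else 0,
    specificity = spec, balanced = (rec + spec) / 2)
}

# Build a network whose target logit is (a positive multiple of) the spatial
# mean of one final-stage channel of the sagittal stream: the Grad-CAM++
# closed-form limit.
linearScoreNet <- function(channel = 3, inputSize = 32) {
  net <- deskNet(inputSize = inputSize, seed = 21)
  p <- net@params$p
  D <- length(p$fc1$b)
  p$gate$w[] <- 0; p$gate$b <- 0              # alpha fixed at 0.5
  p$cvfim$sag$w[] <- 0; p$cvfim$sag$b[] <- 0
  p$cvfim$cor$w[] <- 0; p$cvfim$cor$b[] <- 0
  p$fc1$w[] <- 0
  p$fc1$w[channel, 1] <- 1                    # h1[1] = fused[channel] >= 0
  p$fc1$b[] <- 0
  p$fc2$w[] <- 0
  p$fc2$w[1, 2] <- 1                          # agenesis logit = h1[1]
  p$fc2$b[] <- 0
  net@params$p <- p
  net
}

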