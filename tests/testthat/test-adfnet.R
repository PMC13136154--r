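test_that("CVFIM limit cases follow the gating equation", {
  set.seed(1)
  fs <- array(runif(4 * 4 * 3), c(4, 4, 3))
  fc <- array(runif(4 * 4 * 3), c(4, 4, 3))
  # zero phi: gate = sigmoid(0) = 0.5 everywhere -> exact x1.5 scaling
  out <- cvfim(fs, fc)
  expect_equal(out$fSag, 1.5 * fs, tolerance = 1e-15)
  expect_equal(out$fCor, 1.5 * fc, tolerance = 1e-15)
  # arbitrary phi: residual form keeps F' within [F, 2F] for F >= 0
  phi <- list(w = matrix(rnorm(9), 3, 3), b = rnorm(3))
  out2 <- cvfim(fs, fc, phiSag = phi, phiCor = phi)
  expect_true(all(out2$fSag >= fs & out2$fSag <= 2 * fs))
  expect_error(cvfim(fs, array(0, c(4, 4, 2))), "dimensions")
})

test_that("CVFIM hand-set 2x2 case reproduces elementwise arithmetic", {
  fs <- array(c(1, 3, 2, 4), c(2, 2, 1))      # [[1,2],[3,4]] row-major
  fc <- array(0, c(2, 2, 1))
  out <- cvfim(fs, fc)                        # zero phi -> gate 0.5
  expect_equal(out$fSag[, , 1], matrix(c(1.5, 4.5, 3, 6), 2, 2))
})

test_that("fusion is the stated convex combination", {
  set.seed(2)
  vs <- rnorm(8); vc <- rnorm(8)
  expect_identical(fuse(vs, vc, 1), vs)
  expect_identical(fuse(vs, vc, 0), vc)
  expect_equal(fuse(vs, vs, 0.37), vs)
  for (a in runif(10)) {
    f <- fuse(vs, vc, a)
    expect_true(all(f >= pmin(vs, vc) - 1e-12 & f <= pmax(vs, vc) + 1e-12))
  }
  expect_error(fuse(vs, vc[1:3], 0.5), "length")
  expect_error(fuse(vs, vc, 1.2), "alpha")
})

test_that("the alpha gate is sigmoid-bounded and 0.5 at zero parameters", {
  set.seed(3)
  vs <- rnorm(16); vc <- rnorm(16)
  expect_equal(computeAlpha(vs, vc), 0.5)
  g <- list(w = rnorm(32), b = rnorm(1))
  a <- computeAlpha(vs, vc, g)
  expect_true(a > 0 && a < 1)
})

test_that("class weights reproduce the reference imbalance ratio", {
  w <- computeClassWeights(311, 36)
  expect_equal(w$w_normal, 1.0)
  expect_equal(round(w$w_agenesis, 2), 8.64)
  expect_equal(computeClassWeights(100, 25)$w_agenesis, 4.0)
  expect_equal(computeClassWeights(50, 50)$w_agenesis, 1.0)
  expect_error(computeClassWeights(10, 0), "zero agenesis")
})

test_that("weighted cross-entropy matches closed forms", {
  expect_equal(weightedCeLoss(c(0, 1), "agenesis"), 0, tolerance = 1e-9)
  expect_equal(weightedCeLoss(c(0.5, 0.5), "normal"), log(2))
  w <- computeClassWeights(311, 36)
  expect_equal(weightedCeLoss(c(0.5, 0.5), "agenesis", w, normalize = FALSE),
               (311 / 36) * log(2))
  # all weights 1 reduces exactly to mean cross-entropy
  set.seed(4)
  probsA <- runif(20, 0.05, 0.95)
  probs <- cbind(1 - probsA, probsA)
  labels <- sample(c("normal", "agenesis"), 20, replace = TRUE)
  plain <- mean(-log(ifelse(labels == "agenesis", probs[, 2], probs[, 1])))
  expect_equal(weightedCeLoss(probs, labels), plain, tolerance = 1e-12)
  # zero probability is clamped, not infinite
  expect_true(is.finite(weightedCeLoss(c(1, 0), "agenesis")))
})

test_that("eval-mode forward is a pure deterministic function", {
  net <- deskNet()
  a <- randPatch(32, seed = 5); b <- randPatch(32, seed = 6)
  p1 <- predictCase(net, a, b)
  p2 <- predictCase(net, a, b)
  expect_identical(p1@probNormal, p2@probNormal)
  expect_equal(p1@probNormal + p1@probAgenesis, 1, tolerance = 1e-6)
  expect_true(p1@alphaUsed > 0 && p1@alphaUsed < 1)
  expect_error(predictCase(net, randPatch(16), b), "argument error")
})

test_that("probabilities sum to one across random parameter draws", {
  a <- randPatch(32, seed = 7); b <- randPatch(32, seed = 8)
  for (s in 1:5) {
    net <- deskNet(seed = 100 + s)
    p <- predictCase(net, a, b)
    expect_equal(p@probNormal + p@probAgenesis, 1, tolerance = 1e-6)
    expect_true(p@probNormal >= 0 && p@probAgenesis >= 0)
  }
})

test_that("fixed-gate CVFIM scales insertion-stage features by exactly 1.5", {
  net <- deskNet()
  a <- randPatch(32, seed = 9); b <- randPatch(32, seed = 10)
  off <- ccfocus:::featureMaps(net, a, b, cvfimMode = "off")
  fixed <- ccfocus:::featureMaps(net, a, b, cvfimMode = "fixed")
  expect_equal(fixed$atCvfim$sag, 1.5 * off$atCvfim$sag, tolerance = 1e-12)
  expect_equal(fixed$atCvfim$cor, 1.5 * off$atCvfim$cor, tolerance = 1e-12)
  # zero-initialized phi reproduces the fixed gate exactly
  on <- ccfocus:::featureMaps(net, a, b, cvfimMode = "on")
  expect_equal(on$atCvfim$sag, fixed$atCvfim$sag, tolerance = 1e-12)
})

test_that("one training step sends gradient to every parameter group", {
  net <- deskNet()
  cfg <- net@config
  xs <- array(randPatch(32, seed = 11) / 255, c(32, 32, 1))
  xc <- array(randPatch(32, seed = 12) / 255, c(32, 32, 1))
  fw <- ccfocus:::fullFwd(cfg, net@params$p, xs, xc, train = FALSE)
  fw$dlogits <- fw$probs - c(0, 1)
  bw <- ccfocus:::fullBwd(cfg, net@params$p, fw)
  norms <- ccfocus:::gradGroupNorms(bw$grads)
  expect_named(norms, c("fc2", "fc1", "gate", "cvfim", "sag", "cor"),
               ignore.order = TRUE)
  expect_true(all(norms > 0))
})

test_that("checkpoints round-trip through JSON", {
  net <- deskNet(seed = 42)
  a <- randPatch(32, seed = 13); b <- randPatch(32, seed = 14)
  p1 <- predictCase(net, a, b)
  path <- withr::local_tempfile(fileext = ".json")
  saveAdfnet(net, path)
  net2 <- loadAdfnet(path)
  p2 <- predictCase(net2, a, b)
  expect_equal(p1@probNormal, p2@probNormal, tolerance = 1e-12)
  expect_equal(p1@alphaUsed, p2@alphaUsed, tolerance = 1e-12)
})
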