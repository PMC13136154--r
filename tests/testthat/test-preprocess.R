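test_that("homomorphic filter handles degenerate inputs and preserves shape", {
  const <- matrix(100, 32, 32)
  out <- homomorphicFilter(const)
  expect_equal(dim(out), c(32, 32))
  expect_lt(diff(range(out)), 1)          # constant within one level
  z <- homomorphicFilter(matrix(0, 16, 16))
  expect_true(all(is.finite(z)))
  expect_error(homomorphicFilter(matrix(c(1, NA), 2, 2)), "non-finite")
  expect_error(homomorphicFilter(const, lowGain = 1.2), "lowGain")
})

test_that("homomorphic filter reduces speckle coefficient of variation", {
  set.seed(42)
  field <- matrix(120 * rgamma(128 * 128, shape = 8, scale = 1 / 8), 128, 128)
  out <- homomorphicFilter(field)
  cvIn <- sd(field) / mean(field)
  cvOut <- sd(out) / mean(out)
  expect_lt(cvOut, cvIn)
  expect_true(all(out >= 0 & out <= 255))
})

test_that("homomorphic filter commutes with global intensity scaling", {
  set.seed(7)
  img <- matrix(80 + 40 * runif(64 * 64), 64, 64)
  a <- homomorphicFilter(img, eps = 0.01)
  b <- homomorphicFilter(3 * img, eps = 0.01)
  # log converts the scale to a DC offset, removed by the final rescale
  expect_lt(mean(abs(a - b)), 1)
})

test_that("canonical transform is identity for canonical-pose phantoms", {
  cs <- generateCase(canonicalConfig(), "normal", seed = 1)
  tf <- estimateCanonicalTransform(cs@sagittal)
  rot <- atan2(tf$m[2, 1], tf$m[1, 1]) * 180 / pi
  expect_lt(abs(rot), 1)
  ctr <- tf$m[, 1:2] %*% c(128, 128) + tf$m[, 3]   # anatomy center
  expect_lt(max(abs(ctr - 127.5)), 1)
  expect_equal(sqrt(det(tf$m[, 1:2])), 1, tolerance = 0.02)
})

test_that("a known pose is inverted within one degree and one pixel", {
  cfg <- phantomConfig()
  r <- ccfocus:::renderView(cfg, "sagittal", "normal",
                            list(rot = 8, tx = 5, ty = -3))
  set.seed(3)
  img <- pmin(pmax(r$base * matrix(rgamma(256^2, 12, 12), 256), 0), 255)
  tf <- estimateCanonicalTransform(img)
  rot <- atan2(tf$m[2, 1], tf$m[1, 1]) * 180 / pi
  expect_lt(abs(rot - (-8)), 1)
  mapped <- tf$m[, 1:2] %*% c(128 + 5, 128 - 3) + tf$m[, 3]
  expect_lt(max(abs(mapped - 127.5)), 1)
  # idempotence: canonicalize, re-estimate, get identity back
  cano <- canonicalize(img)
  tf2 <- estimateCanonicalTransform(cano$image)
  expect_lt(abs(atan2(tf2$m[2, 1], tf2$m[1, 1]) * 180 / pi), 1)
  expect_lt(max(abs(tf2$m[, 3] -
                      (diag(2) - tf2$m[, 1:2]) %*% c(127.5, 127.5))), 1.5)
})

test_that("missing outline raises a detection error naming the threshold", {
  expect_error(estimateCanonicalTransform(matrix(10, 64, 64)),
               "threshold 190")
})

test_that("letterbox resize follows the stated geometry", {
  sq <- randPatch(256, seed = 2)
  expect_identical(resizeLetterbox(sq, 256), sq)    # identity case, bitwise
  big <- randPatch(512, seed = 3)
  out <- resizeLetterbox(big, 256)
  expect_equal(dim(out), c(256, 256))
  expect_true(all(out[1, ] != 0))                   # no padding for square
  tall <- matrix(100, 512, 256)
  lb <- resizeLetterbox(tall, 256)
  expect_true(all(lb[, 1:64] == 0) && all(lb[, 193:256] == 0))
  expect_true(all(lb[, 65:192] > 0))
  expect_error(resizeLetterbox(matrix(numeric(0), 0, 0)), "empty")
})

test_that("augmentation is identity at zero limits and seeded-deterministic", {
  img <- randPatch(64, seed = 4)
  nullParams <- augmentationParams(rotationLimit = 0, brightnessLimit = 0,
                                   elasticSigma = 1, elasticAlpha = 0)
  expect_identical(augment(img, nullParams, seed = 1), img)
  p <- augmentationParams()
  a1 <- augment(img, p, seed = 9)
  a2 <- augment(img, p, seed = 9)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment(img, p, seed = 10)))
  expect_equal(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 255))
})

test_that("default augmentation changes phantom mean intensity by at most ~12%", {
  cs <- generateCase(phantomConfig(), "normal", seed = 5)
  p <- augmentationParams()
  for (s in 1:5) {
    a <- augment(cs@sagittal, p, seed = s)
    expect_lt(abs(mean(a) - mean(cs@sagittal)) / mean(cs@sagittal), 0.12)
  }
})

test_that("TTA variants leave the input untouched and are reproducible", {
  img <- randPatch(64, seed = 6)
  before <- img + 0
  v <- makeTtaVariants(img, k = 5, seed = 3)
  expect_length(v, 5)
  expect_identical(img, before)
  v2 <- makeTtaVariants(img, k = 5, seed = 3)
  expect_identical(v, v2)
  expect_error(makeTtaVariants(img, k = 0), "k must be")
})

test_that("canonicalize + filter reduces pose variance between same-anatomy pairs", {
  cfg <- phantomConfig()
  r1 <- ccfocus:::renderView(cfg, "sagittal", "normal",
                             list(rot = 7, tx = 6, ty = -4))
  r2 <- ccfocus:::renderView(cfg, "sagittal", "normal",
                             list(rot = -5, tx = -3, ty = 5))
  set.seed(11)
  i1 <- pmin(pmax(r1$base * matrix(rgamma(256^2, 12, 12), 256), 0), 255)
  i2 <- pmin(pmax(r2$base * matrix(rgamma(256^2, 12, 12), 256), 0), 255)
  rawDiff <- mean(abs(i1 - i2))
  p1 <- homomorphicFilter(canonicalize(i1)$image)
  p2 <- homomorphicFilter(canonicalize(i2)$image)
  expect_lt(mean(abs(p1 - p2)), rawDiff)
})
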