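test_that("iou matches hand arithmetic and rasterized counting", {
  a <- boundingBox(0, 0, 10, 10)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, boundingBox(20, 20, 30, 30)), 0.0)
  b <- boundingBox(5, 0, 15, 10)
  expect_equal(iou(a, b), 1 / 3)       # overlap 50, union 150
  set.seed(1)
  for (i in 1:60) {
    p <- randomBox(); g <- randomBox()
    expect_identical(iou(p, g), iou(g, p))
    expect_equal(iou(p, g), rasterIou(p, g))
    expect_true(iou(p, g) >= 0 && iou(p, g) <= 1)
    if (!identical(boxCoords(p), boxCoords(g))) expect_lt(iou(p, g), 1)
  }
  expect_error(iou(a, "box"), "argument error")
})

test_that("dynamic boundary expansion follows the 3-5 px rule", {
  shape <- c(256, 256)
  e4 <- expandBox(boundingBox(60, 80, 120, 110), shape, 4)
  expect_equal(unname(boxCoords(e4)), c(56, 76, 124, 114))
  clipped <- expandBox(boundingBox(1, 1, 20, 20), shape, 5)
  expect_equal(unname(boxCoords(clipped)), c(0, 0, 25, 25))
  # auto: 5% of the major dimension clamped into [3,5]
  wide <- expandBox(boundingBox(0, 0, 100, 10), shape, "auto")
  expect_equal(wide@xMin, 0)            # 0.05*100 = 5, clipped at border
  expect_equal(wide@xMax, 105)
  small <- expandBox(boundingBox(50, 50, 60, 60), shape, "auto")
  expect_equal(unname(boxCoords(small)), c(47, 47, 63, 63))   # clamp up to 3
  expect_error(expandBox(boundingBox(0, 0, 5, 5), shape, 2), "expansion")
  expect_error(expandBox(boundingBox(0, 0, 5, 5), shape, "full"), "expansion")
})

test_that("expansion is monotone and composes additively under clipping", {
  shape <- c(200, 200)
  set.seed(2)
  for (i in 1:40) {
    b <- randomBox(150)
    e <- sample(3:5, 1)
    ex <- expandBox(b, shape, e)
    expect_true(ex@xMin <= b@xMin && ex@yMin <= b@yMin &&
                ex@xMax >= b@xMax && ex@yMax >= b@yMax)
    # twice e vs once 2e (manual, outside the 3..5 public range)
    twice <- expandBox(expandBox(b, shape, e), shape, e)
    manual <- boundingBox(max(0, b@xMin - 2 * e), max(0, b@yMin - 2 * e),
                          min(shape[2], b@xMax + 2 * e),
                          min(shape[1], b@yMax + 2 * e))
    expect_identical(boxCoords(twice), boxCoords(manual))
  }
})

test_that("cropRoi extracts the expanded half-open extent", {
  img <- randPatch(256, seed = 3)
  det <- new("Detection", box = boundingBox(60, 80, 120, 110),
             confidence = 0.9, structure = "cc")
  roi <- cropRoi(img, det, expansion = 4)
  expect_equal(dim(roi@patch), c(38, 68))          # rows x cols
  expect_equal(unname(boxCoords(roi@sourceBox)), c(56, 76, 124, 114))
  expect_identical(roi@patch, img[77:114, 57:124])
})

test_that("baseline detector finds the cc in normals and not in agenesis", {
  cfg <- phantomConfig()
  det <- matchedFilterDetector("sagittal", cfg)
  ious <- numeric(0)
  for (s in 1:10) {
    cs <- generateCase(cfg, "normal", seed = 400 + s)
    pv <- preprocessView(cs@sagittal, det)
    ccDet <- Filter(function(d) d@structure == "cc", pv$detections)
    expect_length(ccDet, 1)
    back <- mapBoxThroughAffine(ccDet[[1]]@box, pv$transform,
                                dim(cs@sagittal), inverse = TRUE)
    ious <- c(ious, iou(back, gtBoxes(cs, "sagittal")$cc))
  }
  expect_gte(mean(ious), 0.7)
  for (s in 1:10) {
    ca <- generateCase(cfg, "agenesis", seed = 500 + s)
    pva <- preprocessView(ca@sagittal, det)
    expect_length(Filter(function(d) d@structure == "cc", pva$detections), 0)
  }
  expect_length(detectStructures(matrix(0, 256, 256), det), 0)
})

test_that("detection evaluation averages per-structure IoU with misses as zero", {
  gt <- data.frame(case_id = c("a", "b"), structure = "cc",
                   x_min = 10, y_min = 10, x_max = 30, y_max = 30)
  predPerfect <- data.frame(case_id = c("a", "b"), structure = "cc",
                            x_min = 10, y_min = 10, x_max = 30, y_max = 30)
  r <- evaluateDetection(predPerfect, gt)
  expect_equal(r$mean_iou, 1.0)
  expect_equal(r$sd_iou, 0.0)
  r2 <- evaluateDetection(predPerfect[1, ], gt)    # one perfect, one missing
  expect_equal(r2$mean_iou, 0.5)
  expect_error(evaluateDetection(predPerfect, gt[0, ]), "empty")
})

test_that("jittered detection evaluation equals the rasterized oracle", {
  set.seed(9)
  gtBoxesL <- replicate(20, randomBox(80), simplify = FALSE)
  predBoxesL <- lapply(gtBoxesL, function(b) {
    d <- sample(-2:2, 4, replace = TRUE)
    boundingBox(max(0, b@xMin + d[1]), max(0, b@yMin + d[2]),
                max(b@xMin + d[1] + 1, b@xMax + d[3]),
                max(b@yMin + d[2] + 1, b@yMax + d[4]))
  })
  toDf <- function(bl) do.call(rbind, lapply(seq_along(bl), function(i)
    data.frame(case_id = paste0("c", i), structure = "cc",
               x_min = bl[[i]]@xMin, y_min = bl[[i]]@yMin,
               x_max = bl[[i]]@xMax, y_max = bl[[i]]@yMax)))
  r <- evaluateDetection(toDf(predBoxesL), toDf(gtBoxesL))
  oracle <- mean(mapply(rasterIou, predBoxesL, gtBoxesL))
  expect_equal(r$mean_iou, oracle, tolerance = 1e-12)
})

test_that("detect-expand-crop never leaves the image", {
  cfg <- phantomConfig()
  det <- matchedFilterDetector("axial", cfg)
  for (s in 1:5) {
    cs <- generateCase(cfg, sample(c("normal", "agenesis"), 1), seed = 600 + s)
    pv <- preprocessView(cs@axial, det)
    for (d in pv$detections) {
      roi <- cropRoi(pv$filtered, d, "auto", view = "axial")
      b <- roi@sourceBox
      expect_true(b@xMin >= 0 && b@yMin >= 0 &&
                  b@xMax <= 256 && b@yMax <= 256)
      expect_equal(dim(roi@patch),
                   c(b@yMax - b@yMin, b@xMax - b@xMin))
    }
  }
})
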