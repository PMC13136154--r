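test_that("generation is a pure function of (config, label, seed)", {
  cfg <- phantomConfig()
  a <- generateCase(cfg, "normal", seed = 7)
  b <- generateCase(cfg, "normal", seed = 7)
  expect_identical(a@sagittal, b@sagittal)
  expect_identical(a@axial, b@axial)
  expect_identical(lapply(gtBoxes(a, "sagittal"), boxCoords),
                   lapply(gtBoxes(b, "sagittal"), boxCoords))
  d1 <- generateDataset(cfg, 12, seed = 3)
  d2 <- generateDataset(cfg, 12, seed = 3)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$cases[[5]]@axial, d2$cases[[5]]@axial)
})

test_that("case invariants hold: labels, views, boxes", {
  cfg <- phantomConfig()
  for (seed in 1:5) {
    cn <- generateCase(cfg, "normal", seed = seed)
    ca <- generateCase(cfg, "agenesis", seed = seed)
    expect_identical(dim(cn@sagittal), dim(cn@axial))
    expect_false(is.null(gtBoxes(cn, "sagittal")$cc))
    expect_null(gtBoxes(ca, "sagittal")$cc)
    for (view in c("sagittal", "axial"))
      for (b in gtBoxes(cn, view)) {
        expect_true(b@xMax <= ncol(cn@sagittal) && b@yMax <= nrow(cn@sagittal))
        expect_true(b@xMin < b@xMax && b@yMin < b@yMax)
      }
    expect_true(all(cn@sagittal >= 0 & cn@sagittal <= 255))
  }
})

test_that("the normal sagittal view contains the dark callosal band", {
  cfg <- canonicalConfig()
  cn <- generateCase(cfg, "normal", seed = 2)
  r <- ccfocus:::renderView(cfg, "sagittal", "normal",
                            list(rot = 0, tx = 0, ty = 0))
  bandPix <- r$base[r$masks$cc]
  expect_true(all(bandPix < cfg@parenchymaMean))
  bb <- gtBoxes(cn, "sagittal")$cc
  # band enclosed by its ground-truth box
  idx <- which(r$masks$cc, arr.ind = TRUE)
  expect_true(min(idx[, 2]) - 1 >= bb@xMin && max(idx[, 2]) <= bb@xMax)
  expect_true(min(idx[, 1]) - 1 >= bb@yMin && max(idx[, 1]) <= bb@yMax)
  # agenesis render has no band layer at all; the midline stretch of the
  # band region (clear of the lateral ventricle and third ventricle) reverts
  # to parenchyma
  ra <- ccfocus:::renderView(cfg, "sagittal", "agenesis",
                             list(rot = 0, tx = 0, ty = 0))
  expect_null(ra$masks$cc)
  g <- ccfocus:::pixelGrid(256, 256)
  central <- r$masks$cc & abs(g$x - 128) <= 20
  expect_true(all(ra$base[central] >= cfg@parenchymaMean))
})

test_that("dataset prevalence follows the rounding rule", {
  cfg <- phantomConfig(prevalence = 0.1)
  d <- generateDataset(cfg, 100, seed = 1)
  expect_equal(sum(d$manifest$label == "agenesis"), 10)
  expect_equal(length(unique(d$manifest$case_id)), 100)
  d0 <- generateDataset(phantomConfig(prevalence = 0), 1, seed = 9)
  expect_equal(d0$manifest$label, "normal")
  expect_error(generateDataset(cfg, 0), "nCases")
})

test_that("speckle sd/mean decreases monotonically with looks", {
  cvs <- vapply(c(4, 12, 36), function(L) {
    cs <- generateCase(canonicalConfig(speckleLooks = L), "normal", seed = 3)
    patch <- cs@sagittal[156:180, 76:104]       # flat parenchyma region
    sd(patch) / mean(patch)
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
  # and the level tracks the gamma model 1/sqrt(L)
  expect_equal(cvs[1], 1 / sqrt(4), tolerance = 0.15)
})

test_that("matched-filter score separates the classes perfectly", {
  cfg <- canonicalConfig()
  r <- ccfocus:::renderView(cfg, "sagittal", "normal",
                            list(rot = 0, tx = 0, ty = 0))
  mask <- r$masks$cc
  bb <- ccfocus:::maskBox(mask)
  ring <- matrix(FALSE, 256, 256)
  ring[max(1, bb@yMin - 5):min(256, bb@yMax + 6),
       max(1, bb@xMin - 5):min(256, bb@xMax + 6)] <- TRUE
  ring <- ring & !mask
  score <- function(img) mean(img[mask]) - mean(img[ring])
  sNorm <- vapply(1:15, function(s)
    score(generateCase(cfg, "normal", seed = s)@sagittal), numeric(1))
  sAg <- vapply(1:15, function(s)
    score(generateCase(cfg, "agenesis", seed = 100 + s)@sagittal), numeric(1))
  expect_true(max(sNorm) < min(sAg))
})

test_that("agenesis widens ventricles by the dilation factor and shifts the third ventricle up", {
  cfg <- canonicalConfig()
  cn <- generateCase(cfg, "normal", seed = 4)
  ca <- generateCase(cfg, "agenesis", seed = 4)
  bn <- gtBoxes(cn, "axial")$lateral_ventricle_anterior_horn
  ba <- gtBoxes(ca, "axial")$lateral_ventricle_anterior_horn
  # horn ellipse half-width scales by the factor (union box spans both horns,
  # so compare heights, which are pure ellipse extents)
  ratio <- (ba@yMax - ba@yMin) / (bn@yMax - bn@yMin)
  expect_equal(ratio, cfg@ventricleDilationFactor, tolerance = 0.08)
  tvN <- gtBoxes(cn, "sagittal")$third_ventricle
  tvA <- gtBoxes(ca, "sagittal")$third_ventricle
  shift <- (tvN@yMin + tvN@yMax) / 2 - (tvA@yMin + tvA@yMax) / 2
  expect_equal(shift, cfg@thirdVentricleShift, tolerance = 1)
})

test_that("invalid configurations are rejected", {
  expect_error(phantomConfig(prevalence = 1.2), "prevalence")
  expect_error(phantomConfig(ventricleDilationFactor = 0.5), "ilation")
  expect_error(phantomConfig(skullEllipse = list(center = c(128, 128),
                                                 axes = c(140, 85),
                                                 angle = 0)),
               "bounds")
  expect_error(phantomConfig(ccBand = list(center = c(128, 135), radius = 45,
                                           thickness = 6,
                                           thetaRange = c(-160, -20),
                                           intensity = 95)),
               "darker")
})

test_that("written datasets round-trip through PNG and manifest", {
  dir <- withr::local_tempdir()
  d <- generateDataset(phantomConfig(), 3, seed = 2, outDir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  img <- readImage(d$manifest$sagittal_path[1])
  expect_equal(dim(img), c(256, 256))
  # 8-bit quantization only
  expect_lt(max(abs(img - round(d$cases[[1]]@sagittal))), 0.51)
})
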