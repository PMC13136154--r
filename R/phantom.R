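# Synthetic paired-plane fetal cranial ultrasound phantom.
#
# Anatomy is defined analytically in a canonical pose (ellipse / annulus-arc
# predicates over 0-based pixel coordinates) and evaluated at per-case
# similarity-transformed coordinates, so masks and ground-truth boxes are
# exact rather than resampled. Speckle is multiplicative gamma noise
# (shape = number of looks), the standard fully-developed B-mode model.

#' Construct a phantom generator configuration
#'
#' Defaults define the study conditions used throughout: 256x256 images,
#' 12-look speckle (coefficient of variation about 0.29), a hypoechoic
#' callosal band at intensity 40 against parenchyma 90 under a falx arc at
#' 200, 20 percent agenesis prevalence, and a random per-case pose of up to
#' 10 degrees rotation and 10 px translation.
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param speckleLooks gamma-speckle shape (larger = smoother).
#' @param ventricleDilationFactor ventricle axis multiplier in agenesis cases.
#' @param thirdVentricleShift upward third-ventricle displacement (px) in
#'   agenesis cases.
#' @param prevalence fraction of agenesis cases when generating a dataset.
#' @param poseRotationLimit,poseTranslationLimit per-case pose jitter limits
#'   (degrees / pixels).
#' @param seed default dataset seed.
#' @param skullEllipse,ccBand,falxIntensity,parenchymaMean advanced geometry
#'   overrides; see \linkS4class{PhantomConfig}.
#' @return A validated \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig()
#' case <- generateCase(cfg, "normal", seed = 7)
#' @export
phantomConfig <- function(imageHeight = 256, imageWidth = 256,
                          speckleLooks = 12,
                          skullEllipse = list(center = c(128, 128),
                                              axes = c(105, 85), angle = 0),
                          ccBand = list(center = c(128, 135), radius = 45,
                                        thickness = 6,
                                        thetaRange = c(-160, -20),
                                        intensity = 40),
                          falxIntensity = 200, parenchymaMean = 90,
                          ventricleDilationFactor = 1.6,
                          thirdVentricleShift = 25, prevalence = 0.2,
                          poseRotationLimit = 10, poseTranslationLimit = 10,
                          seed = 1L) {
  new("PhantomConfig", imageHeight = imageHeight, imageWidth = imageWidth,
      speckleLooks = speckleLooks, skullEllipse = skullEllipse,
      ccBand = ccBand, falxIntensity = falxIntensity,
      parenchymaMean = parenchymaMean,
      ventricleDilationFactor = ventricleDilationFactor,
      thirdVentricleShift = thirdVentricleShift, prevalence = prevalence,
      poseRotationLimit = poseRotationLimit,
      poseTranslationLimit = poseTranslationLimit, seed = seed)
}

ellipseInside <- function(x, y, cx, cy, ax, ay, angle = 0) {
  a <- angle * pi / 180
  u <- (x - cx) * cos(a) + (y - cy) * sin(a)
  v <- -(x - cx) * sin(a) + (y - cy) * cos(a)
  (u / ax)^2 + (v / ay)^2 <= 1
}

annulusArc <- function(x, y, cx, cy, r0, r1, th0, th1) {
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) * 180 / pi
  r >= r0 & r <= r1 & th >= th0 & th <= th1
}

# Layer list for one view: painted in order; layers flagged `structure` also
# contribute a ground-truth mask under the given name.
phantomLayers <- function(cfg, view, label) {
  dil <- if (label == "agenesis") cfg@ventricleDilationFactor else 1
  tvShift <- if (label == "agenesis") cfg@thirdVentricleShift else 0
  sk <- cfg@skullEllipse
  cc <- cfg@ccBand
  darkVent <- 55; wall <- 190; cavumInt <- 50; tvInt <- 45
  layers <- list()
  add <- function(name, type, par, intensity, structure = NA_character_) {
    layers[[length(layers) + 1L]] <<- list(name = name, type = type,
                                           par = par, intensity = intensity,
                                           structure = structure)
  }
  if (view == "sagittal") {
    lv <- list(c = c(165, 118), ax = c(20, 7) * dil, ang = -15)
    add("lv_wall", "ellipse",
        c(lv$c, lv$ax + 2.5, lv$ang), wall, "lateral_ventricle_anterior_horn")
    add("lv_in", "ellipse", c(lv$c, lv$ax, lv$ang), darkVent,
        "lateral_ventricle_anterior_horn")
    add("cavum", "ellipse", c(128, 150, 13, 7, 0), cavumInt,
        "cavum_septi_pellucidi")
    add("third_ventricle", "ellipse", c(128, 176 - tvShift, 7, 5, 0), tvInt,
        "third_ventricle")
    add("falx", "arc", c(cc$center, cc$radius + 6, cc$radius + 10,
                         cc$thetaRange), cfg@falxIntensity)
    if (label == "normal")
      add("cc", "arc", c(cc$center, cc$radius - cc$thickness / 2,
                         cc$radius + cc$thickness / 2, cc$thetaRange),
          cc$intensity, "cc")
  } else {
    add("midline", "ellipse", c(128, 120, 1.5, 70, 0), cfg@falxIntensity)
    add("lh_wall", "ellipse", c(104, 88, c(8, 16) * dil + 2.5, 12), wall,
        "lateral_ventricle_anterior_horn")
    add("lh_in", "ellipse", c(104, 88, c(8, 16) * dil, 12), darkVent,
        "lateral_ventricle_anterior_horn")
    add("rh_wall", "ellipse", c(152, 88, c(8, 16) * dil + 2.5, -12), wall,
        "lateral_ventricle_anterior_horn")
    add("rh_in", "ellipse", c(152, 88, c(8, 16) * dil, -12), darkVent,
        "lateral_ventricle_anterior_horn")
    add("cavum", "ellipse", c(128, 92, 10, 6, 0), cavumInt,
        "cavum_septi_pellucidi")
    add("third_ventricle", "ellipse", c(128, 126 - tvShift, 4, 9, 0), tvInt,
        "third_ventricle")
  }
  layers
}

layerMask <- function(layer, x, y) {
  p <- layer$par
  if (layer$type == "ellipse")
    ellipseInside(x, y, p[1], p[2], p[3], p[4], p[5])
  else
    annulusArc(x, y, p[1], p[2], p[3], p[4], p[5], p[6])
}

# Render one view's noise-free base image and structure masks at the given
# pose (rotation degrees, translation px applied to the canonical anatomy).
renderView <- function(cfg, view, label, pose) {
  h <- cfg@imageHeight; w <- cfg@imageWidth
  g <- pixelGrid(h, w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  a <- -pose$rot * pi / 180
  xs <- g$x - cx - pose$tx; ys <- g$y - cy - pose$ty
  xc <- xs * cos(a) - ys * sin(a) + cx
  yc <- xs * sin(a) + ys * cos(a) + cy
  sk <- cfg@skullEllipse
  inSkullOuter <- ellipseInside(xc, yc, sk$center[1], sk$center[2],
                                sk$axes[1], sk$axes[2], sk$angle)
  inBrain <- ellipseInside(xc, yc, sk$center[1], sk$center[2],
                           sk$axes[1] - 6, sk$axes[2] - 6, sk$angle)
  base <- matrix(12, h, w)
  base[inSkullOuter] <- 235          # skull ring ...
  base[inBrain] <- cfg@parenchymaMean  # ... then parenchyma interior
  masks <- list()
  for (layer in phantomLayers(cfg, view, label)) {
    m <- layerMask(layer, xc, yc) & inBrain
    base[m] <- layer$intensity
    if (!is.na(layer$structure)) {
      if (sum(m) == 0)
        stop("configuration error: structure '", layer$structure,
             "' lies outside the image/brain region", call. = FALSE)
      masks[[layer$structure]] <-
        if (is.null(masks[[layer$structure]])) m else masks[[layer$structure]] | m
    }
  }
  list(base = base, masks = masks)
}

#' Generate one phantom case
#'
#' Draws the shared latent anatomy at a random small similarity pose, renders
#' both views, applies multiplicative gamma speckle, and records tight
#' ground-truth boxes for each structure. Bitwise deterministic in
#' \code{(config, label, seed)}.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param label "normal" or "agenesis".
#' @param seed integer seed for this case.
#' @param caseId identifier stored on the case.
#' @return A \linkS4class{CasePair}.
#' @export
generateCase <- function(config, label = c("normal", "agenesis"), seed,
                         caseId = sprintf("case_seed%d", seed)) {
  label <- match.arg(label)
  validObject(config)
  withSeed(seed, {
    pose <- list(
      rot = runif(1, -config@poseRotationLimit, config@poseRotationLimit),
      tx = runif(1, -config@poseTranslationLimit, config@poseTranslationLimit),
      ty = runif(1, -config@poseTranslationLimit, config@poseTranslationLimit))
    views <- list()
    boxes <- list()
    for (view in c("sagittal", "axial")) {
      r <- renderView(config, view, label, pose)
      L <- config@speckleLooks
      speckle <- matrix(rgamma(length(r$base), shape = L, scale = 1 / L),
                        nrow(r$base), ncol(r$base))
      views[[view]] <- clip01(r$base * speckle)
      boxes[[view]] <- lapply(r$masks, maskBox)
    }
    new("CasePair", caseId = caseId, sagittal = views$sagittal,
        axial = views$axial, label = label, gtBoxes = boxes,
        provenance = list(seed = seed, pose = pose,
                          speckleLooks = config@speckleLooks,
                          prevalence = config@prevalence,
                          dilation = config@ventricleDilationFactor,
                          thirdVentricleShift = config@thirdVentricleShift))
  })
}

#' Generate a phantom dataset
#'
#' Exactly \code{round(prevalence * nCases)} agenesis cases are generated;
#' class assignment order is a seeded permutation, and each case gets its own
#' derived seed, so the whole dataset is a pure function of
#' \code{(config, seed)}.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param nCases number of cases (>= 1).
#' @param seed dataset seed (defaults to the config seed).
#' @param outDir optional directory; when given, PNGs, a JSON manifest and a
#'   CSV summary are written via \code{\link{writePhantomDataset}}.
#' @return list with \code{cases} (list of \linkS4class{CasePair}) and
#'   \code{manifest} (data.frame of case_id, label, file paths).
#' @export
generateDataset <- function(config, nCases, seed = config@seed, outDir = NULL) {
  stopIfNot(nCases >= 1, "argument error: nCases must be >= 1")
  nAg <- round(config@prevalence * nCases)
  labels <- c(rep("agenesis", nAg), rep("normal", nCases - nAg))
  labels <- withSeed(deriveSeed(seed, 0), sample(labels))
  cases <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    cases[[i]] <- generateCase(config, labels[i], seed = deriveSeed(seed, i),
                               caseId = sprintf("case_%04d", i))
  }
  manifest <- data.frame(
    case_id = vapply(cases, function(cs) cs@caseId, character(1)),
    label = labels,
    sagittal_path = NA_character_, axial_path = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(outDir)) manifest <- writePhantomDataset(cases, outDir, manifest)
  list(cases = cases, manifest = manifest)
}

boxesToList <- function(boxes)
  lapply(boxes, function(b) unname(boxCoords(b)))

#' Write a phantom dataset to disk
#'
#' Writes one 8-bit grayscale PNG per view, a JSON manifest (case id, label,
#' view paths, ground-truth boxes serialized as
#' \code{[x_min, y_min, x_max, y_max]}) and a flat CSV summary.
#'
#' @param cases list of \linkS4class{CasePair}.
#' @param outDir output directory (created if missing).
#' @param manifest optional pre-built manifest data.frame to fill in.
#' @return the manifest data.frame with file paths set.
#' @export
writePhantomDataset <- function(cases, outDir, manifest = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(manifest))
    manifest <- data.frame(
      case_id = vapply(cases, function(cs) cs@caseId, character(1)),
      label = vapply(cases, caseLabel, character(1)),
      sagittal_path = NA_character_, axial_path = NA_character_,
      stringsAsFactors = FALSE)
  entries <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    sp <- file.path(outDir, paste0(cs@caseId, "_sagittal.png"))
    ap <- file.path(outDir, paste0(cs@caseId, "_axial.png"))
    png::writePNG(round(cs@sagittal) / 255, sp)
    png::writePNG(round(cs@axial) / 255, ap)
    manifest$sagittal_path[i] <- sp
    manifest$axial_path[i] <- ap
    entries[[i]] <- list(case_id = cs@caseId, label = cs@label,
                         sagittal_path = sp, axial_path = ap,
                         boxes = list(sagittal = boxesToList(cs@gtBoxes$sagittal),
                                      axial = boxesToList(cs@gtBoxes$axial)))
  }
  jsonlite::write_json(entries, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(manifest, file.path(outDir, "summary.csv"), row.names = FALSE)
  manifest
}

#' Read an image written by the phantom writer
#'
#' @param path PNG path.
#' @return numeric matrix on the [0,255] intensity scale.
#' @export
readImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 255
}
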