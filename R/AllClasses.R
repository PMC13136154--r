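#' @import methods
#' @importFrom stats rnorm runif rgamma rbinom fft sd quantile cor cov
#' @importFrom utils write.csv modifyList head
#' @useDynLib ccfocus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Axis-aligned pixel bounding box
#'
#' Boxes use 0-based, half-open pixel coordinates: the box covers columns
#' \code{[xMin, xMax)} and rows \code{[yMin, yMax)}, so its pixel area is
#' \code{(xMax - xMin) * (yMax - yMin)}.
#'
#' @slot xMin,yMin,xMax,yMax integer pixel coordinates.
#' @export
setClass("BoundingBox",
  representation(xMin = "numeric", yMin = "numeric",
                 xMax = "numeric", yMax = "numeric"))

setValidity("BoundingBox", function(object) {
  v <- c(object@xMin, object@yMin, object@xMax, object@yMax)
  if (length(v) != 4L || anyNA(v) || any(!is.finite(v)))
    return("coordinates must be four finite numbers")
  if (any(v != round(v))) return("coordinates must be integer-valued")
  if (any(v < 0)) return("coordinates must be non-negative")
  if (object@xMin >= object@xMax) return("xMin must be < xMax")
  if (object@yMin >= object@yMax) return("yMin must be < yMax")
  TRUE
})

#' Construct a BoundingBox
#'
#' @param xMin,yMin,xMax,yMax 0-based, half-open pixel coordinates.
#' @return A \linkS4class{BoundingBox}.
#' @examples
#' boundingBox(0, 0, 10, 10)
#' @export
boundingBox <- function(xMin, yMin, xMax, yMax) {
  new("BoundingBox", xMin = as.numeric(xMin), yMin = as.numeric(yMin),
      xMax = as.numeric(xMax), yMax = as.numeric(yMax))
}

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%d,%d) x [%d,%d), area %d px\n",
              object@xMin, object@xMax, object@yMin, object@yMax,
              boxArea(object)))
})

#' Phantom generator configuration
#'
#' Geometry and noise parameters of the synthetic paired-plane fetal cranial
#' ultrasound phantom. All geometry is in pixels in the canonical (unrotated,
#' centered) pose; a random small similarity transform is applied per case.
#' Intensities are on the 8-bit [0,255] scale and satisfy
#' \code{ccIntensity < parenchymaMean < falxIntensity}.
#'
#' @slot imageHeight,imageWidth output image size in pixels.
#' @slot speckleLooks positive integer; the shape of the multiplicative gamma
#'   speckle (number of looks). The speckle coefficient of variation is
#'   \code{1/sqrt(speckleLooks)}.
#' @slot skullEllipse list(center, axes, angle): bright cranial outline.
#' @slot ccBand list(center, radius, thickness, thetaRange, intensity): the
#'   slender hypoechoic callosal band, drawn as an annulus arc (sagittal,
#'   normal cases only).
#' @slot falxIntensity intensity of the bright midline falx/pericallosal arc.
#' @slot parenchymaMean mean brain-tissue intensity.
#' @slot ventricleDilationFactor multiplier (>= 1) applied to ventricle axes in
#'   agenesis cases.
#' @slot thirdVentricleShift upward displacement (pixels) of the third
#'   ventricle in agenesis cases.
#' @slot prevalence fraction of agenesis cases in a generated set.
#' @slot poseRotationLimit,poseTranslationLimit per-case random similarity
#'   pose: rotation within +/- limit degrees, translation within +/- limit px.
#' @slot seed integer default seed for dataset generation.
#' @export
setClass("PhantomConfig",
  representation(imageHeight = "numeric", imageWidth = "numeric",
                 speckleLooks = "numeric", skullEllipse = "list",
                 ccBand = "list", falxIntensity = "numeric",
                 parenchymaMean = "numeric",
                 ventricleDilationFactor = "numeric",
                 thirdVentricleShift = "numeric", prevalence = "numeric",
                 poseRotationLimit = "numeric",
                 poseTranslationLimit = "numeric", seed = "numeric"))

setValidity("PhantomConfig", function(object) {
  if (object@imageHeight < 64 || object@imageWidth < 64)
    return("image must be at least 64x64")
  if (object@speckleLooks < 1) return("speckleLooks must be >= 1")
  if (object@prevalence < 0 || object@prevalence > 1)
    return("prevalence must be in [0,1]")
  if (object@ventricleDilationFactor < 1)
    return("ventricleDilationFactor must be >= 1")
  if (object@ccBand$intensity >= object@parenchymaMean)
    return("cc band must be darker than parenchyma")
  if (object@parenchymaMean >= object@falxIntensity)
    return("falx must be brighter than parenchyma")
  ## outermost structure (skull ring incl. thickness) must fit in the image
  ax <- object@skullEllipse$axes
  c0 <- object@skullEllipse$center
  if (c0[1] - ax[1] - 4 < 0 || c0[1] + ax[1] + 4 > object@imageWidth ||
      c0[2] - ax[2] - 4 < 0 || c0[2] + ax[2] + 4 > object@imageHeight)
    return("skull ellipse (plus ring) exceeds image bounds")
  TRUE
})

#' One phantom case: paired sagittal/axial images with ground truth
#'
#' @slot caseId character identifier.
#' @slot sagittal,axial numeric matrices in [0,255] (rows = y, cols = x).
#' @slot label "normal" or "agenesis".
#' @slot gtBoxes named list with elements \code{sagittal} and \code{axial},
#'   each a named list of \linkS4class{BoundingBox} keyed by structure
#'   (\code{cc}, \code{cavum_septi_pellucidi},
#'   \code{lateral_ventricle_anterior_horn}, \code{third_ventricle}). Normal
#'   cases carry a \code{cc} box in the sagittal view; agenesis cases do not.
#' @slot provenance list of generator parameters and the per-case seed.
#' @export
setClass("CasePair",
  representation(caseId = "character", sagittal = "matrix", axial = "matrix",
                 label = "character", gtBoxes = "list", provenance = "list"))

setValidity("CasePair", function(object) {
  if (!object@label %in% c("normal", "agenesis"))
    return("label must be 'normal' or 'agenesis'")
  if (!identical(dim(object@sagittal), dim(object@axial)))
    return("views must share the configured shape")
  hasCc <- !is.null(object@gtBoxes$sagittal$cc)
  if (object@label == "normal" && !hasCc)
    return("normal cases must have a sagittal cc box")
  if (object@label == "agenesis" && hasCc)
    return("agenesis cases must not have a cc box")
  h <- nrow(object@sagittal); w <- ncol(object@sagittal)
  for (view in names(object@gtBoxes))
    for (b in object@gtBoxes[[view]])
      if (b@xMax > w || b@yMax > h)
        return("ground-truth box outside image bounds")
  TRUE
})

setMethod("show", "CasePair", function(object) {
  cat(sprintf("CasePair %s [%s], %dx%d, structures: sag{%s} ax{%s}\n",
              object@caseId, object@label,
              nrow(object@sagittal), ncol(object@sagittal),
              paste(names(object@gtBoxes$sagittal), collapse = ","),
              paste(names(object@gtBoxes$axial), collapse = ",")))
})

#' A detected structure
#'
#' @slot box \linkS4class{BoundingBox}.
#' @slot confidence normalized correlation confidence in [0,1].
#' @slot structure structure name.
#' @export
setClass("Detection",
  representation(box = "BoundingBox", confidence = "numeric",
                 structure = "character"))

setValidity("Detection", function(object) {
  if (object@confidence < 0 || object@confidence > 1)
    return("confidence must be in [0,1]")
  TRUE
})

setMethod("show", "Detection", function(object) {
  cat(sprintf("Detection %s conf=%.3f ", object@structure, object@confidence))
  show(object@box)
})

#' A cropped region of interest
#'
#' @slot patch numeric matrix; its shape equals the (post-expansion)
#'   \code{sourceBox} extent.
#' @slot sourceBox \linkS4class{BoundingBox} after dynamic boundary expansion.
#' @slot view "sagittal" or "axial".
#' @slot caseId originating case.
#' @export
setClass("ROI",
  representation(patch = "matrix", sourceBox = "BoundingBox",
                 view = "character", caseId = "character"))

setValidity("ROI", function(object) {
  b <- object@sourceBox
  if (nrow(object@patch) != b@yMax - b@yMin ||
      ncol(object@patch) != b@xMax - b@xMin)
    return("patch shape must equal sourceBox extent")
  TRUE
})

#' Grad-CAM++ heatmap
#'
#' @slot values numeric matrix in [0,255], upsampled to the classifier input
#'   size. Whenever any pre-normalization value is positive, the maximum is
#'   exactly 255.
#' @slot view which stream the map explains.
#' @slot targetClass class the attribution targets.
#' @slot layerName name of the attributed convolutional stage.
#' @export
setClass("Heatmap",
  representation(values = "matrix", view = "character",
                 targetClass = "character", layerName = "character"))

setValidity("Heatmap", function(object) {
  if (any(object@values < 0) || any(object@values > 255))
    return("heatmap values must lie in [0,255]")
  TRUE
})

#' Classification metrics report
#'
#' Confusion counts (positive class = agenesis) and all derived metrics.
#' \code{balancedAccuracy} is exactly
#' \code{(sensitivityAgenesis + specificityNormal)/2}. Metrics whose
#' denominator is zero are reported as 0 with the corresponding flag in
#' \code{undefined}.
#'
#' @slot tp,tn,fp,fn confusion counts.
#' @slot accuracy,precision,recall,f1,auc,sensitivityAgenesis,specificityNormal,balancedAccuracy reals in [0,1]; \code{auc} is NA until scores are supplied.
#' @slot undefined character vector of metric names with zero denominators.
#' @export
setClass("MetricsReport",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric", accuracy = "numeric", precision = "numeric",
                 recall = "numeric", f1 = "numeric", auc = "numeric",
                 sensitivityAgenesis = "numeric",
                 specificityNormal = "numeric",
                 balancedAccuracy = "numeric", undefined = "character"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0(
    "MetricsReport (positive = agenesis)\n",
    "  counts: TP=%d TN=%d FP=%d FN=%d\n",
    "  accuracy=%.4f precision=%.4f recall=%.4f F1=%.4f AUC=%s\n",
    "  sensitivity(agenesis)=%.4f specificity(normal)=%.4f balanced=%.4f\n"),
    object@tp, object@tn, object@fp, object@fn, object@accuracy,
    object@precision, object@recall, object@f1,
    ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc)),
    object@sensitivityAgenesis, object@specificityNormal,
    object@balancedAccuracy))
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})

#' Anatomy-aware dual-stream fusion network
#'
#' Holds the network configuration and a mutable parameter environment so the
#' training loop can update weights in place (the Bioconductor idiom for large
#' mutable state behind an S4 facade).
#'
#' @slot config list produced by \code{\link{networkConfig}}.
#' @slot params environment with element \code{p}, the nested parameter list.
#' @export
setClass("ADFNet",
  representation(config = "list", params = "environment"))

setMethod("show", "ADFNet", function(object) {
  np <- sum(vapply(rapply(object@params$p, length, how = "unlist"),
                   identity, numeric(1)))
  cat(sprintf("ADFNet backbone=%s widths=[%s] cvfim after stage %d, %d parameters\n",
              object@config$backbone,
              paste(object@config$widths, collapse = ","),
              object@config$cvfimStage, np))
})

#' A single-case classifier prediction
#'
#' @slot probNormal,probAgenesis softmax probabilities (sum to 1 within 1e-6).
#' @slot predictedLabel argmax label.
#' @slot alphaUsed the per-case learned sagittal contribution coefficient.
#' @export
setClass("Prediction",
  representation(probNormal = "numeric", probAgenesis = "numeric",
                 predictedLabel = "character", alphaUsed = "numeric"))

setValidity("Prediction", function(object) {
  if (abs(object@probNormal + object@probAgenesis - 1) > 1e-6)
    return("probabilities must sum to 1 within 1e-6")
  if (object@probNormal < 0 || object@probAgenesis < 0)
    return("probabilities must be non-negative")
  TRUE
})

setMethod("show", "Prediction", function(object) {
  cat(sprintf("Prediction %s (p_normal=%.4f p_agenesis=%.4f alpha=%.3f)\n",
              object@predictedLabel, object@probNormal, object@probAgenesis,
              object@alphaUsed))
})
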