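# ROI extraction: IoU scoring, dynamic boundary expansion (3-5 px), cropping,
# a pluggable detector interface with a matched-filter baseline, and per-case
# detection evaluation. Coordinates follow the package-wide 0-based half-open
# convention, so pixel areas are simple coordinate differences.

#' Intersection over union of two boxes
#'
#' \code{area(p ∩ g) / area(p ∪ g)} with half-open pixel-count
#' areas; symmetric, in [0,1], and exactly 1 iff the boxes are identical.
#'
#' @param p,g \linkS4class{BoundingBox} objects.
#' @return IoU in [0,1].
#' @examples
#' iou(boundingBox(0, 0, 10, 10), boundingBox(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(p, g) {
  stopIfNot(is(p, "BoundingBox") && is(g, "BoundingBox"),
            "argument error: iou needs two BoundingBox objects")
  validObject(p); validObject(g)
  ix <- max(0, min(p@xMax, g@xMax) - max(p@xMin, g@xMin))
  iy <- max(0, min(p@yMax, g@yMax) - max(p@yMin, g@yMin))
  inter <- ix * iy
  union <- boxArea(p) + boxArea(g) - inter
  inter / union
}

#' Dynamic boundary expansion of a detection box
#'
#' Each side is moved outward by \code{e} pixels (then clipped to the image):
#' either a fixed \code{e} in 3..5, or \code{"auto"}, where
#' \code{e = clamp(round(0.05 * max(boxWidth, boxHeight)), 3, 5)} ties the
#' margin to the expected anatomical dimensions of the detected structure.
#'
#' @param box a \linkS4class{BoundingBox}.
#' @param imageShape c(rows, cols) of the host image.
#' @param expansion 3, 4, 5, or "auto".
#' @return the expanded, clipped \linkS4class{BoundingBox}.
#' @export
expandBox <- function(box, imageShape, expansion = "auto") {
  validObject(box)
  if (identical(expansion, "auto")) {
    e <- max(3, min(5, round(0.05 * max(box@xMax - box@xMin,
                                        box@yMax - box@yMin))))
  } else if (is.numeric(expansion) && length(expansion) == 1 &&
             expansion %in% c(3, 4, 5)) {
    e <- expansion
  } else {
    stop("argument error: expansion must be 3, 4, 5 or \"auto\"",
         call. = FALSE)
  }
  boundingBox(max(0, box@xMin - e), max(0, box@yMin - e),
              min(imageShape[2], box@xMax + e),
              min(imageShape[1], box@yMax + e))
}

#' Matched-filter baseline detector
#'
#' A phantom-scale stand-in for a learned detector behind the same interface:
#' for each structure it slides the noise-free canonical-anatomy template over
#' a search window centered on the structure's canonical location in the
#' canonicalized image and scores zero-mean normalized cross-correlation. The
#' best-scoring window becomes the detection when its correlation exceeds the
#' confidence threshold. External detectors can be plugged in as any function
#' \code{f(image) -> list of Detection}.
#'
#' @param view "sagittal" or "axial".
#' @param config the \linkS4class{PhantomConfig} describing expected anatomy.
#' @param structures structures to search for; defaults to the view's
#'   detectable set (\code{cc} is sagittal-only).
#' @param searchRadius half-size (px) of the search window around the
#'   canonical location.
#' @param threshold minimum normalized correlation (in [0,1]) to report:
#'   a single number or a named per-structure vector. The cc default (0.75)
#'   sits midway between present-band and absent-band correlation responses
#'   on despeckled phantoms; always-present landmarks use a permissive 0.3.
#' @return a detector function of class \code{MatchedFilterDetector}.
#' @export
matchedFilterDetector <- function(view = c("sagittal", "axial"),
                                  config = phantomConfig(),
                                  structures = NULL, searchRadius = 20,
                                  threshold = c(cc = 0.75,
                                                cavum_septi_pellucidi = 0.3,
                                                lateral_ventricle_anterior_horn = 0.3)) {
  view <- match.arg(view)
  if (is.null(structures))
    structures <- if (view == "sagittal")
      c("cc", "cavum_septi_pellucidi", "lateral_ventricle_anterior_horn")
    else c("cavum_septi_pellucidi", "lateral_ventricle_anterior_horn")
  ref <- renderView(config, view, "normal", list(rot = 0, tx = 0, ty = 0))
  tpl <- list()
  for (s in structures) {
    b <- maskBox(ref$masks[[s]])
    tpl[[s]] <- list(box = b,
                     template = ref$base[(b@yMin + 1):b@yMax,
                                         (b@xMin + 1):b@xMax, drop = FALSE])
  }
  f <- function(image) {
    out <- list()
    for (s in names(tpl)) {
      b <- tpl[[s]]$box
      th <- b@yMax - b@yMin; tw <- b@xMax - b@xMin
      y0 <- b@yMin + 1 - searchRadius; x0 <- b@xMin + 1 - searchRadius
      scores <- .ncc_search(image, tpl[[s]]$template, y0, x0,
                            2 * searchRadius + 1, 2 * searchRadius + 1)
      if (all(scores <= 0)) next
      best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
      conf <- min(1, max(scores))
      thr <- if (length(threshold) > 1) threshold[[s]] else threshold
      if (conf < thr) next
      py <- y0 - 1 + best[1] - 1; px <- x0 - 1 + best[2] - 1  # 0-based
      out[[length(out) + 1L]] <-
        new("Detection", box = boundingBox(px, py, px + tw, py + th),
            confidence = conf, structure = s)
    }
    out
  }
  class(f) <- c("MatchedFilterDetector", "function")
  attr(f, "view") <- view
  attr(f, "threshold") <- threshold
  attr(f, "canonicalBoxes") <- lapply(tpl, function(t) t$box)
  f
}

#' Detect anatomical structures in a canonicalized image
#'
#' @param image numeric matrix in the canonical frame (see
#'   \code{\link{canonicalize}}).
#' @param detector a detector function (e.g.
#'   \code{\link{matchedFilterDetector}}) mapping an image to a list of
#'   \linkS4class{Detection}.
#' @return list of \linkS4class{Detection} (possibly empty; an empty list for
#'   the \code{cc} structure is the expected outcome on agenesis images).
#' @export
detectStructures <- function(image, detector) {
  stopIfNot(is.function(detector), "argument error: detector must be a function")
  detector(image)
}

#' Map a box through an affine transform
#'
#' Transforms the four corners and returns the rounded tight axis-aligned
#' bounds, clipped to \code{imageShape}.
#'
#' @param box a \linkS4class{BoundingBox}.
#' @param tf an \code{\link{affineTransform}}.
#' @param imageShape c(rows, cols) for clipping.
#' @param inverse apply the inverse transform instead.
#' @return a \linkS4class{BoundingBox}.
#' @export
mapBoxThroughAffine <- function(box, tf, imageShape, inverse = FALSE) {
  A <- tf$m[, 1:2]; b <- tf$m[, 3]
  if (inverse) { A <- solve(tf$m[, 1:2]); b <- -A %*% tf$m[, 3] }
  corners <- rbind(c(box@xMin, box@yMin), c(box@xMax, box@yMin),
                   c(box@xMin, box@yMax), c(box@xMax, box@yMax))
  tc <- t(A %*% t(corners) + as.vector(b))
  boundingBox(max(0, round(min(tc[, 1]))), max(0, round(min(tc[, 2]))),
              min(imageShape[2], round(max(tc[, 1]))),
              min(imageShape[1], round(max(tc[, 2]))))
}

#' Crop an ROI around a detection
#'
#' Applies \code{\link{expandBox}} (expansion always at least 3 px) and
#' extracts the sub-image; the patch shape equals the post-expansion box
#' extent.
#'
#' @param image numeric matrix.
#' @param detection a \linkS4class{Detection}.
#' @param expansion 3, 4, 5 or "auto".
#' @param view,caseId provenance recorded on the ROI.
#' @return an \linkS4class{ROI}.
#' @export
cropRoi <- function(image, detection, expansion = "auto",
                    view = "sagittal", caseId = "") {
  b <- expandBox(detection@box, dim(image), expansion)
  if (b@xMax - b@xMin < 1 || b@yMax - b@yMin < 1)
    stop("internal error: degenerate post-clip box", call. = FALSE)
  patch <- image[(b@yMin + 1):b@yMax, (b@xMin + 1):b@xMax, drop = FALSE]
  new("ROI", patch = patch, sourceBox = b, view = view, caseId = caseId)
}

#' Convert detections to a data frame
#'
#' @param caseId case identifier.
#' @param detections list of \linkS4class{Detection}.
#' @return data.frame(case_id, structure, confidence, x_min, y_min, x_max,
#'   y_max) with zero rows when nothing was detected.
#' @export
detectionsToFrame <- function(caseId, detections) {
  if (length(detections) == 0)
    return(data.frame(case_id = character(0), structure = character(0),
                      confidence = numeric(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0)))
  do.call(rbind, lapply(detections, function(d)
    data.frame(case_id = caseId, structure = d@structure,
               confidence = d@confidence, x_min = d@box@xMin,
               y_min = d@box@yMin, x_max = d@box@xMax, y_max = d@box@yMax,
               stringsAsFactors = FALSE)))
}

#' Evaluate detections against ground truth
#'
#' Predictions and ground truth are matched by \code{case_id} and
#' \code{structure} — and by \code{view} when both frames carry a view
#' column, since the same structure name can appear in both imaging planes.
#' A ground-truth box with no matching prediction counts as IoU 0.
#'
#' @param predictions data.frame with columns case_id, structure, x_min,
#'   y_min, x_max, y_max (e.g. from \code{\link{detectionsToFrame}}) and
#'   optionally view.
#' @param gt data.frame with the same box columns.
#' @return data.frame(structure, mean_iou, sd_iou, n) per structure.
#' @export
evaluateDetection <- function(predictions, gt) {
  stopIfNot(nrow(gt) > 0, "argument error: empty evaluation set")
  useView <- "view" %in% names(predictions) && "view" %in% names(gt)
  rowBox <- function(r) boundingBox(r$x_min, r$y_min, r$x_max, r$y_max)
  gt$iou <- vapply(seq_len(nrow(gt)), function(i) {
    sel <- predictions$case_id == gt$case_id[i] &
      predictions$structure == gt$structure[i]
    if (useView) sel <- sel & predictions$view == gt$view[i]
    hit <- predictions[sel, , drop = FALSE]
    if (nrow(hit) == 0) return(0)
    iou(rowBox(hit[1, ]), rowBox(gt[i, ]))
  }, numeric(1))
  agg <- split(gt$iou, gt$structure)
  data.frame(structure = names(agg),
             mean_iou = vapply(agg, mean, numeric(1)),
             sd_iou = vapply(agg, function(v) if (length(v) > 1) sd(v) else 0,
                             numeric(1)),
             n = vapply(agg, length, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
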