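#' Pixel area of a bounding box
#' @param x a \linkS4class{BoundingBox}.
#' @return integer pixel count under the half-open convention.
#' @export
setGeneric("boxArea", function(x) standardGeneric("boxArea"))

#' @rdname boxArea
#' @export
setMethod("boxArea", "BoundingBox", function(x)
  as.integer((x@xMax - x@xMin) * (x@yMax - x@yMin)))

#' Box coordinates as a numeric vector
#' @param x a \linkS4class{BoundingBox}.
#' @return numeric vector \code{c(xMin, yMin, xMax, yMax)} (the manifest
#'   serialization order).
#' @export
setGeneric("boxCoords", function(x) standardGeneric("boxCoords"))

#' @rdname boxCoords
#' @export
setMethod("boxCoords", "BoundingBox", function(x)
  c(xMin = x@xMin, yMin = x@yMin, xMax = x@xMax, yMax = x@yMax))

#' Case accessors
#'
#' @param x a \linkS4class{CasePair}.
#' @param view "sagittal" or "axial".
#' @return \code{caseLabel}: the class label; \code{caseImage}: the requested
#'   view's intensity matrix; \code{gtBoxes}: the named list of ground-truth
#'   \linkS4class{BoundingBox} for that view.
#' @export
setGeneric("caseLabel", function(x) standardGeneric("caseLabel"))

#' @rdname caseLabel
#' @export
setMethod("caseLabel", "CasePair", function(x) x@label)

#' @rdname caseLabel
#' @export
setGeneric("caseImage", function(x, view) standardGeneric("caseImage"))

#' @rdname caseLabel
#' @export
setMethod("caseImage", "CasePair", function(x, view) {
  view <- match.arg(view, c("sagittal", "axial"))
  slot(x, view)
})

#' @rdname caseLabel
#' @export
setGeneric("gtBoxes", function(x, view) standardGeneric("gtBoxes"))

#' @rdname caseLabel
#' @export
setMethod("gtBoxes", "CasePair", function(x, view) {
  view <- match.arg(view, c("sagittal", "axial"))
  x@gtBoxes[[view]]
})

#' Heatmap values accessor
#' @param x a \linkS4class{Heatmap}.
#' @return the numeric matrix of normalized attribution values in [0,255].
#' @export
setGeneric("heatmapValues", function(x) standardGeneric("heatmapValues"))

#' @rdname heatmapValues
#' @export
setMethod("heatmapValues", "Heatmap", function(x) x@values)

#' Convert a metrics report to a one-row data.frame
#' @param x a \linkS4class{MetricsReport}.
#' @return one-row \code{data.frame} with counts and all derived metrics.
#' @export
setGeneric("asMetricsRow", function(x) standardGeneric("asMetricsRow"))

#' @rdname asMetricsRow
#' @export
setMethod("asMetricsRow", "MetricsReport", function(x)
  data.frame(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn,
             accuracy = x@accuracy, precision = x@precision,
             recall = x@recall, f1 = x@f1, auc = x@auc,
             sensitivity_agenesis = x@sensitivityAgenesis,
             specificity_normal = x@specificityNormal,
             balanced_accuracy = x@balancedAccuracy))
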