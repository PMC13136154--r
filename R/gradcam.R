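# Grad-CAM++ attribution over a stream's final convolutional stage, heatmap
# normalization to the 0-255 signal scale, clinical intensity banding, and
# overlay rendering.

# Core Grad-CAM++ combination from an activation cube A and the gradient dS/dA
# of the class score at the same node. Channel weights use the standard
# first/second/third-order terms under the exponential-score smoothing:
#   alpha = g^2 / (2 g^2 + sum_spatial(A) * g^3),  w_k = sum(alpha * relu(g)),
#   cam = relu(sum_k w_k A_k).
gradCamPPCore <- function(A, dA) {
  C <- dim(A)[3]
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(C)) {
    g <- dA[, , k]
    g2 <- g * g
    denom <- 2 * g2 + sum(A[, , k]) * g2 * g
    alpha <- ifelse(abs(denom) > 1e-12, g2 / denom, 0)
    wk <- sum(alpha * pmax(g, 0))
    cam <- cam + wk * A[, , k]
  }
  pmax(cam, 0)
}

upsampleBilinear <- function(m, target) {
  h <- nrow(m); w <- ncol(m)
  g <- pixelGrid(target, target)
  mapy <- (g$y + 0.5) * (h / target) - 0.5
  mapx <- (g$x + 0.5) * (w / target) - 0.5
  # clamp to the source extent so the border replicates instead of fading
  mapy <- pmin(pmax(mapy, 0), h - 1)
  mapx <- pmin(pmax(mapx, 0), w - 1)
  .warp_bilinear(m, mapy, mapx, 0)
}

#' Grad-CAM++ heatmap for one stream
#'
#' Computes the class-score gradient at the stream's final convolutional
#' stage (after the cross-view exchange and all residual stages, immediately
#' before global average pooling), combines channels with the Grad-CAM++
#' weighting, rectifies, bilinearly upsamples to the classifier input size,
#' and min-max normalizes to [0,255]. A map that is identically zero after
#' rectification is returned as all zeros rather than an error.
#'
#' @param net a trained \linkS4class{ADFNet} (eval mode is implied).
#' @param roiSag,roiCor input patches at the classifier input size, [0,255].
#' @param targetClass "normal" or "agenesis"; default the predicted class.
#' @param view which stream to attribute.
#' @param layer attribution layer; \code{"final"} (the last convolutional
#'   stage) is the supported stage name.
#' @param contentBox optional \linkS4class{BoundingBox} marking the letterbox
#'   content region of the input; attribution outside it is zeroed before
#'   normalization. The zero padding carries no image signal, and convolution
#'   responses at the content/padding boundary would otherwise dominate the
#'   normalized map.
#' @return a \linkS4class{Heatmap}; its \code{raw} attribute (feature-grid
#'   resolution, pre-normalization) is kept for diagnostics.
#' @export
gradCamPP <- function(net, roiSag, roiCor, targetClass = NULL,
                      view = c("sagittal", "axial"), layer = "final",
                      contentBox = NULL) {
  view <- match.arg(view)
  if (!identical(layer, "final"))
    stop("argument error: unknown layer '", layer,
         "'; the attribution layer is \"final\"", call. = FALSE)
  cfg <- net@config
  p <- net@params$p
  fw <- fullFwd(cfg, p, asInputArray(roiSag, cfg),
                asInputArray(roiCor, cfg), train = FALSE)
  if (is.null(targetClass))
    targetClass <- c("normal", "agenesis")[which.max(fw$probs)]
  targetClass <- match.arg(targetClass, c("normal", "agenesis"))
  onehot <- c(0, 0); onehot[match(targetClass, c("normal", "agenesis"))] <- 1
  fw$dlogits <- onehot          # gradient of the raw class logit
  bw <- fullBwd(cfg, p, fw)
  A <- if (view == "sagittal") fw$cache$As else fw$cache$Ac
  dA <- if (view == "sagittal") bw$dAs else bw$dAc
  raw <- gradCamPPCore(A, dA)
  up <- upsampleBilinear(raw, cfg$inputSize)
  if (!is.null(contentBox)) {
    m <- matrix(0, nrow(up), ncol(up))
    m[(contentBox@yMin + 1):contentBox@yMax,
      (contentBox@xMin + 1):contentBox@xMax] <- 1
    up <- up * m
  }
  mx <- max(up)
  values <- if (mx > 0) up / mx * 255 else up
  hm <- new("Heatmap", values = values, view = view,
            targetClass = targetClass, layerName = layer)
  attr(hm@values, "raw") <- raw
  hm
}

#' Band a normalized heatmap into clinical signal levels
#'
#' Pixel bands on the 0-255 signal scale: \code{decisive} above 220,
#' \code{high} in (200, 220], \code{perceptible} in [100, 200],
#' \code{background} below 80, and \code{low} for the remaining gap
#' [80, 100). Banding is a pure function of the heatmap values, so it is
#' idempotent under re-normalization.
#'
#' @param heatmap a \linkS4class{Heatmap} (or a numeric matrix in [0,255]).
#' @return character matrix of band names, same shape.
#' @export
band <- function(heatmap) {
  v <- if (is(heatmap, "Heatmap")) heatmap@values else heatmap
  b <- matrix("low", nrow(v), ncol(v))
  b[v > 220] <- "decisive"
  b[v > 200 & v <= 220] <- "high"
  b[v >= 100 & v <= 200] <- "perceptible"
  b[v < 80] <- "background"
  b
}

#' Band pixel fractions
#' @param bands character matrix from \code{\link{band}}.
#' @return named numeric vector of pixel fractions per band.
#' @export
bandFractions <- function(bands) {
  lv <- c("background", "low", "perceptible", "high", "decisive")
  tab <- table(factor(bands, levels = lv))
  fr <- as.vector(tab) / length(bands)
  names(fr) <- lv
  fr
}

jetColor <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  list(r = r, g = g, b = b)
}

#' Overlay a heatmap on its grayscale input
#'
#' Jet-style colorization alpha-blended over the image; pixels with zero
#' heatmap signal keep the pure grayscale value, so an all-zero heatmap
#' reproduces the input rendered to RGB.
#'
#' @param heatmap a \linkS4class{Heatmap} or numeric matrix in [0,255].
#' @param image grayscale matrix of the same shape, [0,255].
#' @param alpha blend weight of the colorized heatmap where signal > 0.
#' @return numeric array H x W x 3 in [0,255].
#' @export
overlay <- function(heatmap, image, alpha = 0.4) {
  v <- if (is(heatmap, "Heatmap")) heatmap@values else heatmap
  stopIfNot(identical(dim(v), dim(image)), "argument error: shape mismatch")
  jet <- jetColor(v / 255)
  a <- alpha * (v > 0)
  out <- array(0, c(nrow(v), ncol(v), 3))
  out[, , 1] <- (1 - a) * image + a * jet$r * 255
  out[, , 2] <- (1 - a) * image + a * jet$g * 255
  out[, , 3] <- (1 - a) * image + a * jet$b * 255
  out
}

#' Map an image-frame box into ROI (classifier-input) coordinates
#'
#' Accounts for the crop offset and the letterbox scaling/padding so that
#' ground-truth regions can be compared against heatmaps computed on the
#' resized ROI patch.
#'
#' @param box a \linkS4class{BoundingBox} in the cropped image's frame.
#' @param roiBox the ROI's source \linkS4class{BoundingBox}.
#' @param inputSize the classifier input side length.
#' @return a \linkS4class{BoundingBox} in ROI-patch coordinates, or NULL when
#'   the box does not intersect the ROI.
#' @export
mapBoxToRoi <- function(box, roiBox, inputSize = 256) {
  x0 <- max(box@xMin, roiBox@xMin) - roiBox@xMin
  y0 <- max(box@yMin, roiBox@yMin) - roiBox@yMin
  x1 <- min(box@xMax, roiBox@xMax) - roiBox@xMin
  y1 <- min(box@yMax, roiBox@yMax) - roiBox@yMin
  if (x1 <= x0 || y1 <= y0) return(NULL)
  h <- roiBox@yMax - roiBox@yMin; w <- roiBox@xMax - roiBox@xMin
  s <- min(inputSize / h, inputSize / w)
  ch <- round(h * s); cw <- round(w * s)
  oy <- floor((inputSize - ch) / 2); ox <- floor((inputSize - cw) / 2)
  boundingBox(max(0, floor(x0 * cw / w) + ox), max(0, floor(y0 * ch / h) + oy),
              min(inputSize, ceiling(x1 * cw / w) + ox),
              min(inputSize, ceiling(y1 * ch / h) + oy))
}

#' Fraction of top-decile heatmap mass inside ground-truth regions
#'
#' Takes the pixels in the top decile of heatmap values and reports the
#' fraction lying inside the union of the given boxes dilated by
#' \code{dilatePx}.
#'
#' @param heatmap a \linkS4class{Heatmap} or numeric matrix.
#' @param boxes list of \linkS4class{BoundingBox} in heatmap coordinates
#'   (NULL entries are skipped).
#' @param dilatePx dilation margin in pixels.
#' @return fraction in [0,1] (NA if the heatmap is identically zero).
#' @export
topDecileMass <- function(heatmap, boxes, dilatePx = 5) {
  v <- if (is(heatmap, "Heatmap")) heatmap@values else heatmap
  if (max(v) <= 0) return(NA_real_)
  mask <- matrix(FALSE, nrow(v), ncol(v))
  for (b in boxes) {
    if (is.null(b)) next
    ys <- max(1, b@yMin + 1 - dilatePx):min(nrow(v), b@yMax + dilatePx)
    xs <- max(1, b@xMin + 1 - dilatePx):min(ncol(v), b@xMax + dilatePx)
    mask[ys, xs] <- TRUE
  }
  thr <- quantile(v, 0.9)
  top <- v >= thr & v > 0     # sparse rectified maps: stay within the signal
  sum(top & mask) / sum(top)
}
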