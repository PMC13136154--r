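# Preprocessing: homomorphic speckle filtering, affine canonicalization to a
# shared frame, aspect-preserving letterbox resize, and the train-time /
# test-time augmentation stack (rotation, brightness, elastic deformation).

#' Homomorphic speckle filter
#'
#' Multiplicative speckle becomes additive in the log domain; a Gaussian
#' transfer function then attenuates the high-frequency speckle band while
#' mildly boosting the low-frequency anatomy:
#' \code{out = exp(IFFT(H * FFT(log(img + eps))))}, min-max rescaled to
#' [0,255]. \code{H} interpolates \code{highGain -> lowGain} as frequency
#' rises through \code{cutoff} (a fraction of the Nyquist frequency), so on
#' flat speckle the output coefficient of variation is strictly reduced.
#'
#' @param image numeric matrix with finite, non-negative values.
#' @param lowGain gain applied to the high-frequency (speckle) band (<= 1).
#' @param highGain gain applied at DC / low frequency (>= 1). The default 1.0
#'   attenuates speckle without expanding the global dynamic range: a DC gain
#'   above 1 acts like a gamma expansion in the log domain and, after the
#'   final min-max rescale, crushes the soft-tissue contrast under the bright
#'   skull echo.
#' @param cutoff transition frequency as a fraction of Nyquist (> 0). The
#'   default 0.25 sits above the spectral band of the thin callosal
#'   structures (about 0.17 Nyquist for a 6 px band) so despeckling does not
#'   erase the anatomy the classifier needs.
#' @param eps log-domain offset guarding zeros.
#' @return filtered matrix, same shape, values in [0,255].
#' @export
homomorphicFilter <- function(image, lowGain = 0.5, highGain = 1.0,
                              cutoff = 0.25, eps = 1.0) {
  stopIfNot(length(image) > 0, "input error: empty image")
  stopIfNot(all(is.finite(image)), "input error: non-finite pixels")
  stopIfNot(lowGain <= 1 && highGain >= 1 && cutoff > 0,
            "argument error: need lowGain <= 1 <= highGain and cutoff > 0")
  h <- nrow(image); w <- ncol(image)
  L <- log(image + eps)
  FL <- fft(L)
  fy <- (seq_len(h) - 1) / h; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  fx <- (seq_len(w) - 1) / w; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  D <- sqrt(outer(fy^2, fx^2, "+")) / 0.5   # radius in Nyquist units
  H <- lowGain + (highGain - lowGain) * exp(-D^2 / (2 * cutoff^2))
  out <- exp(Re(fft(FL * H, inverse = TRUE)) / (h * w))
  rng <- range(out)
  if (rng[2] - rng[1] < 1e-9) return(clip01(matrix(rng[1], h, w)))
  (out - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Affine transform (2x3, input -> output pixel coordinates)
#'
#' @param m numeric 2x3 matrix; \code{p_out = m[,1:2] \%*\% p_in + m[,3]} on
#'   0-based (x, y) pixel coordinates.
#' @return object of class \code{AffineTransform}.
#' @export
affineTransform <- function(m) {
  stopIfNot(is.matrix(m) && all(dim(m) == c(2, 3)), "m must be 2x3")
  stopIfNot(abs(det(m[, 1:2])) > 1e-12,
            "linear part must have nonzero determinant")
  structure(list(m = m), class = "AffineTransform")
}

#' @export
print.AffineTransform <- function(x, ...) {
  cat("AffineTransform (input -> output):\n"); print(x$m); invisible(x)
}

# Algebraic least-squares conic fit (a x^2 + b xy + c y^2 + d x + e y = 1)
# returning ellipse center, major-axis angle and semi-axes.
fitEllipse <- function(xy) {
  X <- cbind(xy[, 1]^2, xy[, 1] * xy[, 2], xy[, 2]^2, xy[, 1], xy[, 2])
  th <- qr.solve(X, rep(1, nrow(X)))
  a <- th[1]; b <- th[2]; cc <- th[3]; d <- th[4]; e <- th[5]
  ctr <- solve(matrix(c(2 * a, b, b, 2 * cc), 2, 2), -c(d, e))
  fc <- a * ctr[1]^2 + b * ctr[1] * ctr[2] + cc * ctr[2]^2 +
    d * ctr[1] + e * ctr[2] - 1
  eg <- eigen(matrix(c(a, b / 2, b / 2, cc), 2, 2), symmetric = TRUE)
  axes <- sqrt(-fc / eg$values)    # descending: major first
  list(ctr = ctr, ang = 0.5 * atan2(b, a - cc), axes = axes, th = th)
}

#' Estimate the canonicalizing similarity transform from the cranial outline
#'
#' Detects the bright elliptical skull outline by intensity thresholding,
#' keeps the outermost bright band, fits an ellipse by algebraic least
#' squares (with one outlier-trimming refinement pass), and returns the
#' similarity transform mapping the fitted center to the image center, the
#' major axis to the horizontal, and the semi-major axis to a fixed
#' canonical length.
#'
#' @param image numeric matrix in [0,255].
#' @param threshold intensity threshold for outline pixels.
#' @param canonicalMajorAxis target semi-major axis length in pixels;
#'   default 0.3984 * image width (the canonical skull mid-ring).
#' @return an \code{\link{affineTransform}}.
#' @export
estimateCanonicalTransform <- function(image, threshold = 190,
                                       canonicalMajorAxis = 0.3984 * ncol(image)) {
  bright <- which(image >= threshold, arr.ind = TRUE)
  if (nrow(bright) < 50)
    stop("detection error: no bright outline found at threshold ", threshold,
         call. = FALSE)
  xy <- cbind(x = bright[, 2] - 1, y = bright[, 1] - 1)
  # keep the outermost bright band (the skull ring, not interior echoes)
  ctr <- colMeans(xy)
  r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  keep <- r >= 0.7 * quantile(r, 0.9)
  xy <- xy[keep, , drop = FALSE]
  f <- fitEllipse(xy)
  q <- f$th[1] * xy[, 1]^2 + f$th[2] * xy[, 1] * xy[, 2] +
    f$th[3] * xy[, 2]^2 + f$th[4] * xy[, 1] + f$th[5] * xy[, 2]
  near <- abs(q - 1) < 0.1
  if (sum(near) >= 50) f <- fitEllipse(xy[near, , drop = FALSE])
  theta <- f$ang
  if (theta > pi / 2) theta <- theta - pi        # axis is sign-ambiguous:
  if (theta <= -pi / 2) theta <- theta + pi      # wrap to (-90, 90]
  s <- canonicalMajorAxis / f$axes[1]
  cx <- (ncol(image) - 1) / 2; cy <- (nrow(image) - 1) / 2
  R <- s * matrix(c(cos(-theta), sin(-theta), -sin(-theta), cos(-theta)), 2, 2)
  b <- c(cx, cy) - R %*% f$ctr
  affineTransform(cbind(R, b))
}

#' Apply an affine transform to an image
#'
#' @param image numeric matrix.
#' @param tf an \code{\link{affineTransform}} (input -> output coordinates).
#' @param outDim output c(rows, cols); defaults to the input shape.
#' @return warped matrix (bilinear interpolation, border value 0).
#' @export
applyAffine <- function(image, tf, outDim = dim(image)) {
  A <- tf$m[, 1:2]; b <- tf$m[, 3]
  Ai <- solve(A); bi <- -Ai %*% b
  g <- pixelGrid(outDim[1], outDim[2])
  mapx <- Ai[1, 1] * g$x + Ai[1, 2] * g$y + bi[1]
  mapy <- Ai[2, 1] * g$x + Ai[2, 2] * g$y + bi[2]
  .warp_bilinear(image, mapy, mapx, 0)
}

#' Canonicalize an image (estimate + apply)
#'
#' @inheritParams estimateCanonicalTransform
#' @return list with \code{image} (warped to the canonical frame) and
#'   \code{transform}.
#' @export
canonicalize <- function(image, threshold = 190,
                         canonicalMajorAxis = 0.3984 * ncol(image)) {
  tf <- estimateCanonicalTransform(image, threshold, canonicalMajorAxis)
  list(image = applyAffine(image, tf), transform = tf)
}

#' Aspect-preserving letterbox resize
#'
#' Content is scaled by \code{min(target/h, target/w)} and centered; the
#' remainder is padded with intensity 0.
#'
#' @param image numeric matrix.
#' @param target output side length (default 256).
#' @return target x target matrix.
#' @export
resizeLetterbox <- function(image, target = 256) {
  stopIfNot(length(image) > 0, "input error: empty image")
  h <- nrow(image); w <- ncol(image)
  s <- min(target / h, target / w)
  ch <- round(h * s); cw <- round(w * s)
  oy <- floor((target - ch) / 2); ox <- floor((target - cw) / 2)
  g <- pixelGrid(target, target)
  mapy <- (g$y - oy + 0.5) * (h / ch) - 0.5
  mapx <- (g$x - ox + 0.5) * (w / cw) - 0.5
  inside <- g$y >= oy & g$y < oy + ch & g$x >= ox & g$x < ox + cw
  out <- .warp_bilinear(image, mapy, mapx, 0)
  out[!inside] <- 0
  out
}

#' Augmentation parameters
#'
#' @param rotationLimit max absolute rotation in degrees.
#' @param brightnessLimit max fractional brightness change.
#' @param elasticSigma Gaussian smoothing scale (px) of the elastic
#'   displacement field.
#' @param elasticAlpha displacement magnitude scale (px).
#' @param seed optional default seed.
#' @return a validated parameter list of class \code{AugmentationParams}.
#' @export
augmentationParams <- function(rotationLimit = 15, brightnessLimit = 0.10,
                               elasticSigma = 8, elasticAlpha = 32,
                               seed = NULL) {
  stopIfNot(rotationLimit >= 0 && brightnessLimit >= 0 && elasticAlpha >= 0,
            "limits must be >= 0")
  stopIfNot(elasticSigma > 0, "elasticSigma must be > 0")
  structure(list(rotationLimit = rotationLimit,
                 brightnessLimit = brightnessLimit,
                 elasticSigma = elasticSigma, elasticAlpha = elasticAlpha,
                 seed = seed), class = "AugmentationParams")
}

# Draw one set of augmentation random variates (fixed draw order so that
# determinism is independent of which components are active).
drawAugment <- function(image, params) {
  h <- nrow(image); w <- ncol(image)
  rot <- runif(1, -params$rotationLimit, params$rotationLimit)
  bright <- runif(1, 1 - params$brightnessLimit, 1 + params$brightnessLimit)
  dxn <- matrix(runif(h * w, -1, 1), h, w)
  dyn <- matrix(runif(h * w, -1, 1), h, w)
  dx <- params$elasticAlpha * .gauss_blur(dxn, params$elasticSigma)
  dy <- params$elasticAlpha * .gauss_blur(dyn, params$elasticSigma)
  list(rot = rot, bright = bright, dx = dx, dy = dy,
       alpha = params$elasticAlpha)
}

applyAugmentDraws <- function(image, d) {
  h <- nrow(image); w <- ncol(image)
  out <- image
  if (d$rot != 0) {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    a <- -d$rot * pi / 180   # inverse map rotates back
    g <- pixelGrid(h, w)
    xs <- g$x - cx; ys <- g$y - cy
    mapx <- xs * cos(a) - ys * sin(a) + cx
    mapy <- xs * sin(a) + ys * cos(a) + cy
    out <- .warp_bilinear(out, mapy, mapx, 0)
  }
  if (d$bright != 1) out <- clip01(out * d$bright)
  if (d$alpha > 0) {
    g <- pixelGrid(h, w)
    out <- .warp_bilinear(out, g$y + d$dy, g$x + d$dx, 0)
  }
  clip01(out)
}

#' Random augmentation: rotation, brightness, elastic deformation
#'
#' Applies, in order: rotation ~ U(-limit, +limit) degrees about the image
#' center, multiplicative brightness ~ U(1-limit, 1+limit) with clipping, and
#' an elastic warp whose per-pixel displacement is
#' \code{elasticAlpha * gaussianSmooth(U(-1,1) noise, elasticSigma)}.
#' All interpolation is bilinear with border 0.
#'
#' @param image numeric matrix in [0,255].
#' @param params an \code{\link{augmentationParams}}.
#' @param seed optional integer; when given, output is bitwise reproducible
#'   and the caller's RNG state is untouched.
#' @return augmented matrix, same shape.
#' @export
augment <- function(image, params = augmentationParams(), seed = params$seed) {
  withSeed(seed, applyAugmentDraws(image, drawAugment(image, params)))
}

#' Augment a view pair with shared random draws
#'
#' Both views of a case receive the same geometric and photometric draw, so a
#' test-time-augmentation variant stays spatially consistent across planes.
#'
#' @param sagittal,axial numeric matrices of equal shape.
#' @inheritParams augment
#' @return list(sagittal, axial).
#' @export
augmentPair <- function(sagittal, axial, params = augmentationParams(),
                        seed = NULL) {
  withSeed(seed, {
    d <- drawAugment(sagittal, params)
    list(sagittal = applyAugmentDraws(sagittal, d),
         axial = applyAugmentDraws(axial, d))
  })
}

#' Generate test-time augmentation variants
#'
#' Returns exactly \code{k} independently augmented copies; the input itself
#' is never modified.
#'
#' @param image numeric matrix.
#' @param k number of variants (>= 1; default 5).
#' @param params an \code{\link{augmentationParams}}.
#' @param seed integer seed; variant i uses a seed derived from (seed, i).
#' @return list of \code{k} matrices.
#' @export
makeTtaVariants <- function(image, k = 5, params = augmentationParams(),
                            seed = 1L) {
  stopIfNot(k >= 1, "argument error: k must be >= 1")
  lapply(seq_len(k), function(i) augment(image, params, deriveSeed(seed, i)))
}
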