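# Public surface of the anatomy-aware dual-stream fusion network: two
# residual-CNN streams, the cross-view feature interaction module (CVFIM),
# learned per-case alpha fusion of pooled features, and the MLP head.

#' Network configuration
#'
#' @param backbone \code{"tiny"} (two residual stages at quarter width, for
#'   desk-scale experiments) or \code{"resnet18"} (four stages, standard
#'   widths).
#' @param pretrained optional path to a saved parameter JSON used as
#'   initialization (off by default; training here is always from scratch and
#'   download-free).
#' @param cvfimStage residual stage after which the CVFIM exchange is applied;
#'   defaults to the penultimate stage (stage 3 of 4 for resnet18, mirroring
#'   mid-network insertion; stage 1 of 2 for tiny).
#' @param hiddenUnits MLP hidden width (default 512).
#' @param dropoutRate dropout on the hidden layer, active in train mode only.
#' @param nClasses number of output classes.
#' @param inputSize classifier input side length (ROIs are letterboxed to
#'   this; default 256).
#' @param inputNorm input normalization: \code{"zscore"} (per-image
#'   standardization, the default) or \code{"unit"} (divide by 255).
#' @return a validated config list of class \code{NetworkConfig}.
#' @export
networkConfig <- function(backbone = c("tiny", "resnet18"), pretrained = NULL,
                          cvfimStage = NULL, hiddenUnits = 512,
                          dropoutRate = 0.5, nClasses = 2, inputSize = 256,
                          inputNorm = c("zscore", "unit")) {
  inputNorm <- match.arg(inputNorm)
  backbone <- match.arg(backbone)
  spec <- backboneSpec(backbone)
  if (is.null(cvfimStage)) cvfimStage <- max(1, length(spec$widths) - 1)
  stopIfNot(cvfimStage >= 1 && cvfimStage <= length(spec$widths),
            "cvfimStage must lie within the backbone depth")
  stopIfNot(dropoutRate >= 0 && dropoutRate < 1, "dropoutRate must be in [0,1)")
  structure(c(spec, list(backbone = backbone, pretrained = pretrained,
                         cvfimStage = cvfimStage, hiddenUnits = hiddenUnits,
                         dropoutRate = dropoutRate, nClasses = nClasses,
                         inputSize = inputSize, inputNorm = inputNorm)),
            class = "NetworkConfig")
}

#' Create an (untrained) ADFNet
#'
#' Convolution and fully connected weights use He initialization; the CVFIM
#' 1x1 convolutions and the alpha gate start at zero, so the untrained network
#' begins at the exact x1.5 CVFIM residual scaling and alpha = 0.5.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param seed integer seed for the weight draw.
#' @return an \linkS4class{ADFNet}.
#' @export
adfnet <- function(config = networkConfig(), seed = 1L) {
  p <- withSeed(seed, netInit(config))
  if (!is.null(config$pretrained)) {
    loaded <- loadAdfnet(config$pretrained)
    p <- loaded@params$p
  }
  env <- new.env(parent = emptyenv())
  env$p <- p
  new("ADFNet", config = unclass(config), params = env)
}

# Classifier input normalization. Per-image standardization keeps the
# first-layer activation scale independent of the crop's brightness, which
# shortens the initial training plateau considerably on low-mean ROIs.
asInputArray <- function(patch, cfg) {
  inputSize <- cfg$inputSize
  stopIfNot(is.matrix(patch) && nrow(patch) == inputSize &&
            ncol(patch) == inputSize,
            sprintf("argument error: patch must be %dx%d (resize ROIs first)",
                    inputSize, inputSize))
  norm <- if (is.null(cfg$inputNorm)) "zscore" else cfg$inputNorm
  x <- if (identical(norm, "zscore"))
    (patch - mean(patch)) / (sd(patch) + 1e-6)
  else patch / 255
  array(x, dim = c(inputSize, inputSize, 1))
}

#' Forward pass: one case, one prediction
#'
#' Runs both streams, the CVFIM exchange at the configured stage, global
#' average pooling, the learned-alpha convex fusion, and the MLP head with
#' softmax. Dropout is active only in \code{mode = "train"}; in eval mode the
#' forward pass is a pure function of its inputs.
#'
#' @param net an \linkS4class{ADFNet}.
#' @param roiSag,roiCor numeric matrices of size
#'   \code{inputSize x inputSize} (the letterboxed ROI patches), [0,255].
#' @param mode "eval" or "train".
#' @param cvfimMode "on", "fixed" (gates forced to 0.5) or "off" (module
#'   bypassed) — ablation hooks.
#' @return a \linkS4class{Prediction}.
#' @export
predictCase <- function(net, roiSag, roiCor, mode = c("eval", "train"),
                        cvfimMode = "on") {
  mode <- match.arg(mode)
  cfg <- net@config
  fw <- fullFwd(cfg, net@params$p, asInputArray(roiSag, cfg),
                asInputArray(roiCor, cfg),
                train = (mode == "train"), cvfimMode = cvfimMode)
  new("Prediction", probNormal = fw$probs[1], probAgenesis = fw$probs[2],
      predictedLabel = c("normal", "agenesis")[which.max(fw$probs)],
      alphaUsed = fw$alpha)
}

#' Cross-view feature interaction (CVFIM)
#'
#' Sigmoid-gated residual exchange between the two stream feature maps:
#' \code{F'_sag = F_sag + sigmoid(phi_s(F_cor)) * F_sag} and symmetrically
#' \code{F'_cor = F_cor + sigmoid(phi_c(F_sag)) * F_cor}, with independent
#' learned 1x1 convolutions \code{phi_s}, \code{phi_c}. With zero phi the
#' gate is sigmoid(0) = 0.5 and both maps scale by exactly 1.5.
#'
#' @param fSag,fCor numeric 3D arrays (H, W, C) with equal dimensions.
#' @param phiSag,phiCor 1x1 conv parameters \code{list(w = C x C matrix,
#'   b = length-C vector)}; default zero.
#' @return list(fSag, fCor) of gated maps, shapes preserved.
#' @export
cvfim <- function(fSag, fCor, phiSag = NULL, phiCor = NULL) {
  stopIfNot(identical(dim(fSag), dim(fCor)),
            "argument error: feature maps must share dimensions")
  C <- dim(fSag)[3]
  zero <- list(w = matrix(0, C, C), b = numeric(C), kh = 1, kw = 1)
  mk <- function(phi) {
    if (is.null(phi)) return(zero)
    list(w = phi$w, b = phi$b, kh = 1, kw = 1)
  }
  gs <- sigmoid(convF(fCor, mk(phiSag), 1, 0))
  gc_ <- sigmoid(convF(fSag, mk(phiCor), 1, 0))
  list(fSag = fSag + gs * fSag, fCor = fCor + gc_ * fCor)
}

#' Learned per-case view weighting
#'
#' \code{alpha = sigmoid(w . [vSag; vCor] + b)}, a scalar in (0,1) — the
#' sagittal contribution coefficient. Zero gate parameters give alpha = 0.5.
#'
#' @param vSag,vCor pooled feature vectors of equal length.
#' @param gate list(w = length 2D vector, b = scalar).
#' @return the scalar alpha.
#' @export
computeAlpha <- function(vSag, vCor,
                         gate = list(w = numeric(2 * length(vSag)), b = 0)) {
  stopIfNot(length(vSag) == length(vCor), "argument error: length mismatch")
  sigmoid(sum(gate$w * c(vSag, vCor)) + gate$b)
}

#' Convex fusion of pooled view features
#'
#' \code{fused = alpha * vSag + (1 - alpha) * vCor}; the axial weight is
#' exactly \code{1 - alpha}.
#'
#' @param vSag,vCor pooled feature vectors of equal length.
#' @param alpha scalar in [0,1].
#' @return the fused vector.
#' @export
fuse <- function(vSag, vCor, alpha) {
  stopIfNot(length(vSag) == length(vCor), "argument error: length mismatch")
  stopIfNot(alpha >= 0 && alpha <= 1, "argument error: alpha must be in [0,1]")
  alpha * vSag + (1 - alpha) * vCor
}

#' Class weights for the imbalanced weighted loss
#'
#' Normal weight 1.0; agenesis weight \code{nNormal / nAgenesis} (about 8.64
#' at the reference training counts 311 normal / 36 agenesis).
#'
#' @param nNormal,nAgenesis class counts (>= 1).
#' @return list(w_normal = 1, w_agenesis).
#' @export
computeClassWeights <- function(nNormal, nAgenesis) {
  stopIfNot(nNormal >= 1, "counts must be >= 1")
  if (nAgenesis < 1)
    stop("class weighting undefined: zero agenesis count", call. = FALSE)
  list(w_normal = 1.0, w_agenesis = nNormal / nAgenesis)
}

#' Class-weighted cross-entropy loss
#'
#' Per sample \code{-w_label * log(p_label)} (probabilities clamped at
#' 1e-12); over a batch, the sum of losses divided by the sum of the present
#' labels' weights, so with all weights 1 it reduces exactly to the mean
#' cross-entropy.
#'
#' @param probs numeric vector c(p_normal, p_agenesis) or an n x 2 matrix.
#' @param labels "normal"/"agenesis", length matching the rows of probs.
#' @param weights from \code{\link{computeClassWeights}}.
#' @param normalize divide by the summed weights (the batch form); when
#'   FALSE, returns the summed weighted loss.
#' @return non-negative scalar.
#' @export
weightedCeLoss <- function(probs, labels,
                           weights = list(w_normal = 1, w_agenesis = 1),
                           normalize = TRUE) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  stopIfNot(nrow(probs) == length(labels), "argument error: length mismatch")
  pLab <- ifelse(labels == "agenesis", probs[, 2], probs[, 1])
  w <- ifelse(labels == "agenesis", weights$w_agenesis, weights$w_normal)
  total <- sum(-w * log(pmax(pLab, 1e-12)))
  if (normalize) total / sum(w) else total
}

#' Save / load network parameters
#'
#' Parameters are serialized to plain JSON alongside the network
#' configuration, so checkpoints are text files.
#'
#' @param net an \linkS4class{ADFNet}.
#' @param path output JSON path.
#' @return \code{loadAdfnet} returns the restored \linkS4class{ADFNet}.
#' @export
saveAdfnet <- function(net, path) {
  ser <- function(x) {
    if (is.list(x)) lapply(x, ser)
    else if (is.matrix(x)) list(.mat = dim(x), v = as.vector(x))
    else x
  }
  jsonlite::write_json(list(config = net@config[setdiff(names(net@config),
                                                        "pretrained")],
                            params = ser(net@params$p)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveAdfnet
#' @export
loadAdfnet <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  deser <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$.mat)) return(matrix(x$v, x$.mat[1], x$.mat[2]))
      lapply(x, deser)
    } else x
  }
  cfg <- as.list(raw$config)
  cfg$widths <- as.numeric(cfg$widths)
  cfg$blocks <- as.numeric(cfg$blocks)
  cfg$strides <- as.numeric(cfg$strides)
  env <- new.env(parent = emptyenv())
  env$p <- deser(raw$params)
  new("ADFNet", config = cfg, params = env)
}

# Feature maps at the CVFIM insertion point and at the final stage, for the
# ablation and attribution tests.
featureMaps <- function(net, roiSag, roiCor, cvfimMode = "on") {
  cfg <- net@config
  fw <- fullFwd(cfg, net@params$p, asInputArray(roiSag, cfg),
                asInputArray(roiCor, cfg), train = FALSE,
                cvfimMode = cvfimMode)
  list(atCvfim = list(sag = fw$cache$Fs2, cor = fw$cache$Fc2),
       final = list(sag = fw$cache$As, cor = fw$cache$Ac),
       alpha = fw$alpha, probs = fw$probs)
}
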