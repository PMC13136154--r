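# Internal CNN engine for the dual-stream classifier: plain conv+ReLU residual
# blocks, explicit reverse-mode gradients, and Adam. Feature maps are numeric
# 3D arrays dim c(H, W, C); convolutions run through the Rcpp im2col kernels.

relu <- function(x) { x[x < 0] <- 0; x }

gap3 <- function(a) apply(a, 3, mean)

convInit <- function(kh, kw, cin, cout, zero = FALSE) {
  fanIn <- kh * kw * cin
  w <- if (zero) matrix(0, fanIn, cout)
       else matrix(rnorm(fanIn * cout, sd = sqrt(2 / fanIn)), fanIn, cout)
  list(w = w, b = numeric(cout), kh = kh, kw = kw)
}

convF <- function(x, lp, stride, pad)
  .conv_fwd(x, lp$w, lp$b, lp$kh, lp$kw, stride, pad)

convB <- function(x, lp, dy, stride, pad)
  .conv_bwd(x, lp$w, dy, lp$kh, lp$kw, stride, pad)

# Backbone topology per named configuration.
backboneSpec <- function(backbone) {
  switch(backbone,
    tiny = list(stemWidth = 16, widths = c(16, 32), blocks = c(1, 1),
                strides = c(1, 2)),
    resnet18 = list(stemWidth = 64, widths = c(64, 128, 256, 512),
                    blocks = c(2, 2, 2, 2), strides = c(1, 2, 2, 2)),
    stop("unknown backbone: ", backbone, call. = FALSE))
}

blockInit <- function(cin, cout, stride) {
  b <- list(conv1 = convInit(3, 3, cin, cout),
            conv2 = convInit(3, 3, cout, cout))
  if (stride != 1 || cin != cout) b$proj <- convInit(1, 1, cin, cout)
  b
}

streamInit <- function(cfg) {
  sp <- list(stem = convInit(7, 7, 1, cfg$stemWidth), stages = list())
  cin <- cfg$stemWidth
  for (s in seq_along(cfg$widths)) {
    blocks <- list()
    for (bl in seq_len(cfg$blocks[s])) {
      stride <- if (bl == 1) cfg$strides[s] else 1
      blocks[[bl]] <- blockInit(cin, cfg$widths[s], stride)
      cin <- cfg$widths[s]
    }
    sp$stages[[s]] <- blocks
  }
  sp
}

netInit <- function(cfg) {
  p <- list(sag = streamInit(cfg), cor = streamInit(cfg))
  cW <- cfg$widths[cfg$cvfimStage]
  # zero-initialized gates: CVFIM starts at the exact x1.5 residual scaling
  # and the fusion coefficient starts at alpha = 0.5
  p$cvfim <- list(sag = convInit(1, 1, cW, cW, zero = TRUE),
                  cor = convInit(1, 1, cW, cW, zero = TRUE))
  D <- cfg$widths[length(cfg$widths)]
  p$gate <- list(w = numeric(2 * D), b = 0)
  p$fc1 <- list(w = matrix(rnorm(D * cfg$hiddenUnits,
                                 sd = sqrt(2 / D)), D, cfg$hiddenUnits),
                b = numeric(cfg$hiddenUnits))
  p$fc2 <- list(w = matrix(rnorm(cfg$hiddenUnits * cfg$nClasses,
                                 sd = sqrt(2 / cfg$hiddenUnits)),
                           cfg$hiddenUnits, cfg$nClasses),
                b = numeric(cfg$nClasses))
  p
}

blockFwd <- function(x, bp, stride) {
  a1 <- convF(x, bp$conv1, stride, 1)
  r1 <- relu(a1)
  a2 <- convF(r1, bp$conv2, 1, 1)
  s <- if (!is.null(bp$proj)) convF(x, bp$proj, stride, 0) else x
  y <- relu(a2 + s)
  list(y = y, cache = list(x = x, a1 = a1, r1 = r1, y = y, stride = stride))
}

blockBwd <- function(dy, bp, cache) {
  dpre <- dy * (cache$y > 0)
  g2 <- convB(cache$r1, bp$conv2, dpre, 1, 1)
  da1 <- g2$dx * (cache$a1 > 0)
  g1 <- convB(cache$x, bp$conv1, da1, cache$stride, 1)
  grads <- list(conv1 = list(w = g1$dw, b = g1$db),
                conv2 = list(w = g2$dw, b = g2$db))
  if (!is.null(bp$proj)) {
    gp <- convB(cache$x, bp$proj, dpre, cache$stride, 0)
    grads$proj <- list(w = gp$dw, b = gp$db)
    dx <- g1$dx + gp$dx
  } else dx <- g1$dx + dpre
  list(dx = dx, grads = grads)
}

stagesFwd <- function(x, sp, cfg, stageIdx) {
  caches <- list()
  for (s in stageIdx) {
    for (bl in seq_len(cfg$blocks[s])) {
      stride <- if (bl == 1) cfg$strides[s] else 1
      r <- blockFwd(x, sp$stages[[s]][[bl]], stride)
      x <- r$y
      caches[[sprintf("s%db%d", s, bl)]] <- r$cache
    }
  }
  list(out = x, caches = caches)
}

# Gradients come back nested exactly like the parameter list
# (stages[[s]][[bl]]) so the Adam walker can traverse both in lockstep.
stagesBwd <- function(dy, sp, cfg, stageIdx, caches) {
  grads <- vector("list", length(cfg$widths))
  for (s in rev(stageIdx)) {
    grads[[s]] <- vector("list", cfg$blocks[s])
    for (bl in rev(seq_len(cfg$blocks[s]))) {
      key <- sprintf("s%db%d", s, bl)
      r <- blockBwd(dy, sp$stages[[s]][[bl]], caches[[key]])
      dy <- r$dx
      grads[[s]][[bl]] <- r$grads
    }
  }
  list(dx = dy, grads = grads)
}

# Merge two partial per-stage grad lists (pre- and post-CVFIM stage ranges).
mergeStageGrads <- function(a, b) {
  for (s in seq_along(b)) if (!is.null(b[[s]])) a[[s]] <- b[[s]]
  a
}

streamPreFwd <- function(x, sp, cfg) {
  a <- convF(x, sp$stem, 2, 3)
  r <- relu(a)
  mp <- .maxpool_fwd(r, 3, 2, 1)
  st <- stagesFwd(mp$y, sp, cfg, seq_len(cfg$cvfimStage))
  list(out = st$out,
       cache = list(x = x, a = a, rdim = dim(r), argmax = mp$argmax,
                    pooled = mp$y, stages = st$caches))
}

streamPreBwd <- function(dy, sp, cfg, cache) {
  st <- stagesBwd(dy, sp, cfg, seq_len(cfg$cvfimStage), cache$stages)
  dpool <- .maxpool_bwd(st$dx, cache$argmax,
                        cache$rdim[1], cache$rdim[2], cache$rdim[3])
  da <- dpool * (cache$a > 0)
  g <- convB(cache$x, sp$stem, da, 2, 3)
  list(grads = list(stem = list(w = g$dw, b = g$db), stages = st$grads))
}

postStages <- function(cfg) {
  n <- length(cfg$widths)
  if (cfg$cvfimStage < n) (cfg$cvfimStage + 1):n else integer(0)
}

# Full dual-stream forward pass on one case.
# xs, xc: input arrays H x W x 1 on the [0,1] scale.
# cvfimMode: "on" (learned gates), "fixed" (gates forced to 0.5), "off"
# (module removed; features pass through unchanged) - the ablation hooks.
fullFwd <- function(cfg, p, xs, xc, train = FALSE, cvfimMode = "on") {
  pre_s <- streamPreFwd(xs, p$sag, cfg)
  pre_c <- streamPreFwd(xc, p$cor, cfg)
  Fs <- pre_s$out; Fc <- pre_c$out
  if (cvfimMode == "off") {
    gs <- NULL; gc_ <- NULL; Fs2 <- Fs; Fc2 <- Fc
  } else {
    if (cvfimMode == "fixed") {
      gs <- array(0.5, dim(Fs)); gc_ <- array(0.5, dim(Fc))
    } else {
      gs <- sigmoid(convF(Fc, p$cvfim$sag, 1, 0))
      gc_ <- sigmoid(convF(Fs, p$cvfim$cor, 1, 0))
    }
    Fs2 <- Fs * (1 + gs)
    Fc2 <- Fc * (1 + gc_)
  }
  ps <- postStages(cfg)
  post_s <- stagesFwd(Fs2, p$sag, cfg, ps)
  post_c <- stagesFwd(Fc2, p$cor, cfg, ps)
  As <- post_s$out; Ac <- post_c$out
  vs <- gap3(As); vc <- gap3(Ac)
  z <- sum(p$gate$w * c(vs, vc)) + p$gate$b
  alpha <- sigmoid(z)
  fused <- alpha * vs + (1 - alpha) * vc
  h1pre <- as.vector(crossprod(p$fc1$w, fused)) + p$fc1$b
  h1 <- relu(h1pre)
  if (train && cfg$dropoutRate > 0) {
    mask <- (runif(length(h1)) >= cfg$dropoutRate) / (1 - cfg$dropoutRate)
  } else mask <- rep(1, length(h1))
  h1d <- h1 * mask
  logits <- as.vector(crossprod(p$fc2$w, h1d)) + p$fc2$b
  probs <- softmax2(logits)
  list(probs = probs, logits = logits, alpha = alpha,
       cache = list(pre_s = pre_s$cache, pre_c = pre_c$cache, Fs = Fs,
                    Fc = Fc, gs = gs, gc = gc_, Fs2 = Fs2, Fc2 = Fc2,
                    post_s = post_s$caches, post_c = post_c$caches, As = As,
                    Ac = Ac, vs = vs, vc = vc, alpha = alpha, fused = fused,
                    h1pre = h1pre, h1 = h1, mask = mask, h1d = h1d,
                    cvfimMode = cvfimMode))
}

# Reverse pass from a gradient at the logits. Returns nested grads matching
# the parameter list plus the gradients at the final per-stream feature maps
# (the Grad-CAM++ attribution node).
fullBwd <- function(cfg, p, fw) {
  cc <- fw$cache
  dlogits <- fw$dlogits
  g <- list()
  g$fc2 <- list(w = cc$h1d %o% dlogits, b = dlogits)
  dh1d <- as.vector(p$fc2$w %*% dlogits)
  dh1 <- dh1d * cc$mask
  dh1pre <- dh1 * (cc$h1pre > 0)
  g$fc1 <- list(w = cc$fused %o% dh1pre, b = dh1pre)
  dfused <- as.vector(p$fc1$w %*% dh1pre)
  dalpha <- sum(dfused * (cc$vs - cc$vc))
  dz <- dalpha * cc$alpha * (1 - cc$alpha)
  D <- length(cc$vs)
  dvs <- cc$alpha * dfused + p$gate$w[1:D] * dz
  dvc <- (1 - cc$alpha) * dfused + p$gate$w[(D + 1):(2 * D)] * dz
  g$gate <- list(w = c(cc$vs, cc$vc) * dz, b = dz)
  hw_s <- prod(dim(cc$As)[1:2]); hw_c <- prod(dim(cc$Ac)[1:2])
  dAs <- array(rep(dvs / hw_s, each = hw_s), dim(cc$As))
  dAc <- array(rep(dvc / hw_c, each = hw_c), dim(cc$Ac))
  ps <- postStages(cfg)
  bs <- stagesBwd(dAs, p$sag, cfg, ps, cc$post_s)
  bc <- stagesBwd(dAc, p$cor, cfg, ps, cc$post_c)
  dFs2 <- bs$dx; dFc2 <- bc$dx
  sagPostG <- bs$grads; corPostG <- bc$grads
  if (identical(cc$cvfimMode, "on")) {
    dFs <- dFs2 * (1 + cc$gs)
    dFc <- dFc2 * (1 + cc$gc)
    dgs <- dFs2 * cc$Fs
    dgc <- dFc2 * cc$Fc
    dpre_gs <- dgs * cc$gs * (1 - cc$gs)
    dpre_gc <- dgc * cc$gc * (1 - cc$gc)
    cbs <- convB(cc$Fc, p$cvfim$sag, dpre_gs, 1, 0)
    cbc <- convB(cc$Fs, p$cvfim$cor, dpre_gc, 1, 0)
    dFc <- dFc + cbs$dx
    dFs <- dFs + cbc$dx
    g$cvfim <- list(sag = list(w = cbs$dw, b = cbs$db),
                    cor = list(w = cbc$dw, b = cbc$db))
  } else if (identical(cc$cvfimMode, "fixed")) {
    dFs <- dFs2 * 1.5; dFc <- dFc2 * 1.5
  } else {
    dFs <- dFs2; dFc <- dFc2
  }
  sb <- streamPreBwd(dFs, p$sag, cfg, cc$pre_s)
  cb <- streamPreBwd(dFc, p$cor, cfg, cc$pre_c)
  g$sag <- list(stem = sb$grads$stem,
                stages = mergeStageGrads(sb$grads$stages, sagPostG))
  g$cor <- list(stem = cb$grads$stem,
                stages = mergeStageGrads(cb$grads$stages, corPostG))
  list(grads = g, dAs = dAs, dAc = dAc)
}

# ---- nested parameter-list algebra and Adam ----------------------------------

# Walk two parallel nested lists; match by name where names exist (the two
# trees may order their elements differently), positionally otherwise.
paramMap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      nm <- if (!is.null(nms)) nms[i] else ""
      if (nm %in% c("kh", "kw")) next
      bi <- if (nzchar(nm)) b[[nm]] else b[[i]]
      out[[i]] <- paramMap2(a[[i]], bi, f)
    }
    out
  } else f(a, b)
}

paramMap1 <- function(a, f) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      nm <- if (!is.null(nms)) nms[i] else ""
      if (nm %in% c("kh", "kw")) next
      out[[i]] <- paramMap1(a[[i]], f)
    }
    out
  } else f(a)
}

gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  paramMap2(a, b, `+`)
}

gradZeroLike <- function(p) paramMap1(p, function(x) x * 0)

adamInit <- function(p) list(m = gradZeroLike(p), v = gradZeroLike(p), t = 0)

adamStep <- function(p, g, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st$t <- st$t + 1
  st$m <- paramMap2(st$m, g, function(m, gr) beta1 * m + (1 - beta1) * gr)
  st$v <- paramMap2(st$v, g, function(v, gr) beta2 * v + (1 - beta2) * gr^2)
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  upd <- paramMap2(st$m, st$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  p <- paramMap2(p, upd, `-`)
  list(p = p, state = st)
}

# Flatten nonzero-gradient report per top-level group (the wiring test hook).
gradGroupNorms <- function(g) {
  vapply(names(g), function(nm) {
    leaves <- rapply(g[[nm]], function(x) sum(abs(x)), how = "unlist")
    sum(leaves)
  }, numeric(1))
}
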