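# Internal helpers shared across modules.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item 31-bit seed from a base seed (splitmix-style integer hash,
# done in double precision to stay exact below 2^53).
deriveSeed <- function(seed, index) {
  x <- (as.numeric(seed) * 1000003 + as.numeric(index) * 7919 + 12345) %% 2147483647
  as.integer(x)
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# 2D meshgrid of 0-based pixel centers for an H x W image: returns list(x, y)
# matrices where x is the column coordinate and y the row coordinate.
pixelGrid <- function(h, w) {
  list(x = matrix(rep(0:(w - 1), each = h), h, w),
       y = matrix(rep(0:(h - 1), times = w), h, w))
}

# Tight bounding box (0-based half-open) of a logical mask; NULL if empty.
maskBox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  boundingBox(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
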