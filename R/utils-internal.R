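# Internal numerical helpers: finite differences with replicate-edge
# padding, pixel coordinate grids, and the bilinear affine sampler shared
# by prior warping and registration gradients.

# central difference along x (columns); replicate-edge padding means the
# first/last columns fall back to one-sided half-slope differences
.gradX <- function(f) {
  nc <- ncol(f)
  (f[, c(2:nc, nc), drop = FALSE] - f[, c(1, seq_len(nc - 1)), drop = FALSE]) / 2
}

.gradY <- function(f) {
  nr <- nrow(f)
  (f[c(2:nr, nr), , drop = FALSE] - f[c(1, seq_len(nr - 1)), , drop = FALSE]) / 2
}

# pixel-centre coordinate grids, 1-based: x = column index, y = row index
.coordGrids <- function(dm) {
  nr <- dm[1]; nc <- dm[2]
  list(x = matrix(seq_len(nc), nr, nc, byrow = TRUE),
       y = matrix(seq_len(nr), nr, nc))
}

.defaultCenter <- function(dm) c((dm[2] + 1) / 2, (dm[1] + 1) / 2)

.checkSameDim <- function(...) {
  fs <- list(...)
  d <- dim(fs[[1]])
  for (f in fs[-1])
    if (!all(dim(f) == d))
      stop("field dimensions do not match: ", paste(d, collapse = "x"),
           " vs ", paste(dim(f), collapse = "x"))
  invisible(d)
}

# Bilinear sampler of prior-grid fields at the affinely transformed image
# coordinates.  Returns index/weight sets reusable across fields, plus the
# out-of-domain indicator and the Euclidean distance to the prior grid.
.affineSampler <- function(params, dm, center, grids = NULL,
                           priorDim = dm) {
  if (is.null(grids)) grids <- .coordGrids(dm)
  AT <- composeAffine(params)
  A <- AT$A; tv <- AT$T
  xr <- grids$x - center[1]
  yr <- grids$y - center[2]
  xh <- A[1, 1] * xr + A[1, 2] * yr + center[1] + tv[1]
  yh <- A[2, 1] * xr + A[2, 2] * yr + center[2] + tv[2]

  nrp <- priorDim[1]; ncp <- priorDim[2]
  inside <- xh >= 1 & xh <= ncp & yh >= 1 & yh <= nrp
  dxo <- pmax(1 - xh, xh - ncp, 0)
  dyo <- pmax(1 - yh, yh - nrp, 0)

  xc <- pmin(pmax(xh, 1), ncp)
  yc <- pmin(pmax(yh, 1), nrp)
  j0 <- pmin(floor(xc), ncp - 1)
  i0 <- pmin(floor(yc), nrp - 1)
  wx <- xc - j0
  wy <- yc - i0
  k00 <- i0 + (j0 - 1) * nrp          # [i0,     j0]
  list(xh = xh, yh = yh, inside = inside, i0 = i0, j0 = j0,
       edgeDist = sqrt(dxo^2 + dyo^2),
       k00 = k00, k10 = k00 + 1, k01 = k00 + nrp, k11 = k00 + nrp + 1,
       w00 = (1 - wx) * (1 - wy), w10 = (1 - wx) * wy,
       w01 = wx * (1 - wy), w11 = wx * wy,
       dim = dm, priorDim = priorDim)
}

# bilinear sample with clamped-edge extension
.sampleBilinear <- function(field, sm) {
  v <- sm$w00 * field[sm$k00] + sm$w10 * field[sm$k10] +
       sm$w01 * field[sm$k01] + sm$w11 * field[sm$k11]
  matrix(v, sm$dim[1], sm$dim[2])
}

.sampleNearest <- function(field, sm) {
  xi <- pmin(pmax(round(sm$xh), 1), sm$priorDim[2])
  yi <- pmin(pmax(round(sm$yh), 1), sm$priorDim[1])
  out <- matrix(field[cbind(as.vector(yi), as.vector(xi))],
                sm$dim[1], sm$dim[2])
  out[!sm$inside] <- 0
  out
}

# run expr with a temporary RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
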