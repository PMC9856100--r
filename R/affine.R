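#' Construct affine parameters
#'
#' @param theta rotation angle, radians.
#' @param sx,sy positive scale factors.
#' @param hx,hy shear coefficients.
#' @param tx,ty translations, pixels.
#' @return an [AffineParams-class] object (identity by default).
#' @export
affineParams <- function(theta = 0, sx = 1, sy = 1, hx = 0, hy = 0,
                         tx = 0, ty = 0) {
  methods::new("AffineParams", theta = as.numeric(theta),
               sx = as.numeric(sx), sy = as.numeric(sy),
               hx = as.numeric(hx), hy = as.numeric(hy),
               tx = as.numeric(tx), ty = as.numeric(ty))
}

#' Affine parameters as a named vector
#'
#' @param p an [AffineParams-class].
#' @return named numeric(7): `theta, sx, sy, hx, hy, tx, ty`.
#' @export
affineVector <- function(p) {
  c(theta = p@theta, sx = p@sx, sy = p@sy, hx = p@hx, hy = p@hy,
    tx = p@tx, ty = p@ty)
}

#' Compose the affine matrix
#'
#' Builds the linear part `A = R(theta) %*% H(hx, hy) %*% S(sx, sy)`
#' (rotation, then shear, then scale, exactly in that order) and the
#' translation vector `T = (tx, ty)`.
#'
#' @param p an [AffineParams-class].
#' @return list with the 2x2 matrix `A` and numeric(2) `T`.
#' @export
composeAffine <- function(p) {
  methods::validObject(p)
  R <- matrix(c(cos(p@theta), sin(p@theta),
                -sin(p@theta), cos(p@theta)), 2, 2)
  H <- matrix(c(1, p@hy, p@hx, 1), 2, 2)
  S <- diag(c(p@sx, p@sy))
  list(A = R %*% H %*% S, T = c(p@tx, p@ty))
}

#' Transform coordinates into the prior's reference frame
#'
#' \eqn{\hat X = A (X - c) + c + T}: the linear part acts about the stated
#' centre (default the image centre for matrix input, the origin for bare
#' coordinate pairs), followed by the translation.
#'
#' @param x,y coordinates (scalars, vectors or matrices of equal shape);
#'   1-based pixel-centred, `x` = column, `y` = row.
#' @param p an [AffineParams-class].
#' @param center numeric(2) rotation/scale/shear centre `(x, y)`.
#' @return list with transformed `x`, `y` of the input shape.
#' @export
transformCoords <- function(x, y, p, center = c(0, 0)) {
  AT <- composeAffine(p)
  xr <- x - center[1]
  yr <- y - center[2]
  list(x = AT$A[1, 1] * xr + AT$A[1, 2] * yr + center[1] + AT$T[1],
       y = AT$A[2, 1] * xr + AT$A[2, 2] * yr + center[2] + AT$T[2])
}

# 2x2 matrices M_p such that d(Xhat)/dp = M_p %*% (X - center) for the five
# linear parameters; translations have constant jacobians (1,0), (0,1)
.jacobianMatrices <- function(p) {
  ct <- cos(p@theta); st <- sin(p@theta)
  R  <- matrix(c(ct, st, -st, ct), 2, 2)
  dR <- matrix(c(-st, ct, -ct, -st), 2, 2)
  H  <- matrix(c(1, p@hy, p@hx, 1), 2, 2)
  S  <- diag(c(p@sx, p@sy))
  RH <- R %*% H
  list(
    sx = RH %*% matrix(c(1, 0, 0, 0), 2, 2),
    sy = RH %*% matrix(c(0, 0, 0, 1), 2, 2),
    hx = R %*% matrix(c(0, 0, 1, 0), 2, 2) %*% S,
    hy = R %*% matrix(c(0, 1, 0, 0), 2, 2) %*% S,
    theta = dR %*% H %*% S)
}

#' Analytic parameter Jacobians of the affine map
#'
#' Closed-form derivatives \eqn{\partial\hat X/\partial p} of the
#' transformed coordinates with respect to each of the seven scalar
#' parameters, evaluated at the current parameter values.  At the identity
#' with `center = c(0, 0)`, \eqn{\partial\hat X/\partial\theta = (-y, x)}
#' and the translation Jacobians are the unit vectors.
#'
#' @inheritParams transformCoords
#' @return named list (`theta`, `sx`, `sy`, `hx`, `hy`, `tx`, `ty`); each
#'   element a list with components `x` and `y` shaped like the input.
#' @export
paramJacobians <- function(x, y, p, center = c(0, 0)) {
  M <- .jacobianMatrices(p)
  xr <- x - center[1]
  yr <- y - center[2]
  one <- if (is.null(dim(x))) rep(1, length(x)) else array(1, dim(x))
  zero <- 0 * one
  lin <- function(m) list(x = m[1, 1] * xr + m[1, 2] * yr,
                          y = m[2, 1] * xr + m[2, 2] * yr)
  list(theta = lin(M$theta), sx = lin(M$sx), sy = lin(M$sy),
       hx = lin(M$hx), hy = lin(M$hy),
       tx = list(x = one, y = zero), ty = list(x = zero, y = one))
}

# Workhorse shared by registrationGradients() and the segmentation loop:
# everything already warped/sampled once.  `warp` is the list returned by
# warpPrior(); mK/mB/phi live on the image grid.
.regGradsFromWarp <- function(phi, mK, mB, warp, p, lambda, eps, center,
                              grids, V = NULL, Vpk = NULL, dpk = NULL) {
  if (is.null(V)) V <- smearedHeaviside(phi, eps)
  if (is.null(Vpk)) Vpk <- smearedHeaviside(warp$phiPK, eps)
  if (is.null(dpk)) dpk <- smearedDirac(warp$phiPK, eps)
  term1 <- lambda[2] * V * mB
  term2 <- lambda[2] * (1 - V) * mK
  term3 <- -2 * lambda[3] * dpk * (V - Vpk)
  Gx <- term1 * warp$dPBx + term2 * warp$dPKx + term3 * warp$dphix
  Gy <- term1 * warp$dPBy + term2 * warp$dPKy + term3 * warp$dphiy
  M <- .jacobianMatrices(p)
  xr <- grids$x - center[1]
  yr <- grids$y - center[2]
  dot <- function(m) sum(Gx * (m[1, 1] * xr + m[1, 2] * yr) +
                         Gy * (m[2, 1] * xr + m[2, 2] * yr))
  c(theta = dot(M$theta), sx = dot(M$sx), sy = dot(M$sy),
    hx = dot(M$hx), hy = dot(M$hy), tx = sum(Gx), ty = sum(Gy))
}

#' Discrete energy gradients with respect to the affine parameters
#'
#' Pixel-sum gradients of the total energy with respect to each of the
#' seven registration parameters: for each parameter \eqn{p},
#' \deqn{\frac{\partial E}{\partial p} = \sum_i \Big[
#'   \lambda_2 V_\varepsilon(\phi_i)\, m_B\, \nabla P_B(\hat X_i)
#' + \lambda_2 (1 - V_\varepsilon(\phi_i))\, m_K\, \nabla P_K(\hat X_i)
#' - 2\lambda_3\, \delta_\varepsilon(\phi_{PK}(\hat X_i))
#'   (V_\varepsilon(\phi_i) - V_\varepsilon(\phi_{PK}(\hat X_i)))
#'   \nabla\phi_{PK}(\hat X_i)\Big]\cdot
#'   \frac{\partial \hat X}{\partial p}.}
#' Prior fields and their grid gradients are sampled at the transformed
#' coordinates by bilinear interpolation (see [warpPrior()]).
#'
#' @param phi level-set field on the image grid.
#' @param mK,mB membership fields.
#' @param prior a [ShapePriorModel-class].
#' @param p current [AffineParams-class].
#' @param lambda numeric(3) energy weights.
#' @param eps smearing width.
#' @param center transform centre `(x, y)`; default the image centre.
#' @return named numeric(7): gradient per parameter
#'   (`theta, sx, sy, hx, hy, tx, ty`).
#' @export
registrationGradients <- function(phi, mK, mB, prior, p, lambda, eps,
                                  center = NULL) {
  dm <- .checkSameDim(phi, mK, mB)
  if (is.null(center)) center <- .defaultCenter(dm)
  grids <- .coordGrids(dm)
  warp <- warpPrior(prior, p, dm, center)
  .regGradsFromWarp(phi, mK, mB, warp, p, lambda, eps, center, grids)
}

#' Gradient-descent update of the affine parameters
#'
#' One descent step \eqn{p \leftarrow p - \gamma\,\partial E/\partial p}
#' with per-group step sizes: `gamma[2]` for the scales, `gamma[3]` for the
#' shears, `gamma[4]` for the translations, `gamma[5]` for the rotation.
#' When `normalize = TRUE` the raw pixel-sum gradients are divided by
#' `gradScale` (the pixel count, supplied by the caller) and each group
#' uses a fixed per-group learning rate from `rates`; this removes the
#' dependence of the step on image size and intensity scale while staying
#' a genuine gradient descent.  Scales are clamped to stay positive.
#'
#' @param p current [AffineParams-class].
#' @param grads named numeric(7) as returned by [registrationGradients()].
#' @param gamma numeric(5) step sizes (only `gamma[2:5]` are used here).
#' @param normalize logical; use mean-gradient steps with `rates`.
#' @param rates named numeric(4) `c(s=, h=, t=, theta=)`; learning rates
#'   of the normalized mode, applied to the pixel-mean gradient.
#' @param gradScale divisor turning pixel-sum gradients into means
#'   (normally the number of pixels); used only when `normalize = TRUE`.
#' @return the updated [AffineParams-class].
#' @export
updateParams <- function(p, grads, gamma, normalize = FALSE,
                         rates = c(s = 1.5, h = 4, t = 8000, theta = 2),
                         gradScale = 1) {
  if (any(gamma <= 0)) stop("step sizes must be positive")
  g <- grads
  if (normalize) {
    g <- g / gradScale
    # per-iteration step caps (trust region): gradients in the first
    # iterations, before the clustering state separates, can be large and
    # wrongly oriented; capping the motion keeps that transient harmless
    cap <- function(v, lim) pmin(pmax(v, -lim), lim)
    dS <- cap(rates[["s"]] * g[c("sx", "sy")], 0.0015)
    dH <- cap(rates[["h"]] * g[c("hx", "hy")], 0.003)
    dT <- cap(rates[["t"]] * g[c("tx", "ty")], 0.15)
    dTh <- cap(rates[["theta"]] * g[["theta"]], 0.004)
  } else {
    dS <- gamma[2] * g[c("sx", "sy")]
    dH <- gamma[3] * g[c("hx", "hy")]
    dT <- gamma[4] * g[c("tx", "ty")]
    dTh <- gamma[5] * g[["theta"]]
  }
  affineParams(theta = p@theta - dTh,
               sx = max(p@sx - dS[["sx"]], 1e-3),
               sy = max(p@sy - dS[["sy"]], 1e-3),
               hx = p@hx - dH[["hx"]], hy = p@hy - dH[["hy"]],
               tx = p@tx - dT[["tx"]], ty = p@ty - dT[["ty"]])
}
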