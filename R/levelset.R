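#' Smeared-out Heaviside function
#'
#' \eqn{C^1} approximation of the unit step over a band of width
#' \eqn{\varepsilon} around the zero level:
#' \deqn{V_\varepsilon(\phi) = \begin{cases}
#'   1 & \phi > \varepsilon \\
#'   \tfrac12 + \tfrac{\phi}{2\varepsilon} +
#'     \tfrac{1}{2\pi}\sin(\pi\phi/\varepsilon) & |\phi| \le \varepsilon \\
#'   0 & \phi < -\varepsilon \end{cases}}
#'
#' @param phi numeric vector/matrix: the level-set field.
#' @param eps smearing width \eqn{\varepsilon > 0}.
#' @return values in `[0, 1]`, same shape as `phi`.
#' @seealso [smearedDirac()], its analytic derivative.
#' @examples
#' smearedHeaviside(c(-3, 0, 3), eps = 1.5)      # 0, 0.5, 1
#' @export
smearedHeaviside <- function(phi, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("eps must be a positive finite scalar")
  v <- 0.5 + phi / (2 * eps) + sin(pi * phi / eps) / (2 * pi)
  v[phi > eps] <- 1
  v[phi < -eps] <- 0
  v
}

#' Smeared-out Dirac function
#'
#' The derivative of [smearedHeaviside()]:
#' \eqn{\delta_\varepsilon(\phi) =
#' \frac{1}{2\varepsilon}\left(1 + \cos(\pi\phi/\varepsilon)\right)} for
#' \eqn{|\phi| \le \varepsilon} and 0 outside.  It is compactly supported:
#' every term of the contour evolution is proportional to it, so pixels
#' with \eqn{|\phi| > \varepsilon} are stationary.
#'
#' @inheritParams smearedHeaviside
#' @return nonnegative values, same shape as `phi`; integrates to 1 over
#'   \eqn{[-\varepsilon, \varepsilon]}.
#' @export
smearedDirac <- function(phi, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("eps must be a positive finite scalar")
  d <- (1 + cos(pi * phi / eps)) / (2 * eps)
  d[abs(phi) > eps] <- 0
  d
}

#' Mean curvature of the level sets of a field
#'
#' Discrete \eqn{\mathrm{div}(\nabla\phi / |\nabla\phi|)} with central
#' differences, replicate-edge padding, and the gradient magnitude
#' regularized as \eqn{\sqrt{|\nabla\phi|^2 + 10^{-10}}} so flat regions
#' return 0 instead of dividing by zero.
#'
#' @param phi numeric matrix, at least 3 x 3.
#' @return matrix of the same shape.
#' @export
curvatureField <- function(phi) {
  if (!is.matrix(phi) || nrow(phi) < 3L || ncol(phi) < 3L)
    stop("phi must be a matrix of at least 3 x 3")
  px <- .gradX(phi)
  py <- .gradY(phi)
  mag <- sqrt(px * px + py * py + 1e-10)
  .gradX(px / mag) + .gradY(py / mag)
}

#' Initialize a level-set field
#'
#' Builds a signed field that is positive inside the requested initial
#' contour and negative outside, with (approximately) signed-distance
#' magnitude so that the smearing width `eps` keeps its geometric meaning.
#'
#' Modes: `"border"` places the contour on a rectangle `margin` pixels in
#' from the image frame (positive interior); `"disk"` places it on a
#' circle; `"random"` draws a seeded, Gaussian-smoothed noise field whose
#' zero level is a random set of curves.
#'
#' @param dim integer(2): rows, columns of the image grid.
#' @param mode `"border"`, `"disk"` or `"random"`.
#' @param center disk centre `(x, y)` in pixels; default image centre.
#' @param radius disk radius, pixels; default `min(dim)/4`.
#' @param margin border inset, pixels (default 4).
#' @param seed integer seed, used by `"random"` mode.
#' @return numeric matrix (the level-set field).
#' @export
initializeLevelSet <- function(dim, mode = c("border", "disk", "random"),
                               center = NULL, radius = NULL, margin = 4,
                               seed = 1L) {
  if (length(mode) != 1L || !mode %in% c("border", "disk", "random"))
    stop("unknown initialization mode: ", paste(mode, collapse = ", "))
  dim <- as.integer(dim)
  g <- .coordGrids(dim)
  if (mode == "border") {
    # signed distance to the inset rectangle, positive inside
    pmin(g$x - (margin + 1), g$y - (margin + 1),
         (dim[2] - margin) - g$x, (dim[1] - margin) - g$y)
  } else if (mode == "disk") {
    if (is.null(center)) center <- .defaultCenter(dim)
    if (is.null(radius)) radius <- min(dim) / 4
    radius - sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  } else {
    .withSeed(seed, {
      z <- matrix(stats::rnorm(prod(dim)), dim[1], dim[2])
      z <- as.matrix(EBImage::gblur(z, sigma = max(3, min(dim) / 16)))
      z <- z - stats::median(z)
      z / max(abs(z)) * min(dim) / 8
    })
  }
}

#' One level-set evolution step
#'
#' Explicit gradient-descent update of the level-set field under the joint
#' energy: curvature (length) flow, the fuzzy-clustering force weighted by
#' the warped prior probabilities, and the prior-shape mismatch force,
#' \deqn{\phi \leftarrow \phi + \gamma_1\,\delta_\varepsilon(\phi)\left[
#'   \lambda_1\,\kappa
#' + \lambda_2\,(m_K P_K(\hat X) - m_B P_B(\hat X))
#' - 2\lambda_3\,(V_\varepsilon(\phi) - V_\varepsilon(\phi_{PK}(\hat X)))
#' \right].}
#' Pixels where \eqn{\delta_\varepsilon(\phi) = 0} are returned unchanged.
#'
#' @param phi level-set field (matrix).
#' @param mK,mB kidney/background membership fields.
#' @param PKw,PBw warped prior probability fields (sampled at the
#'   transformed coordinates, see [warpPrior()]).
#' @param phiPKw warped prior level-set field.
#' @param lambda numeric(3) energy weights.
#' @param gamma1 positive step size.
#' @param eps smearing width.
#' @param clamp keep updated pixels inside the active band
#'   `[-0.95 eps, 0.95 eps]`.  The smeared Dirac kernel vanishes outside
#'   the band, so a pixel that escapes it can never move again; clamping
#'   keeps every pixel (softly, since `delta -> 0` at the band edge)
#'   revisable, which is what makes the result insensitive to the initial
#'   contour.  Pixels the update did not touch are never clamped.
#' @return the updated field.
#' @export
evolveStep <- function(phi, mK, mB, PKw, PBw, phiPKw, lambda, gamma1, eps,
                       clamp = TRUE) {
  .checkSameDim(phi, mK, mB, PKw, PBw, phiPKw)
  if (length(lambda) != 3L || any(lambda < 0))
    stop("lambda must be three nonnegative weights")
  if (gamma1 <= 0) stop("gamma1 must be positive")
  del <- smearedDirac(phi, eps)
  force <- 0
  if (lambda[1] > 0) force <- force + lambda[1] * curvatureField(phi)
  force <- force + lambda[2] * (mK * PKw - mB * PBw)
  if (lambda[3] > 0)
    force <- force - 2 * lambda[3] *
      (smearedHeaviside(phi, eps) - smearedHeaviside(phiPKw, eps))
  out <- phi + gamma1 * del * force
  if (clamp) {
    lim <- 0.95 * eps
    act <- del > 0
    out[act & out > lim] <- lim
    out[act & out < -lim] <- -lim
  }
  out
}
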