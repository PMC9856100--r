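#' Initial cluster centroids from the contour
#'
#' The kidney/background centroids are seeded as the mean intensity of the
#' pixels strictly inside (`phi > 0`) and strictly outside (`phi < 0`) the
#' current contour.
#'
#' @param image intensity matrix.
#' @param phi level-set field on the same grid.
#' @return named numeric(2): `cK`, `cB`.
#' @export
initCentroids <- function(image, phi) {
  .checkSameDim(image, phi)
  ins <- phi > 0
  outs <- phi < 0
  if (!any(ins) || !any(outs))
    stop("degenerate initialization: the contour must have pixels both ",
         "strictly inside and strictly outside")
  c(cK = mean(image[ins]), cB = mean(image[outs]))
}

#' Fuzzy membership update
#'
#' Fuzzy c-means memberships with fuzzifier 2 and two clusters:
#' \deqn{m_L = \frac{d_L^{-2}}{d_K^{-2} + d_B^{-2}},\qquad
#'       d_L = |I - C_L|.}
#' A pixel at zero distance from one centroid gets membership 1 for that
#' cluster and 0 for the other; at zero distance from both (identical
#' centroids) it gets 0.5/0.5.
#'
#' @param image intensity matrix.
#' @param cK,cB finite cluster centroids.
#' @return list with membership matrices `mK`, `mB`
#'   (`mK + mB == 1` everywhere).
#' @export
updateMemberships <- function(image, cK, cB) {
  if (!is.finite(cK) || !is.finite(cB)) stop("centroids must be finite")
  dK2 <- (image - cK)^2
  dB2 <- (image - cB)^2
  den <- dK2 + dB2
  mK <- ifelse(den == 0, 0.5, dB2 / den)
  if (!is.matrix(mK)) mK <- matrix(mK, nrow(image), ncol(image))
  list(mK = mK, mB = 1 - mK)
}

#' Heaviside-weighted centroid update
#'
#' Centroids re-estimated with squared memberships weighted by the smeared
#' Heaviside of the level-set field (kidney) or its complement
#' (background):
#' \deqn{C_L = \frac{\sum R_L(\phi)\, I\, m_L^2}{\sum R_L(\phi)\, m_L^2}},
#' with \eqn{R_K = V_\varepsilon(\phi)} and
#' \eqn{R_B = 1 - V_\varepsilon(\phi)}.
#'
#' @param image intensity matrix.
#' @param phi level-set field.
#' @param mK,mB membership fields.
#' @param eps smearing width.
#' @return named numeric(2): `cK`, `cB`.
#' @export
updateCentroids <- function(image, phi, mK, mB, eps) {
  .checkSameDim(image, phi, mK, mB)
  .updateCentroidsV(image, smearedHeaviside(phi, eps), mK, mB)
}

# workhorse on a precomputed Heaviside field (shared within an iteration)
.updateCentroidsV <- function(image, RK, mK, mB) {
  wK <- RK * mK^2
  wB <- (1 - RK) * mB^2
  sK <- sum(wK)
  sB <- sum(wB)
  if (sK <= 0 || sB <= 0)
    stop("degenerate fuzzy state: a centroid denominator is zero")
  c(cK = sum(wK * image) / sK, cB = sum(wB * image) / sB)
}
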