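#' Phantom specification constructor
#'
#' Defaults emulate the geometry and contrast of a 256 x 256 abdominal
#' DCE-MR slice: a bean-shaped kidney (outer ellipse minus an offset notch
#' ellipse) covering about 4% of the image, a bright kidney on a darker
#' background with a perfusion-phase contrast multiplier, and moderate
#' additive Gaussian noise (sd 10 on a 0--255 grey scale).
#'
#' @param dim integer(2) grid size.
#' @param outerSemiAxes,notchSemiAxes,notchOffset bean geometry, pixels.
#' @param kidneyIntensity,backgroundIntensity,phaseMultiplier grey levels.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param semiAxisJitter relative semi-axis jitter for cohort variability.
#' @param seed integer seed.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(256L, 256L), outerSemiAxes = c(26, 40),
                        notchSemiAxes = c(14, 12), notchOffset = c(-26, 0),
                        kidneyIntensity = 100, backgroundIntensity = 60,
                        phaseMultiplier = 1.5, noiseSd = 10,
                        semiAxisJitter = 0.1, seed = 1L) {
  methods::new("PhantomSpec", dim = as.integer(dim),
               outerSemiAxes = as.numeric(outerSemiAxes),
               notchSemiAxes = as.numeric(notchSemiAxes),
               notchOffset = as.numeric(notchOffset),
               kidneyIntensity = as.numeric(kidneyIntensity),
               backgroundIntensity = as.numeric(backgroundIntensity),
               phaseMultiplier = as.numeric(phaseMultiplier),
               noiseSd = as.numeric(noiseSd),
               semiAxisJitter = as.numeric(semiAxisJitter),
               seed = as.integer(seed))
}

#' Generate a bean-shaped kidney mask
#'
#' Outer ellipse minus the offset notch ellipse (the hilum), centred on
#' the grid.  With `semiAxisJitter > 0` all four semi-axes are multiplied
#' by independent seeded uniform factors in
#' `[1 - jitter, 1 + jitter]`, which is how cohort shape variability is
#' produced.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed optional seed override (defaults to `spec@seed`).
#' @return logical matrix.
#' @export
generateKidneyMask <- function(spec, seed = spec@seed) {
  methods::validObject(spec)
  ax <- c(spec@outerSemiAxes, spec@notchSemiAxes)
  if (spec@semiAxisJitter > 0)
    ax <- ax * .withSeed(seed, stats::runif(4, 1 - spec@semiAxisJitter,
                                            1 + spec@semiAxisJitter))
  g <- .coordGrids(spec@dim)
  ctr <- .defaultCenter(spec@dim)
  outer <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 <= 1
  nx <- ctr[1] + spec@notchOffset[1]
  ny <- ctr[2] + spec@notchOffset[2]
  notch <- ((g$x - nx) / ax[3])^2 + ((g$y - ny) / ax[4])^2 <= 1
  outer & !notch
}

#' Render a contrast-phase phantom image
#'
#' Kidney pixels take `kidneyIntensity * phaseMultiplier`, background
#' pixels `backgroundIntensity`; seeded Gaussian noise of sd `noiseSd` is
#' added and the result clipped to `[0, 255]`.
#'
#' @param mask logical kidney mask.
#' @param spec a [PhantomSpec-class].
#' @param seed optional seed override.
#' @return numeric intensity matrix.
#' @export
generateDCEImage <- function(mask, spec, seed = spec@seed) {
  .checkSameDim(mask, matrix(0, spec@dim[1], spec@dim[2]))
  img <- matrix(spec@backgroundIntensity, spec@dim[1], spec@dim[2])
  img[mask] <- spec@kidneyIntensity * spec@phaseMultiplier
  if (spec@noiseSd > 0)
    img <- img + .withSeed(seed,
      matrix(stats::rnorm(prod(spec@dim), 0, spec@noiseSd),
             spec@dim[1], spec@dim[2]))
  pmin(pmax(img, 0), 255)
}

#' Generate an aligned training cohort of kidney masks
#'
#' `n` masks sharing the base bean geometry, each with its own seeded
#' semi-axis jitter, all centred (i.e. pre-aligned, as the prior builder
#' requires).
#'
#' @param n cohort size (>= 2).
#' @param spec a [PhantomSpec-class].
#' @return list of `n` logical masks.
#' @export
generateTrainingCohort <- function(n, spec) {
  if (n < 2) stop("a cohort needs at least 2 masks")
  lapply(seq_len(n), function(i)
    generateKidneyMask(spec, seed = spec@seed + i))
}

#' Apply a random affine misalignment
#'
#' Samples affine parameters uniformly within the stated ranges (rotation
#' and translation symmetric about 0; shear in `[0, range]`; scale in
#' `1 +/- range`) and resamples image (bilinear) and mask (nearest
#' neighbour) at the transformed coordinates
#' \eqn{X' = A(X - c) + c + T}.  The returned parameters are exactly the
#' ground truth that [segmentKidney()] should recover, since the prior
#' warp uses the same forward map.
#'
#' @param image intensity matrix.
#' @param mask logical mask on the same grid.
#' @param ranges named list of half-ranges: `theta` (radians), `shear`,
#'   `translate` (pixels), `scale` (relative); defaults mirror the test
#'   augmentation protocol (rotation within +/- 2 degrees, shear in
#'   `[0, 0.12]`, translation within +/- 5 px, no scaling).
#' @param seed integer seed.
#' @return list: `image`, `mask`, `params` (the true [AffineParams-class]).
#' @export
perturbAffine <- function(image, mask,
                          ranges = list(theta = 2 * pi / 180, shear = 0.12,
                                        translate = 5, scale = 0),
                          seed = 1L) {
  .checkSameDim(image, mask)
  p <- .withSeed(seed, {
    affineParams(theta = stats::runif(1, -ranges$theta, ranges$theta),
                 sx = 1 + stats::runif(1, -ranges$scale, ranges$scale),
                 sy = 1 + stats::runif(1, -ranges$scale, ranges$scale),
                 hx = stats::runif(1, 0, ranges$shear),
                 hy = stats::runif(1, 0, ranges$shear),
                 tx = stats::runif(1, -ranges$translate, ranges$translate),
                 ty = stats::runif(1, -ranges$translate, ranges$translate))
  })
  dm <- dim(image)
  ctr <- .defaultCenter(dm)
  sm <- .affineSampler(p, dm, ctr)
  wimg <- .sampleBilinear(image, sm)
  wimg[!sm$inside] <- stats::median(image[!mask])
  wmask <- .sampleNearest(mask, sm) > 0
  list(image = wimg, mask = wmask, params = p)
}
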