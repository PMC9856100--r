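#' @import methods
NULL

#' Affine transformation parameters
#'
#' Parameters of the 2D affine map aligning image coordinates with the
#' reference frame of the shape-prior model.  The linear part is composed
#' as rotation %*% shear %*% scale (in exactly that order), applied about a
#' configurable centre, followed by a translation:
#' \deqn{\hat X = R(\theta)\,H(h_x,h_y)\,S(s_x,s_y)\,(X - c) + c + T.}
#'
#' The identity state (the initialization used for segmentation) is
#' \eqn{\theta = 0}, \eqn{s_x = s_y = 1}, \eqn{h_x = h_y = 0},
#' \eqn{t_x = t_y = 0}.
#'
#' @slot theta rotation angle, radians (counter-clockwise in pixel
#'   coordinates with y increasing downwards).
#' @slot sx,sy scale factors along x (columns) and y (rows); strictly
#'   positive.
#' @slot hx,hy dimensionless shear coefficients.
#' @slot tx,ty translations in pixels.
#'
#' @seealso [affineParams()], [composeAffine()], [transformCoords()]
#' @export
setClass("AffineParams",
  representation(theta = "numeric", sx = "numeric", sy = "numeric",
                 hx = "numeric", hy = "numeric",
                 tx = "numeric", ty = "numeric"),
  prototype(theta = 0, sx = 1, sy = 1, hx = 0, hy = 0, tx = 0, ty = 0))

setValidity("AffineParams", function(object) {
  v <- c(object@theta, object@sx, object@sy, object@hx, object@hy,
         object@tx, object@ty)
  if (length(v) != 7L || !all(is.finite(v)))
    return("all affine parameters must be finite scalars")
  if (object@sx <= 0 || object@sy <= 0)
    return("scale factors sx, sy must be strictly positive")
  TRUE
})

#' Statistical shape-prior model
#'
#' Pixel-wise kidney/background label probabilities estimated from a cohort
#' of co-aligned binary training masks by Bayesian label-probability
#' estimation, together with a level-set representation of the prior shape
#' (the signed distance to the 0.5 isocontour of the kidney probability).
#'
#' @slot PK,PB matrices of kidney / background probabilities; strictly
#'   inside (0, 1) and summing to 1 pixel-wise.
#' @slot phiPK prior level-set field: signed distance (pixels) to the 0.5
#'   isocontour of `PK`, positive where `PK > 0.5`.
#' @slot N number of training masks.
#' @slot beta positive additive weight of the Bayesian estimator.
#'
#' @seealso [buildShapePrior()], [priorLevelSet()], [saveShapePrior()]
#' @export
setClass("ShapePriorModel",
  representation(PK = "matrix", PB = "matrix", phiPK = "matrix",
                 N = "integer", beta = "numeric"))

setValidity("ShapePriorModel", function(object) {
  if (!all(dim(object@PK) == dim(object@PB)) ||
      !all(dim(object@PK) == dim(object@phiPK)))
    return("PK, PB and phiPK must share the same dimensions")
  if (object@N < 2L) return("a shape prior requires at least 2 training masks")
  if (length(object@beta) != 1L || !is.finite(object@beta) || object@beta <= 0)
    return("beta must be a positive scalar")
  if (any(object@PK <= 0) || any(object@PK >= 1) ||
      any(object@PB <= 0) || any(object@PB >= 1))
    return("probabilities must lie strictly inside (0, 1)")
  if (max(abs(object@PK + object@PB - 1)) > 1e-6)
    return("PK + PB must equal 1 at every pixel (tolerance 1e-6)")
  if (!all(is.finite(object@phiPK)))
    return("phiPK must be finite")
  TRUE
})

#' Segmentation configuration
#'
#' All tunable parameters of the joint segmentation--registration
#' procedure.  The defaults are the fixed setting used throughout the
#' reference experiments:
#' \eqn{(\lambda_1,\lambda_2,\lambda_3,\varepsilon,\beta,
#' \gamma_1,\gamma_2,\gamma_3,\gamma_4,\gamma_5) =
#' (6, 6, 0.1, 1.5, 1, 0.8, 10^{-14}, 10^{-10}, 10^{-10}, 10^{-9})}.
#'
#' @slot lambda numeric(3): weights of the length, clustering and
#'   registration energy terms (all >= 0).
#' @slot eps smearing width \eqn{\varepsilon > 0} (pixels) of the regularized
#'   Heaviside/Dirac kernels.
#' @slot gamma numeric(5): positive step sizes; `gamma[1]` drives the
#'   level-set update, `gamma[2:5]` drive scale, shear, translation and
#'   rotation respectively.
#' @slot beta additive weight used when a prior is (re)built from masks.
#' @slot maxIters maximum number of evolution iterations.
#' @slot energyTol relative total-energy change over `tolWindow` iterations
#'   below which the run is declared converged.
#' @slot tolWindow window length (iterations) of the convergence test
#'   (default 12; consecutive window means are compared, and an even
#'   window length straddles the small even-period boundary-pixel flicker
#'   of the discrete scheme in phase).
#' @slot initMode contour initialization: `"border"`, `"disk"` or `"random"`.
#' @slot seed integer seed for the random initialization mode.
#' @slot clampPhi logical; keep the level-set field inside the active band
#'   `[-0.95 eps, 0.95 eps]` after each update (applied only to pixels the
#'   update touched), so that no pixel ever freezes irrecoverably outside
#'   the support of the smeared Dirac kernel.
#' @slot normalizeGradients logical; when `TRUE`, registration updates use
#'   the direction of each parameter-group gradient with fixed per-group
#'   rates (`normRates`) instead of the raw-gradient steps `gamma[2:5]`.
#'   Intended for phantom-scale images where un-normalized pixel-sum
#'   gradients differ from the clinical setting by orders of magnitude.
#' @slot normRates numeric(4), named `s`, `h`, `t`, `theta`: learning
#'   rates of the normalized registration mode, applied to the pixel-mean
#'   gradient of each parameter group.
#' @slot gradSmooth exponential moving-average factor in `[0, 1)` applied
#'   to the registration gradients in normalized mode (0 disables).  The
#'   pixel-sum gradients are a rough function of sub-pixel prior placement
#'   (the bilinear interpolant has kinks at cell boundaries, and the noisy
#'   membership field multiplies them); averaging along the descent
#'   trajectory recovers the smooth component.
#' @slot regWarmup number of initial prior-free iterations (default 0 in
#'   plain mode, 80 when `normalizeGradients = TRUE`).
#'   During warm-up the contour evolves under the length term and an
#'   uninformative prior (both label probabilities 0.5, no shape-mismatch
#'   force) and the affine parameters are held fixed: the contour-seeded
#'   centroids carry no reliable intensity information yet, and a
#'   misaligned prior acting on that transient both corrupts the contour
#'   and produces meaningless registration gradients.  After warm-up the
#'   contour has locked onto the image intensities and the joint phase
#'   starts from a clean shape-mismatch signal.
#' @slot reinitEvery reinitialize the level-set field to a (band-clamped)
#'   signed distance of its own zero set every this many iterations
#'   (0 = never; default 1).  Without reinitialization the field profile
#'   steepens against the band clamp and the discrete length term
#'   \eqn{\sum\delta_\varepsilon(\phi)|\nabla\phi|} grows even while
#'   the contour itself is stationary, so the energy trace drifts upward;
#'   restoring the signed-distance profile keeps the discretization
#'   faithful to the contour length.
#' @slot innerSteps number of level-set evolution steps per registration
#'   update (default 1: simultaneous update).
#' @slot rescaleIntensities logical; map the image to `[0, 1]` before
#'   clustering (the membership formula is intensity-scale dependent).
#'
#' @seealso [segmentationConfig()], [segmentKidney()]
#' @export
setClass("SegmentationConfig",
  representation(lambda = "numeric", eps = "numeric", gamma = "numeric",
                 beta = "numeric", maxIters = "integer",
                 energyTol = "numeric", tolWindow = "integer",
                 initMode = "character", seed = "integer",
                 clampPhi = "logical", normalizeGradients = "logical",
                 normRates = "numeric", gradSmooth = "numeric",
                 regWarmup = "integer", reinitEvery = "integer",
                 innerSteps = "integer", rescaleIntensities = "logical"))

setValidity("SegmentationConfig", function(object) {
  if (length(object@lambda) != 3L || any(object@lambda < 0))
    return("lambda must be three nonnegative weights")
  if (object@eps <= 0) return("eps must be strictly positive")
  if (length(object@gamma) != 5L || any(object@gamma <= 0))
    return("gamma must be five positive step sizes")
  if (object@maxIters < 1L) return("maxIters must be >= 1")
  if (object@energyTol < 0) return("energyTol must be >= 0")
  if (object@tolWindow < 1L) return("tolWindow must be >= 1")
  if (!object@initMode %in% c("border", "disk", "random"))
    return("initMode must be one of 'border', 'disk', 'random'")
  if (length(object@normRates) != 4L || any(object@normRates <= 0) ||
      !identical(names(object@normRates), c("s", "h", "t", "theta")))
    return("normRates must be positive and named c('s','h','t','theta')")
  if (object@innerSteps < 1L) return("innerSteps must be >= 1")
  if (object@gradSmooth < 0 || object@gradSmooth >= 1)
    return("gradSmooth must lie in [0, 1)")
  if (object@regWarmup < 0L) return("regWarmup must be >= 0")
  if (object@reinitEvery < 0L) return("reinitEvery must be >= 0")
  TRUE
})

#' Result of a joint segmentation--registration run
#'
#' @slot mask logical matrix; the segmented kidney, `{phi > 0}`.
#' @slot phi the final level-set field.
#' @slot finalParams estimated [AffineParams-class] aligning image
#'   coordinates with the prior's reference frame.
#' @slot energyTrace data.frame with one row per iteration: total energy
#'   `E`, its components `L`, `EFCM`, `EREG`, and the affine parameters.
#' @slot iterations number of iterations run.
#' @slot converged logical; `FALSE` means the iteration budget was reached
#'   before the energy stabilized (not an error).
#' @slot seed the seed recorded for the run.
#'
#' @seealso [segmentKidney()]
#' @export
setClass("SegmentationResult",
  representation(mask = "matrix", phi = "matrix",
                 finalParams = "AffineParams", energyTrace = "data.frame",
                 iterations = "integer", converged = "logical",
                 seed = "integer"))

setValidity("SegmentationResult", function(object) {
  if (!all(dim(object@mask) == dim(object@phi)))
    return("mask and phi must share dimensions")
  if (nrow(object@energyTrace) != object@iterations)
    return("energyTrace must have one row per iteration")
  TRUE
})

#' Synthetic kidney phantom specification
#'
#' Geometry and intensity model of the bean-shaped synthetic kidney
#' phantoms: a bright outer ellipse minus an offset notch ellipse (the
#' hilum) on a darker background, with a contrast-phase multiplier
#' emulating perfusion-phase intensity changes and additive Gaussian
#' noise.  All randomness (cohort shape jitter, noise) is seeded.
#'
#' @slot dim integer(2): image rows, columns.
#' @slot outerSemiAxes numeric(2): outer ellipse semi-axes (x, y), pixels.
#' @slot notchSemiAxes numeric(2): notch ellipse semi-axes (x, y), pixels.
#' @slot notchOffset numeric(2): notch centre offset (x, y) from the image
#'   centre, pixels.
#' @slot kidneyIntensity,backgroundIntensity base grey levels.
#' @slot phaseMultiplier multiplicative contrast factor applied to the
#'   kidney intensity (perfusion-phase emulation).
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @slot semiAxisJitter relative (+/-) uniform jitter of the semi-axes used
#'   for cohort variability.
#' @slot seed integer seed.
#'
#' @seealso [phantomSpec()], [generateKidneyMask()], [generateDCEImage()]
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", outerSemiAxes = "numeric",
                 notchSemiAxes = "numeric", notchOffset = "numeric",
                 kidneyIntensity = "numeric", backgroundIntensity = "numeric",
                 phaseMultiplier = "numeric", noiseSd = "numeric",
                 semiAxisJitter = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 2L || any(object@dim < 8L))
    return("dim must be two integers >= 8")
  if (any(object@outerSemiAxes <= 0) || any(object@notchSemiAxes <= 0))
    return("semi-axes must be positive")
  if (object@kidneyIntensity * object@phaseMultiplier ==
      object@backgroundIntensity)
    return("kidney and background intensities must differ")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@semiAxisJitter < 0 || object@semiAxisJitter >= 1)
    return("semiAxisJitter must be in [0, 1)")
  cx <- (object@dim[2] + 1) / 2; cy <- (object@dim[1] + 1) / 2
  jit <- 1 + object@semiAxisJitter
  if (cx + object@outerSemiAxes[1] * jit > object@dim[2] ||
      cy + object@outerSemiAxes[2] * jit > object@dim[1])
    return("phantom geometry (including jitter) exceeds the grid")
  TRUE
})
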