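#' @include AllClasses.R
NULL

#' Accessors for segmentation results and shape priors
#'
#' Small accessor generics so that user code never reaches into slots:
#' `segMask()` returns the binary kidney mask, `energyTrace()` the
#' per-iteration energy/parameter table, `affineEstimate()` the estimated
#' affine parameters as a named numeric vector, `nIterations()` and
#' `hasConverged()` the run diagnostics; `priorProb()` returns a
#' probability field of a [ShapePriorModel-class], `priorPhi()` its
#' level-set representation and `nTraining()` its cohort size.
#'
#' @param object a [SegmentationResult-class] or [ShapePriorModel-class].
#' @param label which probability field, `"kidney"` or `"background"`.
#' @return see details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("segMask", function(object) standardGeneric("segMask"))

#' @rdname accessors
#' @export
setGeneric("energyTrace", function(object) standardGeneric("energyTrace"))

#' @rdname accessors
#' @export
setGeneric("affineEstimate", function(object) standardGeneric("affineEstimate"))

#' @rdname accessors
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))

#' @rdname accessors
#' @export
setGeneric("hasConverged", function(object) standardGeneric("hasConverged"))

#' @rdname accessors
#' @export
setGeneric("priorProb", function(object, label = c("kidney", "background"))
  standardGeneric("priorProb"))

#' @rdname accessors
#' @export
setGeneric("priorPhi", function(object) standardGeneric("priorPhi"))

#' @rdname accessors
#' @export
setGeneric("nTraining", function(object) standardGeneric("nTraining"))

#' @rdname accessors
setMethod("segMask", "SegmentationResult", function(object) object@mask)

#' @rdname accessors
setMethod("energyTrace", "SegmentationResult", function(object)
  object@energyTrace)

#' @rdname accessors
setMethod("affineEstimate", "SegmentationResult", function(object)
  affineVector(object@finalParams))

#' @rdname accessors
setMethod("nIterations", "SegmentationResult", function(object)
  object@iterations)

#' @rdname accessors
setMethod("hasConverged", "SegmentationResult", function(object)
  object@converged)

#' @rdname accessors
setMethod("priorProb", "ShapePriorModel", function(object, label) {
  label <- match.arg(label, c("kidney", "background"))
  if (label == "kidney") object@PK else object@PB
})

#' @rdname accessors
setMethod("priorPhi", "ShapePriorModel", function(object) object@phiPK)

#' @rdname accessors
setMethod("nTraining", "ShapePriorModel", function(object) object@N)

#' @exportMethod show
setMethod("show", "AffineParams", function(object) {
  v <- affineVector(object)
  cat("AffineParams (image -> prior frame)\n")
  cat(sprintf("  theta = %.6g rad (%.4g deg)\n", v["theta"],
              v["theta"] * 180 / pi))
  cat(sprintf("  scale = (%.6g, %.6g)  shear = (%.6g, %.6g)\n",
              v["sx"], v["sy"], v["hx"], v["hy"]))
  cat(sprintf("  translation = (%.6g, %.6g) px\n", v["tx"], v["ty"]))
  invisible(object)
})

setMethod("show", "ShapePriorModel", function(object) {
  cat(sprintf("ShapePriorModel: %d x %d grid, N = %d masks, beta = %g\n",
              nrow(object@PK), ncol(object@PK), object@N, object@beta))
  cat(sprintf("  P(kidney) in [%.4g, %.4g]; prior shape area = %d px\n",
              min(object@PK), max(object@PK), sum(object@PK > 0.5)))
  invisible(object)
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d x %d, %d iterations (%s)\n",
              nrow(object@mask), ncol(object@mask), object@iterations,
              if (object@converged) "converged" else "not converged"))
  cat(sprintf("  kidney area = %d px (%.2f%% of image)\n", sum(object@mask),
              100 * mean(object@mask)))
  if (object@iterations > 0) {
    tr <- object@energyTrace
    cat(sprintf("  energy: %.6g -> %.6g\n", tr$E[1], tr$E[nrow(tr)]))
  }
  show(object@finalParams)
  invisible(object)
})

setMethod("show", "SegmentationConfig", function(object) {
  cat("SegmentationConfig\n")
  cat(sprintf("  lambda = (%g, %g, %g), eps = %g, beta = %g\n",
              object@lambda[1], object@lambda[2], object@lambda[3],
              object@eps, object@beta))
  cat(sprintf("  gamma = (%g, %g, %g, %g, %g)\n", object@gamma[1],
              object@gamma[2], object@gamma[3], object@gamma[4],
              object@gamma[5]))
  cat(sprintf("  maxIters = %d, energyTol = %g (window %d), init = %s\n",
              object@maxIters, object@energyTol, object@tolWindow,
              object@initMode))
  cat(sprintf("  normalizeGradients = %s, innerSteps = %d, seed = %d\n",
              object@normalizeGradients, object@innerSteps, object@seed))
  invisible(object)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d grid, seed = %d\n", object@dim[1],
              object@dim[2], object@seed))
  cat(sprintf("  outer semi-axes (%g, %g), notch (%g, %g) at offset (%g, %g)\n",
              object@outerSemiAxes[1], object@outerSemiAxes[2],
              object@notchSemiAxes[1], object@notchSemiAxes[2],
              object@notchOffset[1], object@notchOffset[2]))
  cat(sprintf("  intensities: kidney %g x phase %g, background %g, noise sd %g\n",
              object@kidneyIntensity, object@phaseMultiplier,
              object@backgroundIntensity, object@noiseSd))
  invisible(object)
})
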