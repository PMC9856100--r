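#' Segmentation configuration constructor
#'
#' Returns a [SegmentationConfig-class] with the reference defaults
#' `lambda = c(6, 6, 0.1)`, `eps = 1.5`, `beta = 1`,
#' `gamma = c(0.8, 1e-14, 1e-10, 1e-10, 1e-9)`.
#'
#' @param lambda,eps,gamma,beta see [SegmentationConfig-class].
#' @param maxIters,energyTol,tolWindow convergence controls.
#' @param initMode,seed contour initialization.
#' @param clampPhi,normalizeGradients,normRates,gradSmooth,regWarmup,reinitEvery,innerSteps,rescaleIntensities
#'   further switches, see [SegmentationConfig-class].
#' @return a validated [SegmentationConfig-class].
#' @export
segmentationConfig <- function(lambda = c(6, 6, 0.1), eps = 1.5,
                               gamma = c(0.8, 1e-14, 1e-10, 1e-10, 1e-9),
                               beta = 1, maxIters = 500L, energyTol = 1e-4,
                               tolWindow = 12L,
                               initMode = c("border", "disk", "random"),
                               seed = 1L, clampPhi = TRUE,
                               normalizeGradients = FALSE,
                               normRates = c(s = 1.5, h = 4, t = 8000,
                                             theta = 2),
                               gradSmooth = 0.9, regWarmup = NULL,
                               reinitEvery = 1L,
                               innerSteps = 1L, rescaleIntensities = FALSE) {
  initMode <- match.arg(initMode)
  # the prior-free warm-up exists to give the (normalized-mode)
  # registration a clean start; plain-mode runs descend the joint energy
  # from the first iteration
  if (is.null(regWarmup)) regWarmup <- if (normalizeGradients) 80L else 0L
  methods::new("SegmentationConfig", lambda = as.numeric(lambda),
               eps = as.numeric(eps), gamma = as.numeric(gamma),
               beta = as.numeric(beta), maxIters = as.integer(maxIters),
               energyTol = as.numeric(energyTol),
               tolWindow = as.integer(tolWindow), initMode = initMode,
               seed = as.integer(seed), clampPhi = clampPhi,
               normalizeGradients = normalizeGradients,
               normRates = normRates, gradSmooth = as.numeric(gradSmooth),
               regWarmup = as.integer(regWarmup),
               reinitEvery = as.integer(reinitEvery),
               innerSteps = as.integer(innerSteps),
               rescaleIntensities = rescaleIntensities)
}

# band-clamped signed-distance reinitialization of the level-set field;
# preserves the zero set (pixel-wise sign) while restoring the profile
.reinitPhi <- function(phi, eps) {
  mask <- phi > 0
  if (!any(mask) || all(mask)) return(phi)
  nr <- nrow(phi)
  din <- as.matrix(EBImage::distmap(matrix(as.numeric(mask), nr)))
  dout <- as.matrix(EBImage::distmap(matrix(as.numeric(!mask), nr)))
  sd <- ifelse(mask, din - 0.5, -(dout - 0.5))
  pmin(pmax(sd, -0.95 * eps), 0.95 * eps)
}

# prior fields bundled once per prior
.priorFieldSet <- function(prior) {
  list(PK = prior@PK, PB = prior@PB, phiPK = prior@phiPK,
       maxPB = max(prior@PB))
}

# value and exact spatial derivative of the bilinear interpolant:
# using the interpolant's own derivative (rather than grid central
# differences resampled at X-hat) makes the parameter gradients the exact
# chain rule of the discrete energy, which is what the finite-difference
# consistency of the registration gradients requires.  On cell boundaries
# (a sample landing exactly on a grid line) the interpolant has a kink;
# the centred average of the two adjacent cell slopes is used there, so a
# symmetric configuration yields a symmetric gradient.
.sampleBilinearGrad <- function(field, sm) {
  f00 <- field[sm$k00]; f10 <- field[sm$k10]
  f01 <- field[sm$k01]; f11 <- field[sm$k11]
  nr <- sm$dim[1]; nc <- sm$dim[2]
  nrp <- sm$priorDim[1]
  # recover the fractional weights: w10 = (1-wx)*wy, w11 = wx*wy
  wy <- sm$w10 + sm$w11
  wx <- sm$w01 + sm$w11
  dx <- (1 - wy) * (f01 - f00) + wy * (f11 - f10)
  dy <- (1 - wx) * (f10 - f00) + wx * (f11 - f01)
  ix <- which(wx == 0 & sm$j0 > 1)
  if (length(ix)) {
    fm <- field[sm$k00[ix] - nrp]
    fmy <- field[sm$k10[ix] - nrp]
    left <- (1 - wy[ix]) * (f00[ix] - fm) + wy[ix] * (f10[ix] - fmy)
    dx[ix] <- (dx[ix] + left) / 2
  }
  iy <- which(wy == 0 & sm$i0 > 1)
  if (length(iy)) {
    fm <- field[sm$k00[iy] - 1]
    fmx <- field[sm$k01[iy] - 1]
    up <- (1 - wx[iy]) * (f00[iy] - fm) + wx[iy] * (f01[iy] - fmx)
    dy[iy] <- (dy[iy] + up) / 2
  }
  list(v = matrix(sm$w00 * f00 + sm$w10 * f10 + sm$w01 * f01 +
                    sm$w11 * f11, nr, nc),
       dx = matrix(dx, nr, nc),
       dy = matrix(dy, nr, nc))
}

# warp a prepared field set at a given sampler
.warpFieldSet <- function(pf, sm) {
  sK <- .sampleBilinearGrad(pf$PK, sm)
  sB <- .sampleBilinearGrad(pf$PB, sm)
  sP <- .sampleBilinearGrad(pf$phiPK, sm)
  out <- list(PK = sK$v, PB = sB$v, phiPK = sP$v,
              dPKx = sK$dx, dPKy = sK$dy,
              dPBx = sB$dx, dPBy = sB$dy,
              dphix = sP$dx, dphiy = sP$dy)
  if (!all(sm$inside)) {
    off <- !sm$inside
    # off-grid rule: most-background probability, complement for kidney,
    # prior level set extended downhill by the distance to the grid; the
    # flat probability extension has zero gradient
    out$PB[off] <- pf$maxPB
    out$PK[off] <- 1 - pf$maxPB
    out$phiPK[off] <- out$phiPK[off] - sm$edgeDist[off]
    out$dPKx[off] <- 0; out$dPKy[off] <- 0
    out$dPBx[off] <- 0; out$dPBy[off] <- 0
  }
  out
}

#' Warp the shape prior onto the image grid
#'
#' Samples the prior probability fields, the prior level-set field, and
#' their precomputed grid gradients at the affinely transformed
#' coordinates \eqn{\hat X = A(X - c) + c + T} by bilinear interpolation.
#' Coordinates falling outside the prior grid receive the most-background
#' in-grid probability (`PB`), its complement for `PK`, and the prior
#' level set extended by the nearest-edge value minus the Euclidean
#' distance to the grid, so off-image placements never attract the
#' contour.
#'
#' @param prior a [ShapePriorModel-class].
#' @param p an [AffineParams-class].
#' @param dim integer(2) image grid size (rows, columns).
#' @param center transform centre; default the image centre.
#' @return list of warped matrices: `PK`, `PB`, `phiPK`, and gradients
#'   `dPKx`, `dPKy`, `dPBx`, `dPBy`, `dphix`, `dphiy`.
#' @export
warpPrior <- function(prior, p, dim = base::dim(prior@PK), center = NULL) {
  dim <- as.integer(dim)
  if (is.null(center)) center <- .defaultCenter(dim)
  sm <- .affineSampler(p, dim, center, priorDim = base::dim(prior@PK))
  .warpFieldSet(.priorFieldSet(prior), sm)
}

#' Total joint energy and its components
#'
#' Pixel-sum discretization of the joint functional:
#' length term \eqn{L = \sum \delta_\varepsilon(\phi)\,|\nabla\phi|},
#' clustering term \eqn{E_{FCM} = \sum V_\varepsilon(\phi)\, m_B\,
#' P_B(\hat X) + \sum (1 - V_\varepsilon(\phi))\, m_K\, P_K(\hat X)},
#' registration term \eqn{E_{REG} = \sum (V_\varepsilon(\phi) -
#' V_\varepsilon(\phi_{PK}(\hat X)))^2}, and
#' \eqn{E = \lambda_1 L + \lambda_2 E_{FCM} + \lambda_3 E_{REG}}.
#'
#' @param phi level-set field.
#' @param mK,mB membership fields.
#' @param PKw,PBw,phiPKw warped prior fields (see [warpPrior()]).
#' @param lambda numeric(3) weights.
#' @param eps smearing width.
#' @return named numeric(4): `E`, `L`, `EFCM`, `EREG`.
#' @export
totalEnergy <- function(phi, mK, mB, PKw, PBw, phiPKw, lambda, eps) {
  .checkSameDim(phi, mK, mB, PKw, PBw, phiPKw)
  .totalEnergyV(phi, smearedHeaviside(phi, eps),
                smearedHeaviside(phiPKw, eps), mK, mB, PKw, PBw, lambda,
                eps)
}

# workhorse on precomputed Heaviside fields (shared within an iteration)
.totalEnergyV <- function(phi, V, Vpk, mK, mB, PKw, PBw, lambda, eps) {
  px <- .gradX(phi); py <- .gradY(phi)
  L <- sum(smearedDirac(phi, eps) * sqrt(px * px + py * py))
  EFCM <- sum(V * mB * PBw) + sum((1 - V) * mK * PKw)
  EREG <- sum((V - Vpk)^2)
  c(E = lambda[1] * L + lambda[2] * EFCM + lambda[3] * EREG,
    L = L, EFCM = EFCM, EREG = EREG)
}

#' Joint kidney segmentation and registration
#'
#' Runs the full variational procedure: the level-set field is initialized
#' (`initMode`), the affine parameters start at the identity, and the
#' cluster centroids/memberships are seeded from the initial contour.
#' Each iteration then (1) warps the prior with the current affine
#' parameters, (2) evolves the level-set field one step ([evolveStep()];
#' `innerSteps` allows several), (3) re-estimates the centroids
#' ([updateCentroids()]) and memberships ([updateMemberships()]),
#' (4) updates the affine parameters by gradient descent
#' ([updateParams()]), and (5) records the energy.  The run stops when the
#' relative change of the total energy over `tolWindow` iterations drops
#' below `energyTol`, or after `maxIters` iterations (`converged = FALSE`,
#' not an error).  The segmentation is the final `{phi > 0}` region.
#'
#' The level-set field is initialized as a signed distance and then
#' compressed into the active band `[-0.9 eps, 0.9 eps]`: the smeared
#' Dirac kernel is compactly supported, so pixels outside the band would
#' otherwise never move.  With the whole image inside the band the
#' evolution force acts everywhere at once, which is what makes the result
#' insensitive to the initial contour location.
#'
#' @param image 2D intensity matrix.
#' @param prior a [ShapePriorModel-class] (grid need not equal the image
#'   grid, but usually does).
#' @param cfg a [SegmentationConfig-class].
#' @param center transform centre; default the image centre.
#' @return a [SegmentationResult-class].
#' @export
segmentKidney <- function(image, prior, cfg = segmentationConfig(),
                          center = NULL) {
  stopifnot(is.matrix(image), methods::is(prior, "ShapePriorModel"),
            methods::is(cfg, "SegmentationConfig"))
  methods::validObject(cfg)
  dm <- dim(image)
  if (is.null(center)) center <- .defaultCenter(dm)
  img <- image
  if (cfg@rescaleIntensities) {
    rng <- range(img)
    img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  }
  eps <- cfg@eps
  lambda <- cfg@lambda

  phi <- initializeLevelSet(dm, cfg@initMode, seed = cfg@seed)
  phi <- pmin(pmax(phi, -0.9 * eps), 0.9 * eps)

  p <- affineParams()
  cent <- initCentroids(img, phi)
  # the kidney is the contrast-enhanced (brighter) structure; an arbitrary
  # initial contour (notably the random mode) can seed the cluster labels
  # with either polarity, so the brighter centroid is assigned to the
  # kidney cluster before the first membership update
  if (cent[["cK"]] < cent[["cB"]])
    cent <- c(cK = cent[["cB"]], cB = cent[["cK"]])
  mem <- updateMemberships(img, cent[["cK"]], cent[["cB"]])

  pf <- .priorFieldSet(prior)
  grids <- .coordGrids(dm)
  priorDim <- dim(prior@PK)

  nTrace <- cfg@maxIters
  trace <- data.frame(iter = seq_len(nTrace), E = NA_real_, L = NA_real_,
                      EFCM = NA_real_, EREG = NA_real_, theta = NA_real_,
                      sx = NA_real_, sy = NA_real_, hx = NA_real_,
                      hy = NA_real_, tx = NA_real_, ty = NA_real_)
  converged <- FALSE
  gbar <- NULL   # EMA of the pixel-mean registration gradient
  half <- matrix(0.5, dm[1], dm[2])
  iter <- 0L
  while (iter < cfg@maxIters) {
    iter <- iter + 1L
    sm <- .affineSampler(p, dm, center, grids, priorDim)
    warp <- .warpFieldSet(pf, sm)
    warmup <- iter <= cfg@regWarmup
    for (k in seq_len(cfg@innerSteps)) {
      if (warmup) {
        # prior-free initialization phase: uninformative label
        # probabilities and no shape-mismatch force, so the contour first
        # locks onto the image intensities before the joint phase starts
        phi <- evolveStep(phi, mem$mK, mem$mB, half, half, warp$phiPK,
                          c(lambda[1], lambda[2], 0), cfg@gamma[1], eps,
                          clamp = cfg@clampPhi)
      } else {
        phi <- evolveStep(phi, mem$mK, mem$mB, warp$PK, warp$PB, warp$phiPK,
                          lambda, cfg@gamma[1], eps, clamp = cfg@clampPhi)
      }
    }
    if (cfg@reinitEvery > 0L && iter %% cfg@reinitEvery == 0L)
      phi <- .reinitPhi(phi, eps)
    V <- smearedHeaviside(phi, eps)
    Vpk <- smearedHeaviside(warp$phiPK, eps)
    cent <- .updateCentroidsV(img, V, mem$mK, mem$mB)
    mem <- updateMemberships(img, cent[["cK"]], cent[["cB"]])
    if (!warmup && (lambda[2] > 0 || lambda[3] > 0)) {
      g <- .regGradsFromWarp(phi, mem$mK, mem$mB, warp, p, lambda, eps,
                             center, grids, V = V, Vpk = Vpk,
                             dpk = smearedDirac(warp$phiPK, eps))
      if (cfg@normalizeGradients && cfg@gradSmooth > 0) {
        gm <- g / prod(dm)
        gbar <- if (is.null(gbar)) gm
                else cfg@gradSmooth * gbar + (1 - cfg@gradSmooth) * gm
        p <- updateParams(p, gbar, cfg@gamma, normalize = TRUE,
                          rates = cfg@normRates, gradScale = 1)
      } else {
        p <- updateParams(p, g, cfg@gamma,
                          normalize = cfg@normalizeGradients,
                          rates = cfg@normRates, gradScale = prod(dm))
      }
    }
    en <- .totalEnergyV(phi, V, Vpk, mem$mK, mem$mB, warp$PK, warp$PB,
                        lambda, eps)
    trace[iter, 2:5] <- en
    trace[iter, 6:12] <- affineVector(p)
    w <- cfg@tolWindow
    if (iter >= 2L * w) {
      # windowed means: single-pixel reinitialization flicker produces a
      # small deterministic limit cycle in E, so consecutive window means
      # (not single iterates) are compared
      cur <- (iter - w + 1L):iter
      prev <- (iter - 2L * w + 1L):(iter - w)
      eNow <- mean(trace$E[cur]); eOld <- mean(trace$E[prev])
      energyStable <- abs(eNow - eOld) <= cfg@energyTol * abs(eOld)
      # the affine parameters must also have stopped drifting: the energy
      # plateau of the contour can precede registration convergence
      pd <- function(col, lim)
        abs(mean(trace[[col]][cur]) - mean(trace[[col]][prev])) < lim
      paramStable <- pd("theta", 1e-3) && pd("tx", 0.1) && pd("ty", 0.1) &&
        pd("sx", 2e-3) && pd("sy", 2e-3) && pd("hx", 2e-3) && pd("hy", 2e-3)
      if (energyStable && paramStable) {
        converged <- TRUE
        break
      }
    }
  }
  trace <- trace[seq_len(iter), , drop = FALSE]
  methods::new("SegmentationResult", mask = phi > 0, phi = phi,
               finalParams = p, energyTrace = trace,
               iterations = iter, converged = converged, seed = cfg@seed)
}
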