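#' Build a statistical shape prior from aligned binary masks
#'
#' Pixel-wise Bayesian label-probability estimation from a cohort of `N`
#' co-aligned expert masks.  With two labels (`l = 2`), kidney count
#' \eqn{N_K} and observed-label count \eqn{O} (2 where both labels occur,
#' 1 where the cohort is unanimous), an observed label gets
#' \deqn{P_L = \frac{N_L + \beta}{N + \beta O}\cdot\frac{N}{N + l - O},}
#' and the unobserved label of a unanimous pixel gets
#' \deqn{P_L = \frac{1}{l - O}\left(1 - \frac{N}{N + l - O}\right).}
#' Unlike a first-order frequency prior, no pixel ever receives an exact
#' 0 or 1: a unanimous-kidney pixel gets \eqn{N/(N+1)}, the background
#' there \eqn{1/(N+1)}.
#'
#' The prior's level-set representation `phiPK` is the signed Euclidean
#' distance to the 0.5 isocontour of the kidney probability (see
#' [priorLevelSet()]); its gradient drives the registration force.
#'
#' Training masks must already be co-aligned (mask co-registration is out
#' of scope; the phantom cohort generator produces aligned cohorts).
#'
#' @param masks list of >= 2 binary matrices (values 0/1) of equal size.
#' @param beta positive additive weight (default 1).
#' @return a [ShapePriorModel-class].
#' @examples
#' m <- matrix(0, 32, 32); m[10:22, 12:20] <- 1
#' prior <- buildShapePrior(list(m, m, m), beta = 1)
#' range(priorProb(prior, "kidney"))   # 1/4 outside, 3/4 inside (N = 3)
#' @export
buildShapePrior <- function(masks, beta = 1) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("at least 2 training masks are required")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a positive scalar")
  d <- dim(masks[[1]])
  for (m in masks) {
    if (!is.matrix(m) || !all(dim(m) == d))
      stop("all masks must be matrices of identical dimensions")
    if (!all(m %in% c(0, 1)))
      stop("masks must be binary (values 0/1)")
  }
  N <- length(masks)
  NK <- Reduce(`+`, masks)
  NB <- N - NK
  mixed <- NK > 0 & NK < N               # O = 2
  # O = 2: second factor N/(N + l - O) = 1
  PK <- (NK + beta) / (N + 2 * beta)
  PB <- (NB + beta) / (N + 2 * beta)
  # O = 1: observed label N/(N+1) (beta cancels), unobserved 1/(N+1)
  PK[!mixed] <- ifelse(NK[!mixed] == N, N / (N + 1), 1 / (N + 1))
  PB[!mixed] <- ifelse(NB[!mixed] == N, N / (N + 1), 1 / (N + 1))
  methods::new("ShapePriorModel", PK = PK, PB = PB,
               phiPK = priorLevelSet(PK), N = as.integer(N),
               beta = as.numeric(beta))
}

#' Level-set representation of a probability field
#'
#' Signed Euclidean distance (pixels) to the 0.5 isocontour of the kidney
#' probability, positive where `PK > 0.5`.  Computed from the exact
#' Euclidean distance transform of the thresholded field, with a half-pixel
#' correction so pixels adjacent to the isocontour sit at roughly
#' \eqn{\pm 0.5}.
#'
#' @param PK kidney-probability matrix with values in (0, 1).
#' @return signed-distance matrix.
#' @export
priorLevelSet <- function(PK) {
  inside <- PK > 0.5
  if (!any(inside) || all(inside))
    stop("degenerate prior: the kidney probability never crosses 0.5")
  din <- as.matrix(EBImage::distmap(matrix(as.numeric(inside), nrow(PK))))
  dout <- as.matrix(EBImage::distmap(matrix(as.numeric(!inside), nrow(PK))))
  ifelse(inside, din - 0.5, -(dout - 0.5))
}

#' Save / load a shape-prior model
#'
#' Lossless round-trip of all fields (`PK`, `PB`, `phiPK`) and metadata
#' (`N`, `beta`) through R's compressed serialization.  `loadShapePrior()`
#' re-validates the object (in particular that `PK + PB` stays within
#' `1e-6` of 1) and refuses corrupt files.
#'
#' @param model a [ShapePriorModel-class].
#' @param path file path (conventionally `.rds`).
#' @return `saveShapePrior()` the path, invisibly; `loadShapePrior()` the
#'   model.
#' @export
saveShapePrior <- function(model, path) {
  stopifnot(methods::is(model, "ShapePriorModel"))
  methods::validObject(model)
  saveRDS(model, path, version = 3, compress = "gzip")
  invisible(path)
}

#' @rdname saveShapePrior
#' @export
loadShapePrior <- function(path) {
  if (!file.exists(path)) stop("prior model file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable prior model file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (!methods::is(obj, "ShapePriorModel"))
    stop("file does not contain a ShapePriorModel: ", path)
  methods::validObject(obj)
  obj
}
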