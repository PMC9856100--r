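#' Segmentation accuracy metrics
#'
#' Overlap and boundary-distance agreement between two binary masks:
#' `diceCoefficient()` returns \eqn{2|A \cap B| / (|A| + |B|)},
#' `iouScore()` returns \eqn{|A \cap B| / |A \cup B|} (both 1 by
#' convention when both masks are empty), and `hausdorff95()` the 95th
#' percentile of the pooled directed boundary-to-boundary Euclidean
#' distances, a robust variant of the Hausdorff distance.  Boundaries are
#' the mask pixels with at least one 4-neighbour outside the mask (image
#' border counts as outside).  Distances are in pixel units.
#'
#' All three metrics are symmetric in their arguments, and for any
#' non-empty overlap `dice >= iou` (algebraically
#' `iou = dice / (2 - dice)`).
#'
#' @param a,b binary masks (logical or 0/1 matrices) of identical size.
#' @return a scalar.
#' @examples
#' a <- matrix(0, 8, 8); a[3:6, 3:6] <- 1
#' diceCoefficient(a, a)   # 1
#' hausdorff95(a, a)       # 0
#' @name metrics
NULL

.asMask <- function(m) {
  if (is.logical(m)) return(m)
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  m > 0
}

#' @rdname metrics
#' @export
diceCoefficient <- function(a, b) {
  .checkSameDim(a, b)
  a <- .asMask(a); b <- .asMask(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' @rdname metrics
#' @export
iouScore <- function(a, b) {
  .checkSameDim(a, b)
  a <- .asMask(a); b <- .asMask(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# 4-connectivity boundary: mask pixels with an off-mask (or off-image)
# neighbour
.maskBoundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(FALSE, m[-nr, , drop = FALSE])
  down <- rbind(m[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, m[, -nc, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & down & left & right)
}

#' @rdname metrics
#' @export
hausdorff95 <- function(a, b) {
  .checkSameDim(a, b)
  a <- .asMask(a); b <- .asMask(b)
  if (!any(a) || !any(b))
    stop("hausdorff95 is undefined for an empty mask")
  ba <- .maskBoundary(a)
  bb <- .maskBoundary(b)
  # distance of every pixel to the nearest boundary pixel of the other mask
  dToB <- as.matrix(EBImage::distmap(matrix(as.numeric(!bb), nrow(bb))))
  dToA <- as.matrix(EBImage::distmap(matrix(as.numeric(!ba), nrow(ba))))
  pooled <- c(dToB[ba], dToA[bb])
  as.numeric(stats::quantile(pooled, 0.95, names = FALSE))
}

#' Evaluate a set of segmentations
#'
#' Per-image Dice, IoU and 95HD for paired predicted/reference masks, plus
#' a mean and standard-deviation summary row per metric.
#'
#' @param pred,truth lists of binary masks of equal length.
#' @return list with `perImage` (data.frame: `image`, `dice`, `iou`,
#'   `hd95`) and `summary` (data.frame: `metric`, `mean`, `sd`).
#' @export
evaluateSegmentation <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  per <- data.frame(
    image = if (!is.null(names(pred))) names(pred) else seq_along(pred),
    dice = mapply(diceCoefficient, pred, truth),
    iou = mapply(iouScore, pred, truth),
    hd95 = mapply(hausdorff95, pred, truth),
    row.names = NULL)
  summ <- data.frame(
    metric = c("dice", "iou", "hd95"),
    mean = c(mean(per$dice), mean(per$iou), mean(per$hd95)),
    sd = c(stats::sd(per$dice), stats::sd(per$iou), stats::sd(per$hd95)))
  list(perImage = per, summary = summ)
}
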