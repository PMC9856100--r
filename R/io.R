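#' Read a grayscale image
#'
#' Reads PNG or TIFF into an intensity matrix on the conventional 0--255
#' scale (both readers return values in `[0, 1]`, which are rescaled by
#' 255).  RGB input is converted to a single luminance channel
#' (0.299 R + 0.587 G + 0.114 B) with a warning.  An alpha channel, if
#' present, is dropped.
#'
#' @param path file path; format inferred from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @return numeric intensity matrix (rows = image rows).
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (supported: PNG, TIFF)"))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      warning("RGB input converted to luminance")
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  arr * 255
}

#' Write / read a binary mask as PNG
#'
#' Masks round-trip losslessly as 8-bit PNG with values 0/255.
#' `readMask()` refuses files containing grey levels other than 0/255
#' unless an explicit binarization `threshold` (on the 0--255 scale) is
#' given.
#'
#' @param mask logical or 0/1 matrix.
#' @param path file path.
#' @param threshold optional binarization threshold for non-binary input.
#' @return `writeMask()` the path invisibly; `readMask()` a logical matrix.
#' @export
writeMask <- function(mask, path) {
  mask <- .asMask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, threshold = NULL) {
  v <- readImage(path)
  if (is.null(threshold)) {
    if (!all(v %in% c(0, 255)))
      stop("mask file is not binary; pass an explicit threshold")
    v > 0
  } else {
    v > threshold
  }
}

#' Write the per-iteration energy trace as CSV
#'
#' @param result a [SegmentationResult-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeEnergyTrace <- function(result, path) {
  utils::write.csv(energyTrace(result), path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a segmentation configuration
#'
#' Flat YAML key/value round-trip of every [SegmentationConfig-class]
#' field.
#'
#' @param cfg a [SegmentationConfig-class].
#' @param path YAML file path.
#' @return `writeSegmentationConfig()` the path invisibly;
#'   `readSegmentationConfig()` the configuration.
#' @export
writeSegmentationConfig <- function(cfg, path) {
  stopifnot(methods::is(cfg, "SegmentationConfig"))
  yaml::write_yaml(list(
    lambda = cfg@lambda, eps = cfg@eps, gamma = cfg@gamma, beta = cfg@beta,
    maxIters = cfg@maxIters, energyTol = cfg@energyTol,
    tolWindow = cfg@tolWindow, initMode = cfg@initMode, seed = cfg@seed,
    clampPhi = cfg@clampPhi, normalizeGradients = cfg@normalizeGradients,
    normRates = as.list(cfg@normRates), gradSmooth = cfg@gradSmooth,
    regWarmup = cfg@regWarmup, reinitEvery = cfg@reinitEvery,
    innerSteps = cfg@innerSteps,
    rescaleIntensities = cfg@rescaleIntensities), path,
    precision = 17)
  invisible(path)
}

#' @rdname writeSegmentationConfig
#' @export
readSegmentationConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  v <- yaml::read_yaml(path)
  segmentationConfig(
    lambda = v$lambda, eps = v$eps, gamma = v$gamma, beta = v$beta,
    maxIters = v$maxIters, energyTol = v$energyTol,
    tolWindow = v$tolWindow, initMode = v$initMode, seed = v$seed,
    clampPhi = v$clampPhi, normalizeGradients = v$normalizeGradients,
    normRates = unlist(v$normRates), gradSmooth = v$gradSmooth,
    regWarmup = v$regWarmup, reinitEvery = v$reinitEvery,
    innerSteps = v$innerSteps,
    rescaleIntensities = v$rescaleIntensities)
}
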