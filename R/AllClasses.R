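#' @import methods
#' @importFrom stats cor dnorm lm median na.omit optim pnorm pt qnorm rbinom
#'   rnorm runif sd setNames var coef complete.cases
#' @importFrom utils combn read.delim write.table packageVersion
#' @useDynLib IVCMgrade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tools md5sum
NULL

#' CohortConfig: parameters of the synthetic dry-eye cohort generator
#'
#' Holds everything needed to simulate a cohort of per-eye records with a
#' Gaussian copula: group sizes, per-group marginal distributions for the
#' clinical variables and the latent morphometric traits, the planted latent
#' correlation structure, female fractions, and the nerve-morphology grading
#' thresholds. Build the published default with [table1Default()] and
#' calibrate the latent correlations with [calibrateCohortConfig()].
#'
#' @slot nAided integer, number of autoimmune dry-eye (AIDED) eyes.
#' @slot nNaided integer, number of non-autoimmune (NAIDED) eyes.
#' @slot marginals named list (`AIDED`, `NAIDED`); each a named list of
#'   marginal specifications (see [marginalTransform()]).
#' @slot latentTargets square numeric matrix of planted latent (Gaussian-scale)
#'   correlations over the simulated variables; `NA` entries are filled by
#'   calibration.
#' @slot latentCorrelation the calibrated, positive-definite latent
#'   correlation matrix actually used for simulation (0 x 0 until calibrated).
#' @slot femaleFraction named numeric, probability that an eye belongs to a
#'   female patient, per group.
#' @slot morphThresholds named numeric with elements `tortuosity` and
#'   `reflectivity`: cutoffs above which the nerve-morphology flags are set.
#'
#' @seealso [generateCohort()], [table1Default()]
#' @export
setClass("CohortConfig", slots = c(
  nAided = "integer",
  nNaided = "integer",
  marginals = "list",
  latentTargets = "matrix",
  latentCorrelation = "matrix",
  femaleFraction = "numeric",
  morphThresholds = "numeric"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@nAided) != 1L || object@nAided < 0L)
    msg <- c(msg, "nAided must be a single non-negative integer")
  if (length(object@nNaided) != 1L || object@nNaided < 0L)
    msg <- c(msg, "nNaided must be a single non-negative integer")
  if (!all(c("AIDED", "NAIDED") %in% names(object@marginals)))
    msg <- c(msg, "marginals must have components 'AIDED' and 'NAIDED'")
  tg <- object@latentTargets
  if (nrow(tg) != ncol(tg))
    msg <- c(msg, "latentTargets must be square")
  else {
    if (!isTRUE(all.equal(unname(diag(tg)), rep(1, nrow(tg)))))
      msg <- c(msg, "latentTargets must have unit diagonal")
    if (any(abs(tg) > 1, na.rm = TRUE))
      msg <- c(msg, "latentTargets entries must lie in [-1, 1]")
    tt <- t(tg)
    sameNa <- identical(is.na(tg), is.na(tt))
    sameVal <- isTRUE(all.equal(tg[!is.na(tg)], tt[!is.na(tt)]))
    if (!sameNa || !sameVal)
      msg <- c(msg, "latentTargets must be symmetric")
  }
  if (!all(c("AIDED", "NAIDED") %in% names(object@femaleFraction)))
    msg <- c(msg, "femaleFraction must be named for both groups")
  else if (any(object@femaleFraction < 0 | object@femaleFraction > 1))
    msg <- c(msg, "femaleFraction must lie in [0, 1]")
  if (!all(c("tortuosity", "reflectivity") %in% names(object@morphThresholds)))
    msg <- c(msg, "morphThresholds needs 'tortuosity' and 'reflectivity'")
  if (length(msg)) msg else TRUE
})

#' IVCMScore: the ordinal corneal confocal grading score
#'
#' Container for one eye's grading: the inflammatory-cell subscore (0-3,
#' codes IC-0..IC-3), the nerve-density subscore (0-1, codes ND-1/ND-2), the
#' nerve-morphology subscore (0-2, codes NM-0, NM1-R, NM1-T, NM-2) and their
#' sum, the total score (0-6).
#'
#' @slot icSub,ndSub,nmSub integer subscores.
#' @slot icCode,ndCode,nmCode character grading codes.
#' @slot total integer total score, always `icSub + ndSub + nmSub`.
#' @seealso [ivcmScore()], [icSubscore()], [ndSubscore()], [nmSubscore()]
#' @export
setClass("IVCMScore", slots = c(
  icSub = "integer", icCode = "character",
  ndSub = "integer", ndCode = "character",
  nmSub = "integer", nmCode = "character",
  total = "integer"
))

setValidity("IVCMScore", function(object) {
  msg <- character()
  if (!object@icSub %in% 0:3) msg <- c(msg, "icSub must be in 0..3")
  if (!object@ndSub %in% 0:1) msg <- c(msg, "ndSub must be in 0..1")
  if (!object@nmSub %in% 0:2) msg <- c(msg, "nmSub must be in 0..2")
  if (object@total != object@icSub + object@ndSub + object@nmSub)
    msg <- c(msg, "total must equal the sum of the subscores")
  if (!identical(object@icCode, paste0("IC-", object@icSub)))
    msg <- c(msg, "icCode inconsistent with icSub")
  nd <- c("ND-1", "ND-2")[object@ndSub + 1L]
  if (!identical(object@ndCode, nd))
    msg <- c(msg, "ndCode inconsistent with ndSub")
  if (!object@nmCode %in% c("NM-0", "NM1-R", "NM1-T", "NM-2"))
    msg <- c(msg, "unknown nmCode")
  nmMap <- c("NM-0" = 0L, "NM1-R" = 1L, "NM1-T" = 1L, "NM-2" = 2L)
  if (nmMap[[object@nmCode]] != object@nmSub)
    msg <- c(msg, "nmCode inconsistent with nmSub")
  if (length(msg)) msg else TRUE
})

#' ImageSpec: parameters of a synthetic confocal frame
#'
#' Geometry and appearance of one rendered sub-basal-plexus frame. The frame
#' is `widthPx` x `heightPx` pixels covering `fieldUm` x `fieldUm`
#' micrometers, so the pixel size is `fieldUm / widthPx` (400/384 um by
#' default). Intensities are on the 8-bit scale (0-255).
#'
#' @slot widthPx,heightPx integer frame size in pixels.
#' @slot fieldUm numeric imaged field side length in micrometers.
#' @slot nCells,nNerves integer number of planted inflammatory cells and
#'   nerve fibers.
#' @slot tortuosityAmplitude numeric >= 0, perpendicular displacement scale
#'   (pixels) of the planted nerve paths; 0 gives straight nerves.
#' @slot nerveContrast,cellContrast numeric >= 0, peak intensity of nerves
#'   and cells above background.
#' @slot backgroundLevel numeric background intensity.
#' @slot noiseSd numeric standard deviation of additive Gaussian noise.
#' @slot blurSigmaPx numeric >= 0, Gaussian blur applied after rendering.
#' @slot seed integer RNG seed making the frame reproducible.
#' @seealso [imageSpec()], [renderFrame()]
#' @export
setClass("ImageSpec", slots = c(
  widthPx = "integer", heightPx = "integer", fieldUm = "numeric",
  nCells = "integer", nNerves = "integer",
  tortuosityAmplitude = "numeric",
  nerveContrast = "numeric", cellContrast = "numeric",
  backgroundLevel = "numeric", noiseSd = "numeric",
  blurSigmaPx = "numeric", seed = "integer"
))

setValidity("ImageSpec", function(object) {
  msg <- character()
  if (object@widthPx < 1L || object@heightPx < 1L)
    msg <- c(msg, "frame must be at least 1x1 px")
  if (object@fieldUm <= 0) msg <- c(msg, "fieldUm must be positive")
  if (object@nCells < 0L || object@nNerves < 0L)
    msg <- c(msg, "object counts must be non-negative")
  if (object@tortuosityAmplitude < 0)
    msg <- c(msg, "tortuosityAmplitude must be >= 0")
  if (object@nerveContrast < 0 || object@cellContrast < 0)
    msg <- c(msg, "contrasts must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@blurSigmaPx < 0) msg <- c(msg, "blurSigmaPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GroundTruthAnnotation: exact annotation of a synthetic frame
#'
#' Pixel coordinates of every planted object in a rendered frame. The
#' coordinate convention is 0-based, x rightward and y downward, with the
#' origin at the top-left pixel center; it matches the rendering and all
#' morphometry code.
#'
#' @slot cells numeric matrix with columns `x`, `y`: planted cell centers.
#' @slot nerves list of numeric matrices (columns `x`, `y`), one ordered
#'   polyline per planted nerve, each with at least two vertices.
#' @slot nerveTortuosity numeric, true arc/chord tortuosity per nerve.
#' @slot nerveLengthUm numeric, true polyline arc length per nerve (um).
#' @seealso [renderFrame()], [nerveMetrics()]
#' @export
setClass("GroundTruthAnnotation", slots = c(
  cells = "matrix", nerves = "list",
  nerveTortuosity = "numeric", nerveLengthUm = "numeric"
))

setValidity("GroundTruthAnnotation", function(object) {
  msg <- character()
  if (ncol(object@cells) != 2L) msg <- c(msg, "cells must have 2 columns")
  bad <- vapply(object@nerves, function(p) !is.matrix(p) || nrow(p) < 2L ||
                  ncol(p) != 2L, logical(1))
  if (any(bad)) msg <- c(msg, "each nerve polyline needs >= 2 (x, y) vertices")
  if (length(object@nerveTortuosity) != length(object@nerves) ||
      length(object@nerveLengthUm) != length(object@nerves))
    msg <- c(msg, "per-nerve truth vectors must match the number of nerves")
  if (length(msg)) msg else TRUE
})

#' BeadCalibration: log-log bead regression for MFI-to-AUF conversion
#'
#' Least-squares fit of `log10(abc)` on `log10(mfi)` over the calibration
#' bead populations; used to convert sample mean fluorescence intensities to
#' arbitrary units of fluorescence.
#'
#' @slot slope,intercept numeric regression coefficients on the log10 scale.
#' @slot rSquared numeric coefficient of determination in `[0, 1]`.
#' @slot nBeads integer number of bead populations used.
#' @seealso [fitBeadCalibration()], [mfiToAuf()]
#' @export
setClass("BeadCalibration", slots = c(
  slope = "numeric", intercept = "numeric",
  rSquared = "numeric", nBeads = "integer"
))

setValidity("BeadCalibration", function(object) {
  msg <- character()
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    msg <- c(msg, "coefficients must be finite")
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@nBeads < 3L) msg <- c(msg, "at least 3 bead populations required")
  if (length(msg)) msg else TRUE
})

#' CorrelogramResult: Spearman correlation matrix with significance mask
#'
#' Symmetric matrices of tie-corrected Spearman correlations, their two-sided
#' p-values and the significance mask (`p < alpha`), together with the
#' pairwise-complete sample sizes used for every cell.
#'
#' @slot variables character vector of variable names (matrix dimnames).
#' @slot rho,p numeric matrices; `rho` has unit diagonal, entries in
#'   `[-1, 1]` (or `NA` for constant variables).
#' @slot mask logical matrix, `TRUE` where `p < alpha`.
#' @slot nPairs integer matrix of pairwise-complete observation counts.
#' @slot alpha numeric significance level.
#' @seealso [spearmanMatrix()], [significantEdges()]
#' @export
setClass("CorrelogramResult", slots = c(
  variables = "character", rho = "matrix", p = "matrix",
  mask = "matrix", nPairs = "matrix", alpha = "numeric"
))

setValidity("CorrelogramResult", function(object) {
  msg <- character()
  k <- length(object@variables)
  for (nm in c("rho", "p", "mask", "nPairs")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(k, k)))
      msg <- c(msg, sprintf("%s must be %d x %d", nm, k, k))
  }
  if (!isTRUE(all.equal(object@rho, t(object@rho)))) {
    if (!identical(is.na(object@rho), is.na(t(object@rho))))
      msg <- c(msg, "rho must be symmetric")
  }
  if (any(object@rho > 1 + 1e-12 | object@rho < -1 - 1e-12, na.rm = TRUE))
    msg <- c(msg, "rho entries must lie in [-1, 1]")
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
    msg <- c(msg, "p entries must lie in [0, 1]")
  if (any(object@mask & !(object@p < object@alpha), na.rm = TRUE))
    msg <- c(msg, "mask must be FALSE wherever p >= alpha")
  if (length(msg)) msg else TRUE
})

#' GroupComparison: two-group Mann-Whitney comparison
#'
#' @slot groups character, the two group labels.
#' @slot n integer, sample size per group.
#' @slot U numeric Mann-Whitney U statistic (for the first group).
#' @slot p numeric two-sided p-value.
#' @slot means,sems numeric per-group means and standard errors of the mean.
#' @slot method character, `"exact"` or `"normal approximation"`.
#' @seealso [mannWhitney()]
#' @export
setClass("GroupComparison", slots = c(
  groups = "character", n = "integer", U = "numeric", p = "numeric",
  means = "numeric", sems = "numeric", method = "character"
))

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (length(object@n) != 2L) msg <- c(msg, "n must have length 2")
  if (object@U < -1e-9 || object@U > prod(object@n) + 1e-9)
    msg <- c(msg, "U must lie in [0, n1 * n2]")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig\n")
  cat(sprintf("  eyes: %d (AIDED %d / NAIDED %d)\n",
              object@nAided + object@nNaided, object@nAided, object@nNaided))
  cat(sprintf("  variables: %s\n",
              paste(colnames(object@latentTargets), collapse = ", ")))
  cat(sprintf("  latent correlation: %s\n",
              if (nrow(object@latentCorrelation)) "calibrated"
              else "not calibrated (run calibrateCohortConfig())"))
  invisible(object)
})

setMethod("show", "IVCMScore", function(object) {
  cat(sprintf("IVCMScore: total %d (%s + %s + %s)\n", object@total,
              object@icCode, object@ndCode, object@nmCode))
  invisible(object)
})

setMethod("show", "ImageSpec", function(object) {
  cat(sprintf("ImageSpec: %dx%d px / %.0fx%.0f um, %d cells, %d nerves\n",
              object@widthPx, object@heightPx, object@fieldUm, object@fieldUm,
              object@nCells, object@nNerves))
  invisible(object)
})

setMethod("show", "BeadCalibration", function(object) {
  cat(sprintf(
    "BeadCalibration: log10(AUF) = %.4f + %.4f log10(MFI), R^2 = %.4f (%d beads)\n",
    object@intercept, object@slope, object@rSquared, object@nBeads))
  invisible(object)
})

setMethod("show", "CorrelogramResult", function(object) {
  cat(sprintf("CorrelogramResult: %d variables, alpha = %g\n",
              length(object@variables), object@alpha))
  sig <- sum(object@mask[upper.tri(object@mask)], na.rm = TRUE)
  cat(sprintf("  significant pairs: %d of %d\n", sig,
              sum(upper.tri(object@mask))))
  invisible(object)
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s): %s (n=%d) vs %s (n=%d)\n", object@method,
              object@groups[1], object@n[1], object@groups[2], object@n[2]))
  cat(sprintf("  U = %g, p = %.4g; means %.4g vs %.4g\n",
              object@U, object@p, object@means[1], object@means[2]))
  invisible(object)
})

#' Accessors for IVCMgrade result objects
#'
#' Small accessor family: subscores and total of an [IVCMScore-class];
#' matrices of a [CorrelogramResult-class].
#'
#' @param object an object of the documented class.
#' @return the requested component.
#' @name accessors
#' @aliases scoreTotal subScores rhoMatrix pMatrix sigMask pairCounts
NULL

#' @rdname accessors
#' @export
setGeneric("scoreTotal", function(object) standardGeneric("scoreTotal"))
#' @rdname accessors
#' @export
setMethod("scoreTotal", "IVCMScore", function(object) object@total)

#' @rdname accessors
#' @export
setGeneric("subScores", function(object) standardGeneric("subScores"))
#' @rdname accessors
#' @export
setMethod("subScores", "IVCMScore", function(object) {
  c(ic = object@icSub, nd = object@ndSub, nm = object@nmSub)
})

#' @rdname accessors
#' @export
setGeneric("rhoMatrix", function(object) standardGeneric("rhoMatrix"))
#' @rdname accessors
#' @export
setMethod("rhoMatrix", "CorrelogramResult", function(object) object@rho)

#' @rdname accessors
#' @export
setGeneric("pMatrix", function(object) standardGeneric("pMatrix"))
#' @rdname accessors
#' @export
setMethod("pMatrix", "CorrelogramResult", function(object) object@p)

#' @rdname accessors
#' @export
setGeneric("sigMask", function(object) standardGeneric("sigMask"))
#' @rdname accessors
#' @export
setMethod("sigMask", "CorrelogramResult", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("pairCounts", function(object) standardGeneric("pairCounts"))
#' @rdname accessors
#' @export
setMethod("pairCounts", "CorrelogramResult", function(object) object@nPairs)
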