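# Bead-based quantitative fluorescence calibration: convert HLA-DR mean
# fluorescence intensities (MFI) into arbitrary units of fluorescence (AUF)
# via an ordinary least-squares fit of log10(assigned antibody-binding
# capacity) on log10(bead MFI), the standard QIFI-style convention.

validateBeadSet <- function(beads) {
  if (!all(c("mfi", "abc") %in% names(beads)))
    stop("bead set needs 'mfi' and 'abc' columns")
  if (nrow(beads) < 3L) stop("at least 3 bead populations are required")
  if (any(!is.finite(beads$mfi)) || any(!is.finite(beads$abc)) ||
      any(beads$mfi <= 0) || any(beads$abc <= 0))
    stop("bead MFI and ABC values must be positive")
  o <- order(beads$mfi)
  if (any(diff(beads$mfi[o]) <= 0) || any(diff(beads$abc[o]) <= 0))
    stop("bead populations must be strictly increasing in MFI and ABC")
  beads[o, , drop = FALSE]
}

#' Fit the bead calibration line
#'
#' Ordinary least squares of `log10(abc)` on `log10(mfi)` over the bead
#' populations. A warning is raised when the fit is poor (R^2 < 0.98),
#' since calibration beads should be near-collinear on the log-log scale.
#' The fit is invariant to the ordering of the bead rows.
#'
#' @param beads data.frame with positive columns `mfi` (measured mean
#'   fluorescence intensity) and `abc` (assigned antibody-binding
#'   capacity); at least 3 rows, strictly increasing in both after sorting.
#' @return a [BeadCalibration-class].
#' @export
#' @examples
#' beads <- data.frame(mfi = c(100, 1000, 10000), abc = c(1e3, 1e4, 1e5))
#' fitBeadCalibration(beads)  # slope 1, intercept 1, R^2 = 1
fitBeadCalibration <- function(beads) {
  beads <- validateBeadSet(beads)
  fit <- lm(log10(abc) ~ log10(mfi), data = beads)
  y <- log10(beads$abc)
  r2 <- 1 - sum(resid(fit)^2) / sum((y - mean(y))^2)
  r2 <- min(max(r2, 0), 1)
  if (r2 < 0.98)
    warning(sprintf("bead calibration R^2 = %.4f (< 0.98); check the beads",
                    r2))
  new("BeadCalibration",
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      rSquared = r2, nBeads = nrow(beads))
}

#' Convert sample MFIs to arbitrary units of fluorescence
#'
#' Applies the bead calibration to background-subtracted sample intensities:
#' `AUF = 10^(intercept + slope * log10(mfi - background))`. Samples at or
#' below background convert to 0 and are flagged (attribute
#' `belowBackground`); a background of 0 (no isotype/negative control
#' available) uses the raw MFI.
#'
#' @param cal a [BeadCalibration-class].
#' @param sampleMfi numeric vector of sample MFIs.
#' @param backgroundMfi numeric scalar or vector of control MFIs
#'   (default 0).
#' @return numeric vector of AUF values (>= 0) with logical attribute
#'   `belowBackground`.
#' @export
#' @examples
#' cal <- fitBeadCalibration(
#'   data.frame(mfi = c(100, 1000, 10000), abc = c(1e3, 1e4, 1e5)))
#' mfiToAuf(cal, 500)  # 5000
mfiToAuf <- function(cal, sampleMfi, backgroundMfi = 0) {
  stopifnot(is(cal, "BeadCalibration"))
  if (any(backgroundMfi < 0)) stop("background MFI must be >= 0")
  net <- sampleMfi - backgroundMfi
  flagged <- net <= 0
  auf <- ifelse(flagged, 0, 10^(cal@intercept + cal@slope * log10(pmax(net,
                                                                 1e-300))))
  structure(auf, belowBackground = flagged)
}

#' Invert the calibration: AUF back to net MFI
#'
#' Algebraic inverse of [mfiToAuf()] (before background addition); useful
#' for round-trip checks and for synthesising instrument-scale MFIs from
#' target AUF values.
#'
#' @param cal a [BeadCalibration-class].
#' @param auf numeric vector of positive AUF values.
#' @return numeric vector of net MFIs.
#' @export
aufToMfi <- function(cal, auf) {
  stopifnot(is(cal, "BeadCalibration"))
  if (any(auf <= 0)) stop("AUF must be positive to invert")
  10^((log10(auf) - cal@intercept) / cal@slope)
}

#' Synthesise a calibration bead set
#'
#' Generates QIFI-like bead populations: assigned ABC values log-spaced
#' over `abcRange`, true MFIs from the inverse calibration line, and
#' optional multiplicative lognormal measurement noise on the MFIs.
#'
#' @param nBeads number of populations (default 5).
#' @param slope,intercept generating line on the log10 scale.
#' @param noiseCv multiplicative noise coefficient of variation (0 = exact).
#' @param abcRange range of assigned ABC values.
#' @param seed integer seed.
#' @return data.frame with columns `mfi`, `abc`.
#' @export
syntheticBeadSet <- function(nBeads = 5L, slope = 1, intercept = 1,
                             noiseCv = 0, abcRange = c(3e3, 8e5),
                             seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  abc <- 10^seq(log10(abcRange[1]), log10(abcRange[2]),
                length.out = nBeads)
  mfi <- 10^((log10(abc) - intercept) / slope)
  if (noiseCv > 0) {
    s <- sqrt(log(1 + noiseCv^2))
    mfi <- mfi * exp(rnorm(nBeads, -s^2 / 2, s))
  }
  data.frame(mfi = mfi, abc = abc)
}

#' Write / read bead and sample tables as TSV
#'
#' @param beads data.frame with `mfi`, `abc`.
#' @param path file path.
#' @return `writeBeadSet()` returns `path` invisibly; `readBeadSet()` the
#'   data.frame.
#' @export
writeBeadSet <- function(beads, path) {
  write.table(beads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBeadSet
#' @export
readBeadSet <- function(path) read.delim(path, stringsAsFactors = FALSE)
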