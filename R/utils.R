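# Shared geometry constants and marginal-distribution machinery.

# Imaged field: 400 x 400 um digitised to 384 x 384 px.
.FIELD_UM <- 400
.FRAME_PX <- 384L
.FIELD_AREA_MM2 <- 0.16

#' Pixel size of the confocal frame
#'
#' The frame covers a 400 x 400 um field digitised to 384 x 384 pixels, so
#' one pixel is exactly 400/384 um.
#'
#' @return pixel side length in micrometers.
#' @export
#' @examples
#' pixelSizeUm() * 384  # 400 um
pixelSizeUm <- function() .FIELD_UM / .FRAME_PX

# Derive a stage/replicate seed from a root seed; stays below 2^31.
deriveSeed <- function(seed, k) {
  ((as.numeric(seed) %% 1e6) * 1009 + 7919 * as.numeric(k)) %% 2147483647
}

# --- truncated normal -------------------------------------------------------

# CDF/quantile of N(mean, sd) truncated to [lo, hi] (closed form).
ptnorm <- function(q, mean, sd, lo, hi) {
  a <- pnorm((lo - mean) / sd); b <- pnorm((hi - mean) / sd)
  pmin(1, pmax(0, (pnorm((q - mean) / sd) - a) / (b - a)))
}

qtnorm <- function(p, mean, sd, lo, hi) {
  a <- pnorm((lo - mean) / sd); b <- pnorm((hi - mean) / sd)
  qnorm(a + p * (b - a)) * sd + mean
}

# Mean and sd of the truncated normal (closed form).
tnormMoments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  mu <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = mu, sd = sqrt(max(v, 0)))
}

# Underlying (mean, sd) such that the truncated distribution has the target
# moments. Needed because truncation biases the naive parameters (e.g. a
# tear-production mean close to the zero bound).
tnormMomentParams <- function(targetMean, targetSd, lo, hi) {
  obj <- function(th) {
    m <- tnormMoments(th[1], exp(th[2]), lo, hi)
    (m["mean"] - targetMean)^2 + (m["sd"] - targetSd)^2
  }
  fit <- optim(c(targetMean, log(targetSd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(mean = fit$par[1], sd = exp(fit$par[2]), lo = lo, hi = hi)
}

# --- rounded (integer-grid) truncated normal --------------------------------

# P(X = k) for k on lo..hi when X = round(truncated normal) on [lo-0.5, hi+0.5].
intGridProbs <- function(mean, sd, lo, hi) {
  k <- lo:hi
  upper <- pnorm((k + 0.5 - mean) / sd)
  lower <- pnorm((k - 0.5 - mean) / sd)
  p <- upper - lower
  p / sum(p)
}

intGridMomentParams <- function(targetMean, targetSd, lo, hi) {
  k <- lo:hi
  obj <- function(th) {
    p <- intGridProbs(th[1], exp(th[2]), lo, hi)
    m <- sum(k * p); v <- sum(k^2 * p) - m^2
    (m - targetMean)^2 + (sqrt(max(v, 0)) - targetSd)^2
  }
  fit <- optim(c(targetMean, log(max(targetSd, 0.2))), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(mean = fit$par[1], sd = exp(fit$par[2]), lo = lo, hi = hi)
}

# --- lognormal helpers ------------------------------------------------------

# Lognormal with the given arithmetic mean and sd (moment matched).
lognormalMomentParams <- function(targetMean, targetSd) {
  s2 <- log(1 + (targetSd / targetMean)^2)
  list(meanlog = log(targetMean) - s2 / 2, sdlog = sqrt(s2))
}

# Discretised-score moments of a lognormal cut at `breaks` (score = number of
# breaks at or below x, so breaks belong to the upper bin).
lognormalScoreMoments <- function(meanlog, sdlog, breaks) {
  cum <- pnorm((log(breaks) - meanlog) / sdlog)
  p <- diff(c(0, cum, 1))
  k <- seq_along(p) - 1
  m <- sum(k * p)
  c(mean = m, sd = sqrt(max(sum(k^2 * p) - m^2, 0)))
}

# Lognormal whose *binned score* has the target mean and sd. Used when the
# published summary reports the ordinal subscore, not the raw trait.
lognormalScoreMatch <- function(targetMean, targetSd, breaks) {
  obj <- function(th) {
    m <- lognormalScoreMoments(th[1], exp(th[2]), breaks)
    (m["mean"] - targetMean)^2 + (m["sd"] - targetSd)^2
  }
  fit <- optim(c(log(breaks[2]), log(0.7)), obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-12))
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

# --- marginal specifications ------------------------------------------------

#' Transform a copula uniform into a marginal draw
#'
#' Applies the inverse-CDF transform of a marginal specification to
#' probabilities in (0, 1). Supported families: `"truncnorm"` (continuous
#' truncated normal; `mean`, `sd`, `lo`, `hi`), `"intgrid"` (rounded
#' truncated normal on an integer grid; same fields), `"lognormal"`
#' (`meanlog`, `sdlog`), and `"shifted_lognormal"` (`offset`, `meanlog`,
#' `sdlog`). All transforms are monotone, so Gaussian-copula Spearman
#' structure is preserved for continuous families and attenuated only by
#' discretisation.
#'
#' @param u numeric vector of probabilities in (0, 1).
#' @param spec a list with a `family` field and the family's parameters.
#' @return numeric vector of draws from the marginal.
#' @export
#' @examples
#' marginalTransform(c(0.5), list(family = "lognormal", meanlog = 0, sdlog = 1))
marginalTransform <- function(u, spec) {
  switch(spec$family,
    truncnorm = qtnorm(u, spec$mean, spec$sd, spec$lo, spec$hi),
    intgrid = {
      p <- intGridProbs(spec$mean, spec$sd, spec$lo, spec$hi)
      spec$lo + findInterval(u, cumsum(p)[-length(p)] ,
                             rightmost.closed = FALSE)
    },
    lognormal = exp(qnorm(u) * spec$sdlog + spec$meanlog),
    shifted_lognormal = spec$offset +
      exp(qnorm(u) * spec$sdlog + spec$meanlog),
    stop("unknown marginal family: ", spec$family)
  )
}

# --- content hashes for manifests (md5) -------------------------------------

hashFile <- function(path) unname(tools::md5sum(path))

hashString <- function(s) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(s, tmp, eos = NULL)
  unname(tools::md5sum(tmp))
}

hashObject <- function(x) hashString(paste(deparse(x), collapse = "\n"))
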