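# Shared oracles and fixtures, independent of the implementation paths they
# check.

# Literal reading of the published grading table: explicit range checks,
# no arithmetic shared with the package's binning.
oracleIcSubscore <- function(d) {
  if (d < 10) 0L
  else if (d < 50) 1L
  else if (d < 100) 2L
  else 3L
}

oracleNdSubscore <- function(nfd) if (nfd > 15) 0L else 1L

oracleNmSubscore <- function(refl, tort) {
  if (!refl && !tort) 0L else if (refl && tort) 2L else 1L
}

# Recursive permutation generator for small n.
permList <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permList(v[-i])
    for (r in rest) out[[length(out) + 1L]] <- c(v[i], r)
  }
  out
}

# Brute-force exact two-sided permutation p-value for Spearman correlation
# on rank vectors (handles ties via the supplied midranks).
oracleSpearmanExactP <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- permList(seq_along(ry))
  hits <- vapply(perms, function(p) abs(cor(rx, ry[p])) >= obs - 1e-9,
                 logical(1))
  mean(hits)
}

# Brute-force exact two-sided Mann-Whitney p by enumerating group
# assignments.
oracleMannWhitneyExactP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combos <- combn(n1 + n2, n1)
  Us <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
}

# Semicircular polyline of given radius, discretised.
semicirclePolyline <- function(radius = 100, n = 200, cx = 150, cy = 150) {
  th <- seq(0, pi, length.out = n)
  cbind(x = cx + radius * cos(th), y = cy + radius * sin(th))
}

# Calibrated default configuration, computed once per test run.
.calEnv <- new.env(parent = emptyenv())
calibratedDefaultConfig <- function() {
  if (is.null(.calEnv$cfg))
    .calEnv$cfg <- calibrateCohortConfig(table1Default(), seed = 1)
  .calEnv$cfg
}
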