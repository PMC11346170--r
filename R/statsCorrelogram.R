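# Nonparametric statistical layer: tie-corrected Spearman correlograms with
# significance masking, exact/approximate Mann-Whitney comparisons, and the
# severity stratifications of the cohort.

# Spearman rho (average ranks, i.e. Pearson on midranks) with two-sided p.
# Exact permutation enumeration for small samples, t approximation above.
spearmanTest <- function(x, y, exactMaxN = 10L) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  p <- if (n <= exactMaxN) {
    exactSpearmanPermP(rx, ry)
  } else {
    if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), n - 2)
    }
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Spearman correlation matrix with significance mask
#'
#' Tie-corrected (average-rank) Spearman correlations for every variable
#' pair of a cohort table, with two-sided p-values (exact permutation
#' enumeration for pairwise n <= 10, t approximation otherwise),
#' pairwise-complete deletion of missing values, per-cell sample sizes, and
#' a significance mask `p < alpha`. Constant variables yield `NA`
#' correlations (undefined, not zero) and are never flagged significant.
#' Raw p-values are masked by default; `adjust = "BH"` applies a
#' Benjamini-Hochberg correction across the upper triangle before masking.
#'
#' @param data data.frame holding the variables.
#' @param variables character vector of column names (default: all numeric
#'   columns, in the order given).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a [CorrelogramResult-class].
#' @export
#' @examples
#' d <- data.frame(a = 1:6, b = c(2, 1, 4, 3, 6, 5), c = rnorm(6))
#' spearmanMatrix(d)
spearmanMatrix <- function(data, variables = NULL, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  missingVars <- setdiff(variables, names(data))
  if (length(missingVars))
    stop("variables not in data: ", paste(missingVars, collapse = ", "))
  k <- length(variables)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  np <- matrix(0L, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    np[i, i] <- sum(!is.na(data[[variables[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      st <- spearmanTest(data[[variables[i]]], data[[variables[j]]])
      rho[i, j] <- rho[j, i] <- st$rho
      p[i, j] <- p[j, i] <- st$p
      np[i, j] <- np[j, i] <- st$n
    }
  }
  if (adjust == "BH" && k > 1) {
    up <- upper.tri(p)
    adj <- stats::p.adjust(p[up], method = "BH")
    p[up] <- adj
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  mask <- !is.na(p) & p < alpha
  diag(mask) <- FALSE
  new("CorrelogramResult", variables = variables, rho = rho, p = p,
      mask = mask, nPairs = np, alpha = alpha)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-sided Mann-Whitney test with midrank ties. The p-value is computed
#' by exact enumeration of all group assignments when `n1 + n2 <= 12` and
#' there are no ties, and otherwise by the normal approximation with tie
#' and continuity corrections.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param labels character length 2, group labels for reporting.
#' @return a [GroupComparison-class]; `U` is the statistic for the first
#'   group.
#' @export
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mannWhitney <- function(a, b, labels = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- any(duplicated(c(a, b)))
  if (n1 + n2 <= 12 && !ties) {
    combos <- combn(n1 + n2, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    p <- mannWhitneyApproxP(a, b)
    method <- "normal approximation"
  }
  new("GroupComparison", groups = labels, n = c(n1, n2), U = U, p = p,
      means = c(mean(a), mean(b)),
      sems = c(sd(a) / sqrt(n1), sd(b) / sqrt(n2)),
      method = method)
}

# Normal approximation with midrank tie correction and continuity
# correction (two-sided); the large-sample branch of mannWhitney().
mannWhitneyApproxP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  tj <- table(c(a, b))
  tieAdj <- sum(tj^3 - tj) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieAdj)
  if (sigma2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Stratify a scored cohort by the inflammatory-cell subscore
#'
#' Splits the eyes into a low inflammatory group (ICsc 0-2) and a high
#' group (ICsc 3, the top grade). Together the two groups partition the
#' cohort.
#'
#' @param records data.frame with an `ic_sub` column.
#' @return list with data.frames `low` and `high`.
#' @export
stratifyIcsc <- function(records) {
  if (is.null(records$ic_sub) || anyNA(records$ic_sub))
    stop("records must carry a complete 'ic_sub' column (score the cohort first)")
  list(low = records[records$ic_sub <= 2L, , drop = FALSE],
       high = records[records$ic_sub == 3L, , drop = FALSE])
}

#' Compare HLA-DR between inflammatory-cell strata
#'
#' Convenience wrapper: stratifies with [stratifyIcsc()] and compares a
#' value column (HLA-DR by default) between the strata with
#' [mannWhitney()]. When a stratum is empty the comparison is reported as
#' not computable (`NULL` with a message).
#'
#' @param records scored cohort data.frame.
#' @param value column to compare (default `"hla_dr_auf"`).
#' @return a [GroupComparison-class], or `NULL` when a stratum is empty.
#' @export
compareHlaByIcsc <- function(records, value = "hla_dr_auf") {
  s <- stratifyIcsc(records)
  if (!nrow(s$low) || !nrow(s$high)) {
    message("ICsc stratification not computable: an empty stratum")
    return(NULL)
  }
  mannWhitney(s$high[[value]], s$low[[value]],
              labels = c("high ICsc", "low ICsc"))
}

#' Stratify by extreme total scores
#'
#' Keeps only the extremes of the total score distribution: group 1 with
#' totals `<= lowMax` (default 2) and group 2 with totals `>= highMin`
#' (default 5); intermediate eyes are set aside.
#'
#' @param records data.frame with a `tivcm` column.
#' @param lowMax,highMin integer cutoffs, `lowMax < highMin`.
#' @return list with data.frames `group1`, `group2`, `excluded`.
#' @export
stratifyExtremeTivcm <- function(records, lowMax = 2L, highMin = 5L) {
  if (lowMax >= highMin) stop("lowMax must be below highMin")
  if (is.null(records$tivcm) || anyNA(records$tivcm))
    stop("records must carry a complete 'tivcm' column")
  list(group1 = records[records$tivcm <= lowMax, , drop = FALSE],
       group2 = records[records$tivcm >= highMin, , drop = FALSE],
       excluded = records[records$tivcm > lowMax &
                            records$tivcm < highMin, , drop = FALSE])
}

#' Within-group correlogram with significant-edge summary
#'
#' Runs [spearmanMatrix()] on a subgroup and reports the significant edges
#' (variable pairs with `p < alpha`) with the sign and size of each
#' correlation, the form used to summarise subgroup structure graphically.
#'
#' @param records subgroup data.frame (>= 3 rows).
#' @param variables character vector of columns to correlate.
#' @param alpha significance level.
#' @return list with `correlogram` (a [CorrelogramResult-class]) and
#'   `edges` (data.frame `var1`, `var2`, `rho`, `p`, `sign`).
#' @export
withinGroupCorrelations <- function(records, variables, alpha = 0.05) {
  if (nrow(records) < 3) stop("group too small for correlation (need >= 3)")
  cr <- spearmanMatrix(records, variables, alpha)
  list(correlogram = cr, edges = significantEdges(cr))
}

#' Significant edges of a correlogram
#'
#' @param cr a [CorrelogramResult-class].
#' @return data.frame with one row per significant (masked) pair: `var1`,
#'   `var2`, `rho`, `p`, `sign` (`"+"`/`"-"`).
#' @export
significantEdges <- function(cr) {
  stopifnot(is(cr, "CorrelogramResult"))
  idx <- which(upper.tri(cr@mask) & cr@mask, arr.ind = TRUE)
  data.frame(var1 = cr@variables[idx[, 1]],
             var2 = cr@variables[idx[, 2]],
             rho = cr@rho[idx],
             p = cr@p[idx],
             sign = ifelse(cr@rho[idx] >= 0, "+", "-"))
}

#' Write correlogram matrices as TSV
#'
#' Writes `rho.tsv`, `p.tsv`, `mask.tsv`, `n_pairs.tsv` and `edges.tsv`
#' into a directory.
#'
#' @param cr a [CorrelogramResult-class].
#' @param dir output directory (created if absent).
#' @return invisible character vector of the written paths.
#' @export
writeCorrelogram <- function(cr, dir) {
  stopifnot(is(cr, "CorrelogramResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(m, f) {
    path <- file.path(dir, f)
    write.table(data.frame(variable = rownames(m), m, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(w(cr@rho, "rho.tsv"), w(cr@p, "p.tsv"),
             w(cr@mask, "mask.tsv"), w(cr@nPairs, "n_pairs.tsv"))
  edgePath <- file.path(dir, "edges.tsv")
  write.table(significantEdges(cr), edgePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, edgePath))
}

#' Correlogram plot
#'
#' Upper-triangle heat map of the significant Spearman correlations: red
#' for positive, blue for negative, blank where not significant. Requires
#' ggplot2.
#'
#' @param cr a [CorrelogramResult-class].
#' @return a ggplot object.
#' @export
plotCorrelogram <- function(cr) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotCorrelogram requires the ggplot2 package")
  stopifnot(is(cr, "CorrelogramResult"))
  idx <- which(upper.tri(cr@rho), arr.ind = TRUE)
  d <- data.frame(
    var1 = factor(cr@variables[idx[, 1]], levels = cr@variables),
    var2 = factor(cr@variables[idx[, 2]], levels = rev(cr@variables)),
    rho = ifelse(cr@mask[idx], cr@rho[idx], NA_real_))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$rho)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1),
                                  na.value = "white",
                                  name = "Spearman r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
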