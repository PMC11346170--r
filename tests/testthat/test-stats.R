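test_that("Spearman matrix equals rank-then-Pearson on every tested input", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    d <- data.frame(a = sample(1:8, n, TRUE), b = rnorm(n),
                    c = rpois(n, 4))
    cr <- spearmanMatrix(d)
    for (p in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      oracle <- cor(rank(d[[p[1]]]), rank(d[[p[2]]]))
      expect_equal(rhoMatrix(cr)[p[1], p[2]], oracle, tolerance = 1e-12)
    }
    expect_equal(rhoMatrix(cr), t(rhoMatrix(cr)))
    expect_equal(unname(diag(rhoMatrix(cr))), rep(1, 3))
  }
})

test_that("perfect monotone pairs give rho of +/- 1", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(10, 20, 30, 40),
                  z = c(8, 6, 4, 2))
  cr <- spearmanMatrix(d)
  expect_equal(rhoMatrix(cr)["x", "y"], 1)
  expect_equal(rhoMatrix(cr)["x", "z"], -1)
})

test_that("exact Spearman p-values match full permutation enumeration", {
  set.seed(11)
  for (i in 1:6) {
    x <- sample(1:4, 6, TRUE)  # ties on purpose
    y <- rnorm(6)
    if (sd(x) == 0) next
    d <- data.frame(x = x, y = y)
    cr <- spearmanMatrix(d)
    expect_equal(pMatrix(cr)["x", "y"], oracleSpearmanExactP(x, y),
                 tolerance = 1e-12)
  }
  # n = 7 with distinct values too
  x <- c(3, 1, 4, 1.5, 5, 9, 2); y <- c(2, 7, 1, 8, 2.8, 1.8, 5)
  cr <- spearmanMatrix(data.frame(x = x, y = y))
  expect_equal(pMatrix(cr)["x", "y"], oracleSpearmanExactP(x, y),
               tolerance = 1e-12)
})

test_that("constant variables yield missing correlations, never significant", {
  d <- data.frame(x = rep(2, 10), y = rnorm(10))
  cr <- spearmanMatrix(d)
  expect_true(is.na(rhoMatrix(cr)["x", "y"]))
  expect_true(is.na(pMatrix(cr)["x", "y"]))
  expect_false(sigMask(cr)["x", "y"])
})

test_that("pairwise-complete deletion is used and audited", {
  d <- data.frame(x = c(1:9, NA), y = c(NA, 2:10), z = 1:10)
  cr <- spearmanMatrix(d)
  expect_equal(pairCounts(cr)["x", "y"], 8L)
  expect_equal(pairCounts(cr)["x", "z"], 9L)
  expect_equal(rhoMatrix(cr)["x", "z"], 1)
})

test_that("Benjamini-Hochberg masking is available but off by default", {
  set.seed(9)
  d <- as.data.frame(matrix(rnorm(60 * 6), 60))
  d$V7 <- d$V1 + rnorm(60, 0, 0.2)  # one real signal
  raw <- spearmanMatrix(d)
  bh <- spearmanMatrix(d, adjust = "BH")
  expect_true(bh@p["V1", "V7"] >= raw@p["V1", "V7"])
  expect_lte(sum(sigMask(bh)), sum(sigMask(raw)))
  expect_true(sigMask(bh)["V1", "V7"])
})

test_that("Mann-Whitney U and exact p match enumeration", {
  gc <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc@U, 0)
  expect_equal(gc@p, 0.1)  # 2 / choose(6, 3)
  expect_equal(gc@method, "exact")
  # identical samples: U = n1 n2 / 2 by symmetry (ties force approximation)
  gcSame <- mannWhitney(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(gcSame@U, 8)
  expect_equal(gcSame@p, 1)
  # random small cases vs the enumeration oracle
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
    got <- mannWhitney(a, b)
    expect_equal(got@p, oracleMannWhitneyExactP(a, b), tolerance = 1e-12)
    expect_true(got@U >= 0 && got@U <= length(a) * length(b))
  }
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("the normal approximation tracks exact enumeration at n1=n2=6", {
  # decision-relevant region: every achievable U whose exact two-sided p is
  # below ~0.1 (the approximation is coarser mid-range, where no
  # significance decision changes)
  for (k in 0:6) {
    a <- c(1:5, 6 + k); b <- setdiff(1:12, a)  # constructs U = k
    exact <- oracleMannWhitneyExactP(a, b)
    approx <- IVCMgrade:::mannWhitneyApproxP(a, b)
    # enumerated maximum tail deviation is 0.0051 (at U = 3)
    expect_lt(abs(approx - exact), 0.0055)
    # and the mirrored extreme
    expect_lt(abs(IVCMgrade:::mannWhitneyApproxP(b, a) - exact), 0.0055)
  }
})

test_that("inflammatory-cell stratification partitions the cohort", {
  rec <- data.frame(ic_sub = c(0L, 1L, 2L, 3L, 3L),
                    hla_dr_auf = c(1, 2, 3, 10, 12))
  s <- stratifyIcsc(rec)
  expect_equal(nrow(s$low), 3L)
  expect_equal(nrow(s$high), 2L)
  expect_equal(nrow(s$low) + nrow(s$high), nrow(rec))
  # empty stratum: comparison reported as not computable
  allLow <- data.frame(ic_sub = rep(0L, 5), hla_dr_auf = rnorm(5))
  expect_message(out <- compareHlaByIcsc(allLow), "not computable")
  expect_null(out)
  expect_error(stratifyIcsc(data.frame(x = 1)), "ic_sub")
})

test_that("high-inflammation eyes carry higher HLA-DR in synthetic cohorts", {
  # the planted ICsc/HLA-DR association separates the strata: the high
  # stratum (~26 of 214 eyes) has the larger mean essentially always, and
  # the rank test detects it in most replicates (power ~0.88 at the
  # planted Spearman 0.3)
  cfg <- calibratedDefaultConfig()
  res <- vapply(1:40, function(i) {
    co <- generateCohort(cfg, seed = 700 + i)
    cmp <- compareHlaByIcsc(co)
    c(ordered = !is.null(cmp) && cmp@means[1] > cmp@means[2],
      sig = !is.null(cmp) && cmp@p < 0.05)
  }, logical(2))
  expect_gte(mean(res["ordered", ]), 0.95)
  expect_gte(mean(res["sig", ]), 0.75)
})

test_that("extreme total-score stratification keeps only the tails", {
  rec <- data.frame(tivcm = 0:6)
  s <- stratifyExtremeTivcm(rec)
  expect_equal(s$group1$tivcm, 0:2)
  expect_equal(s$group2$tivcm, 5:6)
  expect_equal(s$excluded$tivcm, 3:4)
  expect_equal(nrow(s$group1) + nrow(s$group2) + nrow(s$excluded),
               nrow(rec))
  empty <- stratifyExtremeTivcm(rec[0, , drop = FALSE])
  expect_equal(nrow(empty$group1), 0L)
  expect_equal(nrow(empty$group2), 0L)
  expect_error(stratifyExtremeTivcm(rec, lowMax = 5, highMin = 5),
               "below")
})

test_that("within-group correlations recover planted structure", {
  cfg <- calibratedDefaultConfig()
  co <- generateCohort(cfg, seed = 901)
  s <- stratifyExtremeTivcm(co)
  wg <- withinGroupCorrelations(s$group2,
                                c("schirmer_mm", "tbut_s", "oxford"))
  # planted tear-film correlation (Spearman target 0.4) shows up positive
  edge <- wg$edges[wg$edges$var1 == "schirmer_mm" &
                     wg$edges$var2 == "tbut_s", ]
  expect_equal(nrow(edge), 1L)
  expect_equal(edge$sign, "+")
  # the edge list is exactly the masked upper triangle
  cr <- wg$correlogram
  expect_equal(nrow(wg$edges), sum(sigMask(cr)[upper.tri(sigMask(cr))]))
  expect_error(withinGroupCorrelations(co[1:2, ], c("tbut_s", "oxford")),
               "too small")
  # identical records: no significant edges
  same <- data.frame(a = rep(1, 6), b = rep(2, 6))
  wg0 <- withinGroupCorrelations(same, c("a", "b"))
  expect_equal(nrow(wg0$edges), 0L)
})

test_that("correlogram serialisation writes auditable matrices", {
  co <- generateCohort(calibratedDefaultConfig(), seed = 77)[1:60, ]
  cr <- spearmanMatrix(co, c("age", "tbut_s", "tivcm", "hla_dr_auf"))
  dir <- tempfile()
  paths <- writeCorrelogram(cr, dir)
  expect_true(all(file.exists(file.path(dir, c("rho.tsv", "p.tsv",
                                               "mask.tsv", "n_pairs.tsv",
                                               "edges.tsv")))))
  rho <- read.delim(file.path(dir, "rho.tsv"))
  expect_equal(rho$variable, cr@variables)
  expect_equal(as.numeric(rho[1, -1]), unname(rhoMatrix(cr)[1, ]),
               tolerance = 1e-12)
})
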