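test_that("subscore binning matches a literal reading of the grading table", {
  # exhaustive scan of the density grids against the range-check oracle
  densities <- seq(0, 200, by = 0.5)
  got <- icSubscore(densities)
  expect_identical(got$sub, vapply(densities, oracleIcSubscore, integer(1)))
  expect_identical(got$code, paste0("IC-", got$sub))

  nfds <- seq(0, 40, by = 0.25)
  gotNd <- ndSubscore(nfds)
  expect_identical(gotNd$sub, vapply(nfds, oracleNdSubscore, integer(1)))

  for (r in c(FALSE, TRUE)) for (t in c(FALSE, TRUE)) {
    expect_identical(nmSubscore(r, t)$sub, oracleNmSubscore(r, t))
  }
  # printed anchor cases
  expect_equal(icSubscore(75)$sub, 2L)
  expect_equal(icSubscore(75)$code, "IC-2")
  expect_equal(ndSubscore(20)$sub, 0L)
  expect_equal(ndSubscore(15)$sub, 1L)   # boundary is inclusive: decreased
  expect_equal(nmSubscore(FALSE, TRUE)$code, "NM1-T")
  expect_equal(nmSubscore(TRUE, FALSE)$code, "NM1-R")
  # boundary convention: printed gaps closed by half-open bins
  expect_equal(icSubscore(10)$sub, 1L)
  expect_equal(icSubscore(c(49.5, 99.5))$sub, c(1L, 2L))
  expect_equal(icSubscore(100)$sub, 3L)
})

test_that("total score is the sum, bounded by 0 and 6", {
  expect_equal(totalScore(0, 0, 0), 0L)
  expect_equal(totalScore(3, 1, 2), 6L)
  expect_equal(totalScore(2, 1, 2), 5L)
  expect_error(totalScore(4, 0, 0), "out of range")
  expect_error(totalScore(0, 2, 0), "out of range")
  # monotone in each subscore
  for (ic in 0:3) for (nd in 0:1) for (nm in 0:2) {
    t0 <- totalScore(ic, nd, nm)
    if (ic < 3) expect_gte(totalScore(ic + 1, nd, nm), t0)
    if (nd < 1) expect_gte(totalScore(ic, nd + 1, nm), t0)
    if (nm < 2) expect_gte(totalScore(ic, nd, nm + 1), t0)
  }
})

test_that("subscores are monotone in their inputs", {
  d <- sort(runif(200, 0, 200))
  expect_true(all(diff(icSubscore(d)$sub) >= 0))
  nfd <- sort(runif(200, 0, 40))
  expect_true(all(diff(ndSubscore(nfd)$sub) <= 0))
  expect_error(icSubscore(-1), "non-negative")
  expect_error(ndSubscore(-0.1), "non-negative")
})

test_that("morphology flags come from configurable thresholds", {
  s <- list(mean_tortuosity = 1.0, mean_reflectivity = 1.0)
  fl <- flagMorphology(s)
  expect_false(fl$reflectivityAbnormal)
  expect_false(fl$tortuosityAbnormal)
  s2 <- list(mean_tortuosity = 1.5, mean_reflectivity = 1.0)
  expect_true(flagMorphology(s2)$tortuosityAbnormal)
  # custom thresholds move the cut
  expect_false(flagMorphology(s2, c(tortuosity = 2, reflectivity = 2.5))$
                 tortuosityAbnormal)
  expect_error(flagMorphology(list(mean_tortuosity = 1)),
               "mean_reflectivity")
})

test_that("flag rate is monotone in the planted tortuosity amplitude", {
  # synthetic eyes: tortuosity index grows with amplitude, so the abnormal
  # flag rate at a fixed threshold must grow too
  set.seed(42)
  rate <- vapply(c(0.1, 0.3, 0.6), function(a) {
    tort <- 1 + exp(rnorm(300, log(a), 0.4))
    mean(vapply(seq_along(tort), function(i)
      flagMorphology(list(mean_tortuosity = tort[i],
                          mean_reflectivity = 1))$tortuosityAbnormal,
      logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate) > 0))
})

test_that("ivcmScore builds a consistent, valid score object", {
  sc <- ivcmScore(list(mean_ic_density = 75, mean_nfd = 12,
                       mean_tortuosity = 1.1, mean_reflectivity = 3.2))
  expect_s4_class(sc, "IVCMScore")
  expect_true(validObject(sc))
  expect_equal(scoreTotal(sc), 2L + 1L + 1L)
  expect_equal(unname(subScores(sc)), c(2L, 1L, 1L))
  expect_equal(sc@nmCode, "NM1-R")
  # code/subscore bijection over a scan of inputs
  set.seed(7)
  for (i in 1:50) {
    sc <- ivcmScore(list(mean_ic_density = runif(1, 0, 150),
                         mean_nfd = runif(1, 0, 40),
                         mean_tortuosity = runif(1, 1, 2),
                         mean_reflectivity = runif(1, 0.5, 5)))
    expect_true(validObject(sc))
  }
})

test_that("worst-eye selection follows Oxford, then pain, then randomises", {
  expect_equal(selectWorstEye(list(oxford = 3), list(oxford = 1)), "right")
  expect_equal(selectWorstEye(list(oxford = 1), list(oxford = 3)), "left")
  expect_equal(selectWorstEye(list(oxford = 2, pain = 6),
                              list(oxford = 2, pain = 3)), "right")
  expect_error(selectWorstEye(list(oxford = NA), list(oxford = 1)),
               "Oxford")
  # full tie: deterministic under a seed, uniform across seeds
  e <- list(oxford = 2, pain = 4)
  expect_identical(selectWorstEye(e, e, seed = 99),
                   selectWorstEye(e, e, seed = 99))
  picks <- vapply(1:10000, function(s) selectWorstEye(e, e, seed = s),
                  character(1))
  expect_lt(abs(mean(picks == "right") - 0.5), 0.02)
})
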