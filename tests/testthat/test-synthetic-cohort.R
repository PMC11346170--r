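test_that("nearest-correlation projection is idempotent and repairs", {
  expect_equal(nearestPositiveDefinite(diag(4)), diag(4))
  m <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(nearestPositiveDefinite(m), m)
  # indefinite 3x3: all pairwise 0.9 with one -0.9 is not PSD
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  rep <- nearestPositiveDefinite(bad)
  expect_gte(min(eigen(rep, symmetric = TRUE)$values), -1e-10)
  expect_equal(unname(diag(rep)), rep(1, 3))
  expect_equal(rep, t(rep))
  expect_error(nearestPositiveDefinite(matrix(1:6, 2)), "square")
  expect_error(nearestPositiveDefinite(matrix(c(1, 0.2, 0.5, 1), 2)),
               "symmetric")
})

test_that("latent calibration recovers the bivariate-normal closed form", {
  r0 <- calibrateLatentCorrelation(0, nCalib = 20000, seed = 3)
  expect_lt(abs(as.numeric(r0)), 0.02)
  r <- calibrateLatentCorrelation(0.3, nCalib = 20000, seed = 3)
  expect_lt(abs(as.numeric(r) - 2 * sin(pi * 0.3 / 6)), 0.03)
  expect_lt(abs(attr(r, "achieved") - 0.3), 0.02)
  expect_error(calibrateLatentCorrelation(0.96), "0.95")
  expect_error(calibrateLatentCorrelation(0.3, nCalib = 100), "10000")
})

test_that("binned targets need inflated latent correlations", {
  bin4 <- function(z) findInterval(exp(4 + 0.6 * z), c(10, 50, 100))
  r <- calibrateLatentCorrelation(0.3, transformA = bin4,
                                  nCalib = 20000, seed = 5)
  expect_gt(as.numeric(r), 0.3)  # attenuation requires inflation
  # re-simulation oracle at the returned value
  set.seed(99)
  z1 <- rnorm(50000); z2 <- rnorm(50000)
  y <- as.numeric(r) * z1 + sqrt(1 - as.numeric(r)^2) * z2
  expect_lt(abs(cor(bin4(z1), y, method = "spearman") - 0.3), 0.02)
})

test_that("an unreachable Spearman target is flagged with the ceiling", {
  # a 2-level binning cannot reach rho 0.9
  coarse <- function(z) as.integer(z > 1.5)
  expect_error(calibrateLatentCorrelation(0.9, transformA = coarse,
                                          nCalib = 20000, seed = 2),
               "maximum achievable")
})

test_that("default config encodes the published design", {
  cfg <- table1Default()
  expect_s4_class(cfg, "CohortConfig")
  expect_true(validObject(cfg))
  expect_equal(cfg@nAided + cfg@nNaided, 214L)
  expect_equal(cfg@nAided, 63L)
  expect_equal(unname(cfg@femaleFraction["AIDED"]), 0.97)
  # morphometric score marginals reproduce the printed subscore moments
  icSpec <- cfg@marginals$NAIDED$mean_ic_density
  m <- IVCMgrade:::lognormalScoreMoments(icSpec$meanlog, icSpec$sdlog,
                                         c(10, 50, 100))
  expect_lt(abs(m["mean"] - 1.7), 0.05)
  expect_lt(abs(m["sd"] - 0.7), 0.05)
  # nerve-density marginal pins P(NFD <= 15) at the printed subscore mean
  nfdSpec <- cfg@marginals$AIDED$mean_nfd
  expect_lt(abs(pnorm((log(15) - nfdSpec$meanlog) / nfdSpec$sdlog) - 0.4),
            1e-10)
})

test_that("cohort generation is reproducible and correctly sized", {
  cfg <- calibratedDefaultConfig()
  co <- generateCohort(cfg, seed = 11)
  expect_equal(nrow(co), 214L)
  expect_equal(sum(co$group == "AIDED"), 63L)
  expect_equal(sum(co$group == "NAIDED"), 151L)
  co2 <- generateCohort(cfg, seed = 11)
  expect_identical(co, co2)  # byte-identical under the same seed
  expect_false(identical(co, generateCohort(cfg, seed = 12)))
  # empty cohort
  cfg0 <- cfg; cfg0@nAided <- 0L; cfg0@nNaided <- 0L
  expect_equal(nrow(generateCohort(cfg0, seed = 1)), 0L)
})

test_that("generated records respect ranges and scoring invariants", {
  co <- generateCohort(calibratedDefaultConfig(), seed = 21)
  expect_true(all(co$osdi_total >= 0 & co$osdi_total <= 100))
  expect_true(all(co$schirmer_mm >= 0))
  expect_true(all(co$tbut_s > 0))
  expect_true(all(co$oxford %in% 0:5))
  expect_true(all(co$pain %in% 0:10))
  expect_true(all(co$hla_dr_auf >= 0))
  expect_true(all(co$mean_tortuosity >= 1))
  expect_true(all(co$group %in% c("AIDED", "NAIDED")))
  # scores re-derivable from the morphometry columns
  expect_identical(co$ic_sub, icSubscore(co$mean_ic_density)$sub)
  expect_identical(co$nd_sub, ndSubscore(co$mean_nfd)$sub)
  expect_identical(co$tivcm, co$ic_sub + co$nd_sub + co$nm_sub)
  expect_true(all(co$tivcm >= 0 & co$tivcm <= 6))
})

test_that("marginal means are recovered within Monte-Carlo error", {
  cfg <- calibratedDefaultConfig()
  targets <- list(age = c(55, 15), osdi_total = c(56, 24),
                  schirmer_mm = c(17, 10), tbut_s = c(6.4, 3.7),
                  oxford = c(0.8, 1.1))
  hits <- 0L; total <- 0L
  for (rep in 1:8) {
    co <- generateCohort(cfg, seed = 300 + rep)
    na <- co[co$group == "NAIDED", ]
    for (v in names(targets)) {
      tol <- 3 * targets[[v]][2] / sqrt(nrow(na))
      total <- total + 1L
      if (abs(mean(na[[v]]) - targets[[v]][1]) <= tol) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("the induced score/HLA-DR correlation matches the planted target", {
  cfg <- calibratedDefaultConfig()
  rhos <- vapply(1:20, function(i) {
    co <- generateCohort(cfg, seed = 500 + i)
    cor(co$tivcm, co$hla_dr_auf, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.30), 0.05)
})

test_that("configuration round-trips through YAML", {
  cfg <- calibratedDefaultConfig()
  path <- tempfile(fileext = ".yaml")
  writeCohortConfig(cfg, path)
  back <- readCohortConfig(path)
  expect_equal(back@nAided, cfg@nAided)
  expect_equal(back@femaleFraction, cfg@femaleFraction)
  expect_equal(back@latentCorrelation, cfg@latentCorrelation,
               tolerance = 1e-9)
  expect_equal(back@marginals$AIDED$age$mean, cfg@marginals$AIDED$age$mean,
               tolerance = 1e-9)
  # generation from the round-tripped config is equivalent
  expect_equal(generateCohort(back, seed = 4), generateCohort(cfg, seed = 4),
               tolerance = 1e-9)
})

test_that("cohort tables round-trip through TSV", {
  co <- generateCohort(calibratedDefaultConfig(), seed = 8)[1:25, ]
  path <- tempfile(fileext = ".tsv")
  writeCohort(co, path)
  back <- readCohort(path)
  expect_equal(back$tivcm, co$tivcm)
  expect_equal(back$hla_dr_auf, co$hla_dr_auf, tolerance = 1e-9)
  expect_equal(names(back), names(co))
})
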