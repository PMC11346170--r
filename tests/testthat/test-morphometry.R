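test_that("cell density follows the frame geometry", {
  expect_equal(icDensity(12, 0.16), 75)
  expect_equal(icDensity(0, 0.16), 0)
  expect_equal(icDensity(16, 0.16), 100)
  expect_error(icDensity(3, 0), "positive")
  # scale invariance: doubling the count doubles the density
  n <- sample(0:50, 10)
  expect_equal(icDensity(2 * n), 2 * icDensity(n))
})

test_that("pixel/physical unit conversions are exact", {
  expect_equal(pixelSizeUm(), 400 / 384)
  lenPx <- c(1, 17.25, 384, 1000)
  mm <- lenPx * pixelSizeUm() / 1000
  expect_equal(mm * 1000 / pixelSizeUm(), lenPx, tolerance = 1e-12)
})

test_that("nerve metrics reproduce closed-form geometry", {
  straight <- cbind(x = c(0, 384), y = c(100, 100))  # full 400 um span
  nm <- nerveMetrics(list(straight))
  expect_equal(nm$nfl, 2.5)          # 0.4 mm / 0.16 mm2
  expect_equal(nm$nfd, 6.25)         # 1 / 0.16
  expect_equal(nm$meanTortuosity, 1)

  semi <- semicirclePolyline(radius = 100, n = 200)
  expect_lt(abs(nerveMetrics(list(semi))$meanTortuosity - pi / 2),
            0.01 * pi / 2)

  empty <- nerveMetrics(list())
  expect_equal(empty$nfd, 0)
  expect_equal(empty$nfl, 0)
  expect_equal(empty$meanTortuosity, 1)

  # degenerate closed loop: zero chord excluded with a warning
  loop <- rbind(straight, straight[1, , drop = FALSE])
  expect_warning(nm2 <- nerveMetrics(list(loop, straight)), "zero-chord")
  expect_equal(nm2$meanTortuosity, 1)
  expect_equal(nm2$nfd, 12.5)
})

test_that("measured tortuosity matches ground truth on rendered frames", {
  fr <- renderFrame(imageSpec(nNerves = 4L, nCells = 0L, noiseSd = 0,
                              seed = 17L))
  nm <- nerveMetrics(fr$annotation)
  expect_equal(nm$meanTortuosity, mean(fr$annotation@nerveTortuosity),
               tolerance = 0.02)
  expect_equal(nm$nfl * 0.16 * 1000, sum(fr$annotation@nerveLengthUm),
               tolerance = 1e-9)
})

test_that("focus selection keeps the sharpest frames with stable ties", {
  base <- renderFrame(imageSpec(nCells = 10L, nNerves = 2L, noiseSd = 0,
                                seed = 3L))$image
  frames <- list(base, base, base)
  expect_equal(selectSharpest(frames, k = 5), 1:3)  # fewer than k: keep all
  seven <- list(base, IVCMgrade:::gaussianBlur(base, 2), base, base,
                IVCMgrade:::gaussianBlur(base, 2), base, base)
  expect_equal(selectSharpest(seven, k = 5), c(1, 3, 4, 6, 7))
  # identical frames: first k in input order
  expect_equal(selectSharpest(rep(list(base), 7), k = 5), 1:5)
  expect_error(selectSharpest(list()), "no frames")
})

test_that("reflectivity index is calibrated against the planted contrast", {
  # uniform image over any polyline: index exactly 1
  img <- matrix(80, 384, 384)
  line <- cbind(x = c(10, 300), y = c(50, 250))
  expect_equal(reflectivityIndex(img, list(line)), 1)
  # planted contrast 100 over background 50, no blur, no noise: ~3
  fr <- renderFrame(imageSpec(nCells = 0L, nNerves = 3L, noiseSd = 0,
                              blurSigmaPx = 0, nerveContrast = 100,
                              backgroundLevel = 50, seed = 9L))
  ri <- reflectivityIndex(fr$image, fr$annotation)
  expect_lt(abs(ri - 3) / 3, 0.10)
  # monotone in contrast over seeds
  idx <- vapply(1:20, function(s) {
    lo <- renderFrame(imageSpec(nCells = 0L, nNerves = 3L, noiseSd = 0,
                                nerveContrast = 60, seed = 100L + s))
    hi <- renderFrame(imageSpec(nCells = 0L, nNerves = 3L, noiseSd = 0,
                                nerveContrast = 140, seed = 100L + s))
    reflectivityIndex(hi$image, hi$annotation) -
      reflectivityIndex(lo$image, lo$annotation)
  }, numeric(1))
  expect_true(all(idx > 0))
  expect_error(reflectivityIndex(matrix(0, 50, 50), list(line)), "zero")
})

test_that("blob detection recovers planted cells", {
  expect_equal(nrow(detectCells(matrix(50, 384, 384))), 0L)
  fr <- renderFrame(imageSpec(nCells = 12L, nNerves = 0L, noiseSd = 0,
                              seed = 5L))
  det <- detectCells(fr$image)
  expect_equal(nrow(det), 12L)
  tr <- fr$annotation@cells
  d <- vapply(seq_len(nrow(tr)), function(i)
    min(sqrt((det$x - tr[i, 1])^2 + (det$y - tr[i, 2])^2)), numeric(1))
  expect_true(all(d <= 3))
  # recall under noise at the default cell contrast, nerves present
  rec <- vapply(1:20, function(i) {
    f <- renderFrame(imageSpec(nCells = 12L, nNerves = 2L, noiseSd = 5,
                               cellContrast = 80, seed = 2000L + i))
    dd <- detectCells(f$image)
    t2 <- f$annotation@cells
    mean(vapply(seq_len(nrow(t2)), function(j)
      min(sqrt((dd$x - t2[j, 1])^2 + (dd$y - t2[j, 2])^2)) <= 3,
      logical(1)))
  }, numeric(1))
  expect_gte(mean(rec), 0.9)
})

test_that("per-eye summaries average the sharpest five frames", {
  fm <- data.frame(image_id = c("a", "b"), n_cells = c(0, 0),
                   ic_density = c(60, 80), nfd = c(10, 20),
                   nfl = c(1, 2), mean_tortuosity = c(1.1, 1.3),
                   reflectivity_index = c(2, 3), sharpness = c(5, 4))
  s <- summarizeEye(fm, "eye1", k = 5)
  expect_equal(s$mean_ic_density, 70)
  expect_equal(s$n_images_used, 2L)
  # single frame: summary equals that frame
  s1 <- summarizeEye(fm[1, ], k = 5)
  expect_equal(s1$mean_nfd, 10)
  expect_equal(s1$mean_reflectivity, 2)
  # seven frames: only the five sharpest contribute
  set.seed(31)
  fm7 <- data.frame(image_id = letters[1:7], n_cells = 0,
                    ic_density = runif(7, 20, 120), nfd = runif(7, 5, 30),
                    nfl = runif(7, 1, 5), mean_tortuosity = runif(7, 1, 1.5),
                    reflectivity_index = runif(7, 1, 4),
                    sharpness = runif(7))
  s7 <- summarizeEye(fm7, k = 5)
  keep <- order(-fm7$sharpness)[1:5]  # brute-force oracle selection
  expect_equal(s7$mean_ic_density, mean(fm7$ic_density[keep]))
  expect_equal(s7$mean_tortuosity, mean(fm7$mean_tortuosity[keep]))
  expect_error(summarizeEye(fm7[0, ]), "no frame")
})

test_that("frame metrics integrate counting, geometry and focus", {
  fr <- renderFrame(imageSpec(nCells = 8L, nNerves = 2L, noiseSd = 0,
                              seed = 23L))
  m <- frameMetrics(fr$image, fr$annotation, "f1")
  expect_equal(m$n_cells, 8L)
  expect_equal(m$ic_density, 50)
  expect_equal(m$nfd, 2 / 0.16)
  expect_gt(m$sharpness, 0)
  expect_gt(m$reflectivity_index, 1)
})
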