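# Renderer for synthetic sub-basal-plexus frames with exact ground truth.
#
# Raster convention (used everywhere in the package): 8-bit grayscale,
# origin at the top-left pixel center, x rightward, y downward, 0-based
# pixel coordinates. Internally a frame is a numeric matrix indexed
# [y + 1, x + 1].

#' Construct an ImageSpec
#'
#' Parameters of one synthetic confocal frame. Defaults give a 384 x 384 px
#' frame over a 400 x 400 um field with a dozen dendritiform cells and a
#' handful of nerve fibers on a dim background.
#'
#' @param widthPx,heightPx frame size in pixels.
#' @param fieldUm field side length in micrometers.
#' @param nCells,nNerves planted object counts.
#' @param tortuosityAmplitude perpendicular displacement scale (px) of nerve
#'   paths; 0 plants straight nerves.
#' @param nerveContrast,cellContrast peak intensities above background
#'   (8-bit units).
#' @param backgroundLevel background intensity.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param blurSigmaPx post-render Gaussian blur sigma in pixels.
#' @param seed integer RNG seed.
#' @return an [ImageSpec-class].
#' @export
#' @examples
#' imageSpec(nCells = 5L, noiseSd = 0)
imageSpec <- function(widthPx = 384L, heightPx = 384L, fieldUm = 400,
                      nCells = 12L, nNerves = 5L, tortuosityAmplitude = 8,
                      nerveContrast = 100, cellContrast = 80,
                      backgroundLevel = 50, noiseSd = 5,
                      blurSigmaPx = 0.7, seed = 1L) {
  new("ImageSpec", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), fieldUm = fieldUm,
      nCells = as.integer(nCells), nNerves = as.integer(nNerves),
      tortuosityAmplitude = tortuosityAmplitude,
      nerveContrast = nerveContrast, cellContrast = cellContrast,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      blurSigmaPx = blurSigmaPx, seed = as.integer(seed))
}

#' Plant one nerve fiber path
#'
#' Generates a nerve polyline traversing the frame: a straight chord between
#' two random points on opposite frame edges plus a smooth sinusoidal
#' perpendicular displacement scaled by the spec's `tortuosityAmplitude`
#' (two harmonics with random frequency and phase, tapered to zero at the
#' endpoints so the path still spans the frame). Amplitude 0 yields an
#' exactly straight segment (tortuosity 1); expected tortuosity grows with
#' the amplitude. Vertices are clipped to the frame.
#'
#' Consumes the current RNG stream; seed control belongs to the caller
#' ([renderFrame()] seeds it from the spec).
#'
#' @param spec an [ImageSpec-class].
#' @param nVertices number of polyline vertices.
#' @return numeric matrix with columns `x`, `y` (0-based pixel coordinates).
#' @export
plantNerve <- function(spec, nVertices = 100L) {
  w <- spec@widthPx; h <- spec@heightPx
  horizontal <- runif(1) < 0.5
  if (horizontal) {
    p0 <- c(0, runif(1, 0.1, 0.9) * (h - 1))
    p1 <- c(w - 1, runif(1, 0.1, 0.9) * (h - 1))
  } else {
    p0 <- c(runif(1, 0.1, 0.9) * (w - 1), 0)
    p1 <- c(runif(1, 0.1, 0.9) * (w - 1), h - 1)
  }
  t <- seq(0, 1, length.out = nVertices)
  base <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  A <- spec@tortuosityAmplitude
  if (A > 0) {
    f1 <- sample(1:3, 1); f2 <- sample(3:6, 1)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    disp <- A * (0.75 * sin(2 * pi * f1 * t + ph1) +
                 0.35 * sin(2 * pi * f2 * t + ph2)) * sin(pi * t)
  } else disp <- rep(0, nVertices)
  chord <- p1 - p0
  perp <- c(-chord[2], chord[1]) / sqrt(sum(chord^2))
  poly <- base + disp %o% perp
  poly[, 1] <- pmin(pmax(poly[, 1], 0), w - 1)
  poly[, 2] <- pmin(pmax(poly[, 2], 0), h - 1)
  colnames(poly) <- c("x", "y")
  poly
}

# Minimum distance from every pixel (in a bounding window) to a polyline;
# accumulates into a running min-distance field.
accumulatePolylineDistance <- function(D, poly, pad) {
  h <- nrow(D); w <- ncol(D)
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    x0 <- max(0, floor(min(a[1], b[1]) - pad))
    x1 <- min(w - 1, ceiling(max(a[1], b[1]) + pad))
    y0 <- max(0, floor(min(a[2], b[2]) - pad))
    y1 <- min(h - 1, ceiling(max(a[2], b[2]) + pad))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys, length(ys), length(xs))
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      dx <- px - a[1]; dy <- py - a[2]
      d <- sqrt(dx * dx + dy * dy)
    } else {
      tt <- ((px - a[1]) * vx + (py - a[2]) * vy) / len2
      tt <- pmin(pmax(tt, 0), 1)
      dx <- px - (a[1] + tt * vx); dy <- py - (a[2] + tt * vy)
      d <- sqrt(dx * dx + dy * dy)
    }
    ri <- ys + 1; ci <- xs + 1
    D[ri, ci] <- pmin(D[ri, ci], d)
  }
  D
}

polylineArcChord <- function(poly) {
  seg <- sqrt(rowSums(diff(poly)^2))
  arc <- sum(seg)
  chord <- sqrt(sum((poly[nrow(poly), ] - poly[1, ])^2))
  c(arc = arc, chord = chord)
}

#' Render one synthetic confocal frame with ground truth
#'
#' Renders the planted scene: nerves as smooth curvilinear strokes of peak
#' intensity `nerveContrast` (Gaussian cross-section, sigma ~1.2 px), cells
#' as isotropic Gaussian spots (sigma 3 px, about 3 um) with 2-4 short
#' radial processes mimicking dendritiform morphology, on a constant
#' background; the composite is Gaussian-blurred, Gaussian noise is added,
#' and intensities are clipped to the 8-bit range. Cell centers are
#' rejection-sampled to keep a minimum separation so ground truth is
#' unambiguous. Deterministic given `spec@seed`.
#'
#' @param spec an [ImageSpec-class].
#' @return a list with `image` (numeric matrix, values 0-255, indexed
#'   `[y+1, x+1]`) and `annotation` (a [GroundTruthAnnotation-class]).
#' @export
#' @examples
#' fr <- renderFrame(imageSpec(nCells = 3L, nNerves = 1L, noiseSd = 0))
#' dim(fr$image)
renderFrame <- function(spec) {
  validObject(spec)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec@seed)
  w <- spec@widthPx; h <- spec@heightPx
  if (spec@backgroundLevel + max(spec@nerveContrast, spec@cellContrast) > 255)
    warning("contrast exceeds the 8-bit range; intensities will be clipped")

  nerves <- list(); tort <- numeric(0); lenUm <- numeric(0)
  nerveField <- matrix(0, h, w)
  if (spec@nNerves > 0) {
    sigmaW <- 1.2
    D <- matrix(Inf, h, w)
    for (k in seq_len(spec@nNerves)) {
      poly <- plantNerve(spec)
      nerves[[k]] <- poly
      ac <- polylineArcChord(poly)
      tort[k] <- if (ac["chord"] > 0) ac["arc"] / ac["chord"] else NA_real_
      lenUm[k] <- ac["arc"] * spec@fieldUm / w
      D <- accumulatePolylineDistance(D, poly, pad = 4 * sigmaW)
    }
    nerveField <- spec@nerveContrast * exp(-D^2 / (2 * sigmaW^2))
  }

  cellField <- matrix(0, h, w)
  cells <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  if (spec@nCells > 0) {
    margin <- 8; minSep <- 14
    pts <- matrix(NA_real_, spec@nCells, 2)
    placed <- 0; tries <- 0
    while (placed < spec@nCells && tries < 10000) {
      tries <- tries + 1
      cand <- c(runif(1, margin, w - 1 - margin),
                runif(1, margin, h - 1 - margin))
      if (placed == 0 ||
          min(sqrt(rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2,
                                 cand)^2))) >= minSep) {
        placed <- placed + 1
        pts[placed, ] <- cand
      }
    }
    if (placed < spec@nCells)
      stop("could not place the requested number of cells in the frame")
    colnames(pts) <- c("x", "y")
    cells <- pts
    sigmaC <- 3
    xs <- 0:(w - 1); ys <- 0:(h - 1)
    for (k in seq_len(spec@nCells)) {
      cx <- pts[k, 1]; cy <- pts[k, 2]
      x0 <- max(0, floor(cx - 4 * sigmaC)); x1 <- min(w - 1,
                                                      ceiling(cx + 4 * sigmaC))
      y0 <- max(0, floor(cy - 4 * sigmaC)); y1 <- min(h - 1,
                                                      ceiling(cy + 4 * sigmaC))
      gx <- exp(-((x0:x1) - cx)^2 / (2 * sigmaC^2))
      gy <- exp(-((y0:y1) - cy)^2 / (2 * sigmaC^2))
      spot <- spec@cellContrast * (gy %o% gx)
      ri <- (y0:y1) + 1; ci <- (x0:x1) + 1
      cellField[ri, ci] <- pmax(cellField[ri, ci], spot)
      # short dendritiform processes
      nProc <- sample(2:4, 1)
      ang <- runif(nProc, 0, 2 * pi)
      plen <- runif(nProc, 5, 9)
      Dp <- matrix(Inf, h, w)
      for (j in seq_len(nProc)) {
        pend <- c(min(max(cx + plen[j] * cos(ang[j]), 0), w - 1),
                  min(max(cy + plen[j] * sin(ang[j]), 0), h - 1))
        Dp <- accumulatePolylineDistance(Dp, rbind(c(cx, cy), pend), pad = 4)
      }
      proc <- 0.6 * spec@cellContrast * exp(-Dp^2 / 2)
      cellField <- pmax(cellField, proc)
    }
  }

  img <- spec@backgroundLevel + pmax(nerveField, cellField)
  if (spec@blurSigmaPx > 0)
    img <- gaussianBlur(img, spec@blurSigmaPx)
  if (spec@noiseSd > 0)
    img <- img + matrix(rnorm(w * h, 0, spec@noiseSd), h, w)
  img <- round(pmin(pmax(img, 0), 255))

  ann <- new("GroundTruthAnnotation", cells = cells, nerves = nerves,
             nerveTortuosity = tort, nerveLengthUm = lenUm)
  list(image = img, annotation = ann)
}

# Gaussian blur on the package's [y, x] matrix convention (EBImage backend;
# isotropic kernel, so the axis order is immaterial).
gaussianBlur <- function(img, sigma) {
  as.matrix(EBImage::gblur(img, sigma = sigma))
}

#' Render a series of frames
#'
#' @param spec an [ImageSpec-class] serving as the template.
#' @param nFrames number of frames.
#' @param seed root seed; frame `i` uses a seed derived from it.
#' @return list of `list(image, annotation)` as from [renderFrame()].
#' @export
renderFrames <- function(spec, nFrames, seed = 1L) {
  lapply(seq_len(nFrames), function(i) {
    s <- spec
    s@seed <- as.integer(deriveSeed(seed, i))
    renderFrame(s)
  })
}

#' Write / read a frame as an image file
#'
#' 8-bit grayscale PNG or TIFF, chosen from the file extension.
#'
#' @param img numeric matrix (0-255, `[y+1, x+1]` indexing).
#' @param path file path ending in `.png` or `.tif`/`.tiff`.
#' @return `writeFrameImage()` returns `path` invisibly; `readFrameImage()`
#'   the matrix.
#' @export
writeFrameImage <- function(img, path) {
  type <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "tiff"
  # EBImage stores images [x, y] with values in [0, 1]
  EBImage::writeImage(t(img) / 255, path, type = type, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeFrameImage
#' @export
readFrameImage <- function(path) {
  e <- EBImage::readImage(path)
  m <- EBImage::imageData(e)
  if (length(dim(m)) > 2) m <- m[, , 1]
  round(t(m) * 255)
}

#' Write / read ground-truth annotations as TSV
#'
#' Two dialects: a cell table (`image_id`, `x`, `y`) and a nerve polyline
#' table (`image_id`, `nerve_id`, `vertex_index`, `x`, `y`), both 0-based
#' pixel coordinates; round-trippable.
#'
#' @param annotations named list of [GroundTruthAnnotation-class] objects
#'   (names are image ids).
#' @param cellPath,nervePath output TSV paths.
#' @return `writeAnnotations()` returns the two paths invisibly;
#'   `readAnnotations()` a named list of [GroundTruthAnnotation-class].
#' @export
writeAnnotations <- function(annotations, cellPath, nervePath) {
  cellRows <- do.call(rbind, lapply(names(annotations), function(id) {
    cc <- annotations[[id]]@cells
    if (!nrow(cc)) return(NULL)
    data.frame(image_id = id, x = cc[, 1], y = cc[, 2])
  }))
  if (is.null(cellRows))
    cellRows <- data.frame(image_id = character(0), x = numeric(0),
                           y = numeric(0))
  nerveRows <- do.call(rbind, lapply(names(annotations), function(id) {
    nv <- annotations[[id]]@nerves
    if (!length(nv)) return(NULL)
    do.call(rbind, lapply(seq_along(nv), function(k) {
      data.frame(image_id = id, nerve_id = k,
                 vertex_index = seq_len(nrow(nv[[k]])) - 1L,
                 x = nv[[k]][, 1], y = nv[[k]][, 2])
    }))
  }))
  if (is.null(nerveRows))
    nerveRows <- data.frame(image_id = character(0), nerve_id = integer(0),
                            vertex_index = integer(0), x = numeric(0),
                            y = numeric(0))
  write.table(cellRows, cellPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(nerveRows, nervePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(cells = cellPath, nerves = nervePath))
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(cellPath, nervePath) {
  cells <- read.delim(cellPath, stringsAsFactors = FALSE)
  nerves <- read.delim(nervePath, stringsAsFactors = FALSE)
  ids <- union(unique(cells$image_id), unique(nerves$image_id))
  out <- lapply(setNames(ids, ids), function(id) {
    cc <- cells[cells$image_id == id, c("x", "y"), drop = FALSE]
    cc <- as.matrix(cc); colnames(cc) <- c("x", "y")
    nn <- nerves[nerves$image_id == id, , drop = FALSE]
    polys <- lapply(split(nn, nn$nerve_id), function(d) {
      d <- d[order(d$vertex_index), ]
      p <- as.matrix(d[, c("x", "y")]); colnames(p) <- c("x", "y")
      rownames(p) <- NULL
      p
    })
    names(polys) <- NULL
    geom <- lapply(polys, polylineArcChord)
    new("GroundTruthAnnotation", cells = cc, nerves = polys,
        nerveTortuosity = vapply(geom, function(g)
          if (g["chord"] > 0) g[["arc"]] / g[["chord"]] else NA_real_,
          numeric(1)),
        nerveLengthUm = vapply(geom, function(g) g[["arc"]], numeric(1)) *
          pixelSizeUm())
  })
  out
}
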