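# Per-frame and per-eye quantitative metrics: inflammatory-cell density,
# nerve fiber density/length, tortuosity, reflectivity, focus-based frame
# selection, and an optional automated blob detector for cell counting.

#' Inflammatory-cell density
#'
#' Cells per square millimeter for a frame; the standard confocal frame
#' covers 0.16 mm2 (400 x 400 um).
#'
#' @param nCells cell count (non-negative).
#' @param fieldAreaMm2 imaged area in mm2 (> 0).
#' @return density in cells/mm2.
#' @export
#' @examples
#' icDensity(12)  # 75 cells/mm2
icDensity <- function(nCells, fieldAreaMm2 = 0.16) {
  if (any(fieldAreaMm2 <= 0)) stop("field area must be positive")
  if (any(nCells < 0)) stop("cell count must be non-negative")
  nCells / fieldAreaMm2
}

#' Nerve fiber density, length and tortuosity of a frame
#'
#' Computes, from traced nerve polylines (pixel coordinates):
#' nerve fiber density NFD = number of polylines per mm2 of frame; nerve
#' fiber length NFL = summed polyline arc length (mm) per mm2; and the mean
#' arc-length/chord-length tortuosity index. Every annotated polyline counts
#' as one nerve (trunks and branches are separate polylines as annotated).
#' Degenerate polylines with zero chord are excluded from the tortuosity
#' mean with a warning; a frame without valid nerves reports tortuosity 1
#' by convention.
#'
#' @param nerves list of polylines (matrices with columns `x`, `y`), each
#'   with at least 2 vertices, or a [GroundTruthAnnotation-class].
#' @param pixelSize pixel side length in micrometers (default 400/384).
#' @param fieldAreaMm2 frame area in mm2.
#' @return list with `nfd` (nerves/mm2), `nfl` (mm/mm2), `meanTortuosity`.
#' @export
#' @examples
#' straight <- cbind(x = c(0, 384), y = c(100, 100))  # full 400 um span
#' nerveMetrics(list(straight))  # nfl = 2.5 mm/mm2, nfd = 6.25, tortuosity 1
nerveMetrics <- function(nerves, pixelSize = pixelSizeUm(),
                         fieldAreaMm2 = 0.16) {
  if (is(nerves, "GroundTruthAnnotation")) nerves <- nerves@nerves
  if (pixelSize <= 0) stop("pixelSize must be positive")
  if (!length(nerves))
    return(list(nfd = 0, nfl = 0, meanTortuosity = 1.0))
  bad <- vapply(nerves, function(p) !is.matrix(p) || nrow(p) < 2L,
                logical(1))
  if (any(bad)) stop("each polyline needs at least 2 vertices")
  geom <- vapply(nerves, polylineArcChord, numeric(2))
  arcMm <- geom["arc", ] * pixelSize / 1000
  tort <- ifelse(geom["chord", ] > 0, geom["arc", ] / geom["chord", ],
                 NA_real_)
  if (anyNA(tort)) {
    warning("excluding ", sum(is.na(tort)),
            " zero-chord polyline(s) from the tortuosity mean")
  }
  mt <- if (all(is.na(tort))) 1.0 else mean(tort, na.rm = TRUE)
  list(nfd = length(nerves) / fieldAreaMm2,
       nfl = sum(arcMm) / fieldAreaMm2,
       meanTortuosity = mt)
}

#' Focus measure of a frame (variance of Laplacian)
#'
#' Objective sharpness proxy: the image is convolved with the 3x3 Laplacian
#' kernel (4-neighbour) on the float scale and the variance of the interior
#' response is returned. Blur strictly lowers the measure on otherwise
#' identical frames.
#'
#' @param img numeric matrix.
#' @return non-negative scalar.
#' @export
focusMeasure <- function(img) {
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) return(0)
  core <- m[2:(h - 1), 2:(w - 1)]
  lap <- m[1:(h - 2), 2:(w - 1)] + m[3:h, 2:(w - 1)] +
         m[2:(h - 1), 1:(w - 2)] + m[2:(h - 1), 3:w] - 4 * core
  var(as.vector(lap))
}

#' Select the sharpest frames of an eye
#'
#' Orders frames by the variance-of-Laplacian focus measure and keeps the
#' top `k` (all frames when fewer than `k` are supplied). Ties are broken
#' by input order, so selection is deterministic.
#'
#' @param frames list of image matrices.
#' @param k number of frames to keep (default 5).
#' @return integer vector of selected frame indices, in input order.
#' @export
selectSharpest <- function(frames, k = 5L) {
  if (!length(frames)) stop("no frames supplied")
  s <- vapply(frames, focusMeasure, numeric(1))
  keep <- order(-s, seq_along(s))[seq_len(min(k, length(s)))]
  sort(keep)
}

#' Nerve reflectivity index of a frame
#'
#' Mean image intensity sampled along the nerve polylines (bilinear
#' interpolation at ~0.5 px spacing) divided by a robust background level:
#' the median intensity of all pixels farther than `bgDistPx` from every
#' polyline. A uniform image has index 1.
#'
#' @param img numeric matrix (`[y+1, x+1]`, 0-based coordinates).
#' @param nerves list of polylines or a [GroundTruthAnnotation-class].
#' @param bgDistPx pixels closer than this to a nerve are excluded from the
#'   background estimate.
#' @return dimensionless reflectivity index.
#' @export
reflectivityIndex <- function(img, nerves, bgDistPx = 5) {
  if (is(nerves, "GroundTruthAnnotation")) nerves <- nerves@nerves
  if (!length(nerves)) stop("at least one polyline required")
  h <- nrow(img); w <- ncol(img)
  samplePts <- do.call(rbind, lapply(nerves, function(p) resamplePolyline(p,
                                                                          0.5)))
  vals <- bilinearSample(img, samplePts[, 1], samplePts[, 2])
  D <- matrix(Inf, h, w)
  for (p in nerves) D <- accumulatePolylineDistance(D, p, pad = bgDistPx + 2)
  bg <- median(img[D > bgDistPx])
  if (!is.finite(bg) || bg == 0) stop("background median is zero or undefined")
  mean(vals) / bg
}

# Resample a polyline at roughly even arc-length spacing (px).
resamplePolyline <- function(poly, spacing = 0.5) {
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L == 0) return(poly[1, , drop = FALSE])
  s <- seq(0, L, by = spacing)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(poly) - 1)
  f <- (s - cum[i]) / pmax(seg[i], .Machine$double.eps)
  poly[i, , drop = FALSE] + f * (poly[i + 1, , drop = FALSE] -
                                   poly[i, , drop = FALSE])
}

# Bilinear interpolation at 0-based (x, y) positions.
bilinearSample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

#' Automated cell detection (Laplacian-of-Gaussian blobs)
#'
#' Optional automated counting path standing in for manual point annotation:
#' the frame is normalised to `[0, 1]`, smoothed at the cell scale, and the
#' scale-normalised negative Laplacian response is thresholded; local maxima
#' (8-neighbourhood) above the threshold are reported as cell centers. A
#' Hessian shape test rejects elongated (ridge-like) maxima, so nerve
#' fibers crossing the frame do not count as cells: a blob has two strongly
#' negative principal curvatures of similar size, a ridge only one.
#'
#' @param img numeric matrix, 8-bit scale.
#' @param sigma blob scale in pixels (default 3, matching a ~3 um cell
#'   body).
#' @param threshold response threshold on the normalised scale.
#' @param shapeRatio minimum ratio of the weaker to the stronger principal
#'   curvature at a maximum (0 disables the ridge rejection).
#' @return data.frame with 0-based `x`, `y` coordinates of detections.
#' @export
detectCells <- function(img, sigma = 3, threshold = 0.04,
                        shapeRatio = 0.25) {
  m <- matrix(as.numeric(img), nrow(img), ncol(img)) / 255
  g <- gaussianBlur(m, sigma)
  h <- nrow(g); w <- ncol(g)
  lap <- matrix(0, h, w)
  lap[2:(h - 1), 2:(w - 1)] <-
    g[1:(h - 2), 2:(w - 1)] + g[3:h, 2:(w - 1)] +
    g[2:(h - 1), 1:(w - 2)] + g[2:(h - 1), 3:w] -
    4 * g[2:(h - 1), 2:(w - 1)]
  resp <- -sigma^2 * lap
  isMax <- matrix(FALSE, h, w)
  core <- resp[2:(h - 1), 2:(w - 1)]
  isMax[2:(h - 1), 2:(w - 1)] <-
    core >= resp[1:(h - 2), 2:(w - 1)] & core >= resp[3:h, 2:(w - 1)] &
    core >= resp[2:(h - 1), 1:(w - 2)] & core >= resp[2:(h - 1), 3:w] &
    core >= resp[1:(h - 2), 1:(w - 2)] & core >= resp[1:(h - 2), 3:w] &
    core >= resp[3:h, 1:(w - 2)] & core >= resp[3:h, 3:w] &
    core > threshold
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) && shapeRatio > 0) {
    r <- idx[, 1]; c <- idx[, 2]
    hxx <- g[cbind(r, c + 1)] + g[cbind(r, c - 1)] - 2 * g[cbind(r, c)]
    hyy <- g[cbind(r + 1, c)] + g[cbind(r - 1, c)] - 2 * g[cbind(r, c)]
    hxy <- (g[cbind(r + 1, c + 1)] + g[cbind(r - 1, c - 1)] -
              g[cbind(r + 1, c - 1)] - g[cbind(r - 1, c + 1)]) / 4
    tr2 <- (hxx + hyy) / 2
    det0 <- hxx * hyy - hxy^2
    disc <- sqrt(pmax(tr2^2 - det0, 0))
    l1 <- tr2 + disc; l2 <- tr2 - disc  # l1 >= l2 (both < 0 at a blob peak)
    keep <- l1 < 0 & abs(l1) / pmax(abs(l2), 1e-12) >= shapeRatio
    idx <- idx[keep, , drop = FALSE]
  }
  data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

#' Per-frame metrics from an image and its annotation
#'
#' Convenience constructor of one frame's metric row, combining cell
#' counting (from the annotation), nerve metrics, reflectivity and the
#' focus measure.
#'
#' @param img numeric matrix.
#' @param annotation a [GroundTruthAnnotation-class] (or list with `cells`
#'   and `nerves`).
#' @param imageId identifier stored in the row.
#' @param pixelSize micrometers per pixel.
#' @param fieldAreaMm2 frame area in mm2.
#' @return one-row data.frame with `image_id`, `n_cells`, `ic_density`,
#'   `nfd`, `nfl`, `mean_tortuosity`, `reflectivity_index`, `sharpness`.
#' @export
frameMetrics <- function(img, annotation, imageId = "frame",
                         pixelSize = pixelSizeUm(), fieldAreaMm2 = 0.16) {
  cells <- if (is(annotation, "GroundTruthAnnotation")) annotation@cells
           else annotation$cells
  nerves <- if (is(annotation, "GroundTruthAnnotation")) annotation@nerves
            else annotation$nerves
  nm <- nerveMetrics(nerves, pixelSize, fieldAreaMm2)
  refl <- if (length(nerves)) reflectivityIndex(img, nerves) else NA_real_
  data.frame(image_id = imageId,
             n_cells = nrow(cells),
             ic_density = icDensity(nrow(cells), fieldAreaMm2),
             nfd = nm$nfd, nfl = nm$nfl,
             mean_tortuosity = nm$meanTortuosity,
             reflectivity_index = refl,
             sharpness = focusMeasure(img))
}

#' Per-eye morphometry summary
#'
#' Selects the sharpest `k` frames (by the stored `sharpness` column,
#' mirroring [selectSharpest()]) and averages each metric arithmetically
#' over the selection.
#'
#' @param frameMetrics data.frame of per-frame rows as from
#'   [frameMetrics()].
#' @param eyeId identifier for the eye.
#' @param k number of frames to use (default 5).
#' @return one-row data.frame with `eye_id`, `n_images_used`,
#'   `mean_ic_density`, `mean_nfd`, `mean_nfl`, `mean_tortuosity`,
#'   `mean_reflectivity`.
#' @export
summarizeEye <- function(frameMetrics, eyeId = "eye", k = 5L) {
  if (!nrow(frameMetrics)) stop("no frame metrics supplied")
  ord <- order(-frameMetrics$sharpness, seq_len(nrow(frameMetrics)))
  keep <- sort(ord[seq_len(min(k, nrow(frameMetrics)))])
  sel <- frameMetrics[keep, , drop = FALSE]
  data.frame(eye_id = eyeId,
             n_images_used = nrow(sel),
             mean_ic_density = mean(sel$ic_density),
             mean_nfd = mean(sel$nfd),
             mean_nfl = mean(sel$nfl),
             mean_tortuosity = mean(sel$mean_tortuosity),
             mean_reflectivity = mean(sel$reflectivity_index))
}
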