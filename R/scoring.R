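# The ordinal IVCM grading score: inflammatory-cell density, nerve density
# and nerve morphology subscores, their total, and worst-eye selection.

#' Inflammatory-cell density subscore (ICsc)
#'
#' Grades the mean inflammatory-cell density (cells/mm2) into four ordinal
#' categories: low (< 10 cells/mm2, code IC-0, subscore 0), medium-low
#' (10-49, IC-1, 1), medium-high (50-99, IC-2, 2), high (>= 100, IC-3, 3).
#' Densities are real-valued averages, so the printed category limits are
#' treated as half-open bin edges `[0,10), [10,50), [50,100), [100, Inf)`:
#' every non-negative density gets a grade, and 10, 50 and 100 fall in the
#' upper bin.
#'
#' @param density numeric vector of mean inflammatory-cell densities
#'   (cells/mm2), non-negative.
#' @return a list with integer `sub` (0-3) and character `code`
#'   (`"IC-0"`..`"IC-3"`), each of the input length.
#' @export
#' @examples
#' icSubscore(75)   # IC-2
#' icSubscore(100)  # IC-3
icSubscore <- function(density) {
  if (any(is.na(density)) || any(density < 0))
    stop("inflammatory-cell density must be non-negative")
  sub <- findInterval(density, c(10, 50, 100))
  list(sub = as.integer(sub), code = sprintf("IC-%d", sub))
}

#' Nerve-density subscore (NDsc)
#'
#' Grades the mean nerve fiber density: normal (> 15 nerves/mm2, code ND-1,
#' subscore 0) versus decreased (<= 15 nerves/mm2, ND-2, subscore 1). The
#' boundary value 15 counts as decreased.
#'
#' @param nfd numeric vector of mean nerve fiber densities (nerves/mm2),
#'   non-negative.
#' @return a list with integer `sub` (0-1) and character `code`
#'   (`"ND-1"`/`"ND-2"`).
#' @export
#' @examples
#' ndSubscore(20)  # ND-1, subscore 0
#' ndSubscore(15)  # ND-2, subscore 1
ndSubscore <- function(nfd) {
  if (any(is.na(nfd)) || any(nfd < 0))
    stop("nerve fiber density must be non-negative")
  sub <- as.integer(nfd <= 15)
  list(sub = sub, code = c("ND-1", "ND-2")[sub + 1L])
}

#' Nerve-morphology subscore (NMsc)
#'
#' Combines the two qualitative nerve-morphology abnormalities: normal
#' (NM-0, 0), abnormal reflectivity only (NM1-R, 1), abnormal tortuosity
#' only (NM1-T, 1), both (NM-2, 2).
#'
#' @param reflectivityAbnormal,tortuosityAbnormal logical vectors.
#' @return a list with integer `sub` (0-2) and character `code`.
#' @export
#' @examples
#' nmSubscore(TRUE, TRUE)   # NM-2
#' nmSubscore(FALSE, TRUE)  # NM1-T
nmSubscore <- function(reflectivityAbnormal, tortuosityAbnormal) {
  stopifnot(is.logical(reflectivityAbnormal), is.logical(tortuosityAbnormal))
  if (any(is.na(reflectivityAbnormal)) || any(is.na(tortuosityAbnormal)))
    stop("morphology flags must not be NA")
  sub <- as.integer(reflectivityAbnormal) + as.integer(tortuosityAbnormal)
  code <- character(length(sub))
  code[sub == 0L] <- "NM-0"
  code[sub == 2L] <- "NM-2"
  code[sub == 1L & reflectivityAbnormal] <- "NM1-R"
  code[sub == 1L & tortuosityAbnormal] <- "NM1-T"
  list(sub = sub, code = code)
}

#' Derive the nerve-morphology flags from per-eye morphometry
#'
#' The grading treats reflectivity and tortuosity abnormalities as
#' qualitative judgements; this operationalises them as configurable
#' thresholds on the per-eye means: tortuosity is abnormal when the mean
#' arc/chord index exceeds `thresholds["tortuosity"]` (default 1.2) and
#' reflectivity when the mean nerve/background intensity ratio exceeds
#' `thresholds["reflectivity"]` (default 2.5).
#'
#' @param summary a list or one-row data.frame with numeric fields
#'   `mean_tortuosity` and `mean_reflectivity`.
#' @param thresholds named numeric with elements `tortuosity` and
#'   `reflectivity`.
#' @return a list with logical `reflectivityAbnormal` and
#'   `tortuosityAbnormal`.
#' @export
#' @examples
#' flagMorphology(list(mean_tortuosity = 1.5, mean_reflectivity = 1.0))
flagMorphology <- function(summary,
                           thresholds = c(tortuosity = 1.2,
                                          reflectivity = 2.5)) {
  for (f in c("mean_tortuosity", "mean_reflectivity")) {
    v <- summary[[f]]
    if (is.null(v) || any(is.na(v)))
      stop("missing morphometry field: ", f)
  }
  list(
    reflectivityAbnormal =
      as.vector(summary[["mean_reflectivity"]] > thresholds[["reflectivity"]]),
    tortuosityAbnormal =
      as.vector(summary[["mean_tortuosity"]] > thresholds[["tortuosity"]])
  )
}

#' Total IVCM score
#'
#' Sum of the three subscores; ranges 0 (no abnormality) to 6 (high cell
#' density, decreased nerve density, both morphology abnormalities).
#'
#' @param icSub integer 0-3; @param ndSub integer 0-1; @param nmSub integer
#'   0-2.
#' @return integer vector of totals in 0..6.
#' @export
#' @examples
#' totalScore(3, 1, 2)  # 6
totalScore <- function(icSub, ndSub, nmSub) {
  if (any(!icSub %in% 0:3)) stop("icSub out of range 0..3")
  if (any(!ndSub %in% 0:1)) stop("ndSub out of range 0..1")
  if (any(!nmSub %in% 0:2)) stop("nmSub out of range 0..2")
  as.integer(icSub + ndSub + nmSub)
}

#' Grade one eye's morphometry summary
#'
#' Applies the full grading to a per-eye morphometry summary: cell-density
#' binning, nerve-density cutoff, threshold-derived morphology flags, and
#' the total.
#'
#' @param summary list or one-row data.frame with `mean_ic_density`,
#'   `mean_nfd`, `mean_tortuosity`, `mean_reflectivity`.
#' @param thresholds passed to [flagMorphology()].
#' @return an [IVCMScore-class] object.
#' @export
#' @examples
#' ivcmScore(list(mean_ic_density = 75, mean_nfd = 12,
#'                mean_tortuosity = 1.1, mean_reflectivity = 3.2))
ivcmScore <- function(summary,
                      thresholds = c(tortuosity = 1.2, reflectivity = 2.5)) {
  ic <- icSubscore(summary[["mean_ic_density"]])
  nd <- ndSubscore(summary[["mean_nfd"]])
  fl <- flagMorphology(summary, thresholds)
  nm <- nmSubscore(fl$reflectivityAbnormal, fl$tortuosityAbnormal)
  new("IVCMScore",
      icSub = ic$sub, icCode = ic$code,
      ndSub = nd$sub, ndCode = nd$code,
      nmSub = nm$sub, nmCode = nm$code,
      total = totalScore(ic$sub, nd$sub, nm$sub))
}

#' Select the worst eye of a patient
#'
#' Implements the per-patient eye selection: the eye with the higher Oxford
#' staining score is kept; on an Oxford tie the more painful eye wins; on a
#' full tie the choice is randomised (reproducibly, via `seed`).
#'
#' @param right,left lists with numeric `oxford` (required, 0-5) and
#'   optional `pain` (0-10; treated as equal when absent).
#' @param seed integer seed for the randomised tie-break.
#' @return `"right"` or `"left"`.
#' @export
#' @examples
#' selectWorstEye(list(oxford = 3), list(oxford = 1), seed = 1)
selectWorstEye <- function(right, left, seed = 1L) {
  if (is.null(right$oxford) || is.null(left$oxford) ||
      is.na(right$oxford) || is.na(left$oxford))
    stop("both eyes need an Oxford score")
  if (right$oxford != left$oxford)
    return(if (right$oxford > left$oxford) "right" else "left")
  pr <- if (is.null(right$pain) || is.na(right$pain)) 0 else right$pain
  pl <- if (is.null(left$pain) || is.na(left$pain)) 0 else left$pain
  if (pr != pl) return(if (pr > pl) "right" else "left")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (runif(1) < 0.5) "right" else "left"
}

#' Score every eye of a cohort table
#'
#' Vectorised grading over a cohort data.frame carrying the per-eye
#' morphometry columns; appends subscore, code and total columns.
#'
#' @param cohort data.frame with columns `mean_ic_density`, `mean_nfd`,
#'   `mean_tortuosity`, `mean_reflectivity`.
#' @param thresholds passed to [flagMorphology()].
#' @return the cohort with columns `ic_sub`, `ic_code`, `nd_sub`, `nd_code`,
#'   `nm_sub`, `nm_code`, `tivcm` added (overwritten if present).
#' @export
scoreCohort <- function(cohort,
                        thresholds = c(tortuosity = 1.2, reflectivity = 2.5)) {
  ic <- icSubscore(cohort$mean_ic_density)
  nd <- ndSubscore(cohort$mean_nfd)
  fl <- flagMorphology(cohort, thresholds)
  nm <- nmSubscore(fl$reflectivityAbnormal, fl$tortuosityAbnormal)
  cohort$ic_sub <- ic$sub; cohort$ic_code <- ic$code
  cohort$nd_sub <- nd$sub; cohort$nd_code <- nd$code
  cohort$nm_sub <- nm$sub; cohort$nm_code <- nm$code
  cohort$tivcm <- totalScore(ic$sub, nd$sub, nm$sub)
  cohort
}
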