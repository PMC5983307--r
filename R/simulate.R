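## Expected-count simulation and Poisson sampling.

#' Forward projection to expected counts
#'
#' \eqn{\langle y_{im}\rangle = \sum_j P_{ij} x_{jm} + \epsilon_{im}}:
#' the expected sinogram counts given a count-domain image series and a
#' known background term.
#'
#' @param P system matrix (N_D x N_V).
#' @param x count-domain image matrix (N_V x N_T); must be nonnegative.
#' @param eps background matrix (N_D x N_T) or a scalar.
#' @return dense N_D x N_T matrix of expected counts (elementwise >= 0).
#' @export
forwardExpectation <- function(P, x, eps = 0) {
  if (any(x < 0)) stop("negative image values: clip upstream")
  out <- as.matrix(P %*% x) + eps
  out
}

#' Simulate a dynamic scan of a phantom
#'
#' Computes the noise-free ground truth, builds the system matrix, converts
#' activity to expected counts, and calibrates the global sensitivity so
#' that the total expected counts per realization hit `targetCounts`
#' (default 3.5 million, the count regime of a single-slice clinical
#' dynamic FMISO acquisition).  The background term is spatially uniform
#' within each frame with magnitude `bgFrac` of that frame's true counts,
#' standing in for scattered photons and random coincidences as a known
#' additive term.
#'
#' The count-domain image is
#' \eqn{x_{jm} = a_{jm} \Delta T_m V_{vox} S_{cal}} with \eqn{a_{jm}} the
#' frame-averaged decayed activity (Bq/cc), \eqn{V_{vox}} the voxel volume
#' (cc) and \eqn{S_{cal}} the calibration constant (the decay factor is
#' part of \eqn{a_{jm}}).
#'
#' @param phantom a [Phantom-class].
#' @param sched a [FrameSchedule-class].
#' @param geom a [ScannerGeometry-class]; voxel grid must match the phantom.
#' @param targetCounts total expected counts per realization.
#' @param bgFrac background fraction of true counts.
#' @param sliceThickness slice thickness (mm) entering the voxel volume.
#' @param P optional precomputed system matrix.
#' @return a list with elements `truth` ([ImageSeries-class]), `P`,
#'   `expected` (N_D x N_T), `eps`, `calibration` (list with `scal`,
#'   `voxelVolume` in cc, `frameFactors` = scal * voxelVolume * DeltaT_m),
#'   `geometry`, `schedule`, `phantom`.
#' @export
simulateScan <- function(phantom, sched, geom, targetCounts = 3.5e6,
                         bgFrac = 0.2, sliceThickness = 2.0, P = NULL) {
  stopifnot(nrow(phantom@labels) == geom@n)
  truth <- groundTruthActivity(phantom, sched)
  if (is.null(P)) P <- buildSystemMatrix(geom)
  vcc <- geom@voxelSize^2 * sliceThickness / 1000   # mm^3 -> cc
  dur <- frameDurations(sched)
  raw <- as.matrix(P %*% (truth@values %*% diag(dur)))  # per unit scal*vcc
  totRaw <- sum(raw) * vcc
  if (totRaw <= 0) stop("phantom projects to zero counts")
  scal <- targetCounts / ((1 + bgFrac) * totRaw)
  trueCounts <- raw * vcc * scal
  epsFrame <- bgFrac * colSums(trueCounts) / nrow(trueCounts)
  eps <- matrix(epsFrame, nrow(trueCounts), ncol(trueCounts), byrow = TRUE)
  list(truth = truth, P = P, expected = trueCounts + eps, eps = eps,
       calibration = list(scal = scal, voxelVolume = vcc,
                          frameFactors = scal * vcc * dur),
       geometry = geom, schedule = sched, phantom = phantom)
}

## evaluate expr with a private, seeded RNG stream; restores global state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Draw a Poisson noise realization of expected sinogram counts
#'
#' Independent Poisson draws per bin and frame, reproducible under `seed`.
#'
#' @param expected N_D x N_T expected counts (background included), or the
#'   list returned by [simulateScan()].
#' @param seed integer RNG seed.
#' @param eps,geom,sched background, geometry and schedule (taken from the
#'   simulation list when `expected` is one).
#' @return a [SinogramSeries-class].
#' @export
samplePoisson <- function(expected, seed, eps = NULL, geom = NULL,
                          sched = NULL) {
  if (is.list(expected)) {
    sim <- expected
    expected <- sim$expected; eps <- sim$eps
    geom <- sim$geometry; sched <- sim$schedule
  }
  stopifnot(all(expected >= 0))
  y <- withSeed(seed, {
    matrix(rpois(length(expected), as.vector(expected)),
           nrow(expected), ncol(expected))
  })
  new("SinogramSeries", y = y, eps = eps, geometry = geom, schedule = sched,
      seed = as.integer(seed))
}

#' Expected-count sinogram series (no noise)
#'
#' @param sim the list returned by [simulateScan()].
#' @return a [SinogramSeries-class] holding the expected counts themselves
#'   (a "noiseless realization", useful for convergence audits).
#' @export
expectedSinograms <- function(sim) {
  new("SinogramSeries", y = sim$expected, eps = sim$eps,
      geometry = sim$geometry, schedule = sim$schedule, seed = NA_integer_)
}

## counts <-> activity conversions via the simulation calibration
countsToActivity <- function(x, calibration) {
  sweep(x, 2, calibration$frameFactors, "/")
}
activityToCounts <- function(a, calibration) {
  sweep(a, 2, calibration$frameFactors, "*")
}
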