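## Central S4 containers.  All times are seconds, activities Bq/cc, rate
## constants 1/s; conversions to per-minute happen only at reporting
## boundaries.

#' FrameSchedule: the partition of scan time into acquisition frames
#'
#' Frames are half-open intervals `[start, end)` in seconds from scan start,
#' strictly increasing and non-overlapping; gaps are allowed (late frames
#' hours after the main dynamic sequence).  `lambda` is the physical decay
#' constant of the radiotracer (1/s) and `tInj` the injection time (s from
#' scan start).
#'
#' @slot start numeric, frame start times (s).
#' @slot end numeric, frame end times (s).
#' @slot lambda numeric(1), radiotracer decay constant (1/s).
#' @slot tInj numeric(1), injection time (s).
#' @exportClass FrameSchedule
setClass("FrameSchedule",
  representation(start = "numeric", end = "numeric",
                 lambda = "numeric", tInj = "numeric"))

setValidity("FrameSchedule", function(object) {
  msg <- NULL
  if (length(object@start) != length(object@end))
    msg <- c(msg, "start and end must have equal length")
  if (any(object@end <= object@start))
    msg <- c(msg, "every frame must satisfy start < end")
  if (length(object@start) > 1 &&
      any(diff(object@start) <= 0 | object@start[-1] < object@end[-length(object@end)]))
    msg <- c(msg, "frames must be sorted and non-overlapping")
  if (length(object@lambda) != 1 || object@lambda < 0)
    msg <- c(msg, "lambda must be a single value >= 0")
  if (is.null(msg)) TRUE else msg
})

#' AIFModel: arterial input function
#'
#' Either a parametric three-exponential bolus model (`feng3exp`) with
#' parameters `A1` (Bq/cc/s), `A2`, `A3` (Bq/cc), `l1 < l2 < l3 < 0` (1/s)
#' and delay `tau` (s), or a `sampled` curve interpolated linearly between
#' (time, activity) pairs.  Both evaluate to zero before the delay / first
#' sample.
#'
#' @slot form character(1), "feng3exp" or "sampled".
#' @slot params named numeric, feng3exp coefficients.
#' @slot times,values numeric, samples for the sampled form.
#' @exportClass AIFModel
setClass("AIFModel",
  representation(form = "character", params = "numeric",
                 times = "numeric", values = "numeric"))

setValidity("AIFModel", function(object) {
  if (!object@form %in% c("feng3exp", "sampled"))
    return(sprintf("unknown AIF form '%s'", object@form))
  if (object@form == "feng3exp") {
    need <- c("A1", "A2", "A3", "l1", "l2", "l3", "tau")
    if (!all(need %in% names(object@params)))
      return(paste("feng3exp requires params:", paste(need, collapse = ", ")))
  } else {
    if (length(object@times) != length(object@values) || length(object@times) < 2)
      return("sampled AIF needs >= 2 (time, value) pairs")
    if (is.unsorted(object@times, strictly = TRUE))
      return("sampled AIF times must be strictly increasing")
  }
  TRUE
})

#' KnotVector: a cubic B-spline knot sequence
#'
#' Full knot sequence (boundary multiplicities included), nondecreasing,
#' spanning the interval of interest.  `order` is the spline order
#' (4 = cubic).
#'
#' @slot knots numeric, nondecreasing knot positions (s).
#' @slot order integer(1), spline order.
#' @exportClass KnotVector
setClass("KnotVector",
  representation(knots = "numeric", order = "integer"))

setValidity("KnotVector", function(object) {
  msg <- NULL
  if (is.unsorted(object@knots)) msg <- c(msg, "knots must be nondecreasing")
  if (object@order < 1) msg <- c(msg, "order must be >= 1")
  if (length(object@knots) < 2 * object@order)
    msg <- c(msg, "need at least 2*order knots")
  if (is.null(msg)) TRUE else msg
})

#' BasisMatrix: frame-integrated temporal basis functions
#'
#' `B` holds the N_T x N_B matrix of per-frame integrals of the decayed
#' continuous-time basis functions B_k(t) exp(-lambda t); `curves` retains
#' the (un-decayed) continuous-time basis sampled on `timeGrid`, needed for
#' the curvature penalty and for predictions off the frame grid.
#'
#' @slot B matrix, N_T x N_B frame-integrated basis (column k = basis k).
#' @slot kind character(1), "spline", "spectral" or "spline_residue".
#' @slot timeGrid numeric, uniform sampling grid (s) for `curves`.
#' @slot curves matrix, length(timeGrid) x N_B continuous-time basis.
#' @slot knots ANY, KnotVector for spline-based kinds, else NULL.
#' @slot decays numeric, decay-constant grid (1/s) for the spectral kind.
#' @slot aifId character(1), identifier of the AIF used (or "" if none).
#' @slot schedule FrameSchedule the basis was integrated over.
#' @exportClass BasisMatrix
setClass("BasisMatrix",
  representation(B = "matrix", kind = "character", timeGrid = "numeric",
                 curves = "matrix", knots = "ANY", decays = "numeric",
                 aifId = "character", schedule = "FrameSchedule"))

setValidity("BasisMatrix", function(object) {
  msg <- NULL
  if (!object@kind %in% c("spline", "spectral", "spline_residue"))
    msg <- c(msg, sprintf("unknown basis kind '%s'", object@kind))
  if (!all(is.finite(object@B))) msg <- c(msg, "B must be finite")
  if (nrow(object@B) != length(object@schedule@start))
    msg <- c(msg, "nrow(B) must equal the number of frames")
  if (ncol(object@curves) != ncol(object@B))
    msg <- c(msg, "curves and B must have the same number of columns")
  if (is.null(msg)) TRUE else msg
})

#' KineticParams: compartment-model rate constants for one voxel or region
#'
#' Rate constants are stored in 1/s (`K1` is treated as 1/s internally;
#' strictly mL/cc/s with unit tissue density).  `Vb` is the dimensionless
#' fractional blood volume.  `k4`, `k5` are used only by the 3C5K model and
#' are zero otherwise.
#'
#' @slot K1,k2,k3,k4,k5 numeric(1), rate constants (1/s), all >= 0.
#' @slot Vb numeric(1), fractional blood volume in [0, 1].
#' @slot model character(1), "2C3K" or "3C5K".
#' @exportClass KineticParams
setClass("KineticParams",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                 k4 = "numeric", k5 = "numeric", Vb = "numeric",
                 model = "character"))

setValidity("KineticParams", function(object) {
  r <- c(object@K1, object@k2, object@k3, object@k4, object@k5)
  msg <- NULL
  if (any(r < 0)) msg <- c(msg, "rate constants must be >= 0")
  if (object@Vb < 0 || object@Vb > 1) msg <- c(msg, "Vb must lie in [0, 1]")
  if (!object@model %in% c("2C3K", "3C5K"))
    msg <- c(msg, "model must be '2C3K' or '3C5K'")
  if (is.null(msg)) TRUE else msg
})

#' ScannerGeometry: a 2D parallel-beam tomographic geometry
#'
#' @slot nAngles integer(1), number of projection angles over 180 degrees.
#' @slot nBins integer(1), number of radial bins per angle.
#' @slot binWidth numeric(1), radial bin width (mm).
#' @slot n integer(1), image grid is n x n voxels.
#' @slot voxelSize numeric(1), voxel edge length (mm).
#' @slot attenuation ANY, NULL or list(cx, cy, rx, ry, mu) describing a
#'   water-equivalent ellipse attenuation map (mm, 1/mm).
#' @exportClass ScannerGeometry
setClass("ScannerGeometry",
  representation(nAngles = "integer", nBins = "integer", binWidth = "numeric",
                 n = "integer", voxelSize = "numeric", attenuation = "ANY"))

setValidity("ScannerGeometry", function(object) {
  if (object@nAngles < 1 || object@nBins < 1 || object@n < 1)
    return("nAngles, nBins and n must be positive")
  if (object@binWidth <= 0 || object@voxelSize <= 0)
    return("binWidth and voxelSize must be positive")
  TRUE
})

#' Phantom: a digital dynamic phantom
#'
#' A label image on an n x n grid plus one TAC specification per nonzero
#' label.  A TAC spec is a list with `model` one of "2C3K", "3C5K", "aif"
#' (the blood region) or "tabulated" (with `times`/`values` in s and Bq/cc),
#' and `params` a [KineticParams-class] for the compartment kinds.
#'
#' @slot labels matrix, integer region ids (0 = background / air).
#' @slot regions named list of TAC specs; names are region names, and each
#'   spec carries its integer `label`.
#' @slot voxelSize numeric(1), voxel edge length (mm).
#' @slot aif AIFModel, the ground-truth arterial input function.
#' @slot kind character(1), "simplified" or "realistic_like".
#' @exportClass Phantom
setClass("Phantom",
  representation(labels = "matrix", regions = "list", voxelSize = "numeric",
                 aif = "AIFModel", kind = "character"))

setValidity("Phantom", function(object) {
  lab <- sort(unique(as.vector(object@labels)))
  lab <- lab[lab != 0]
  have <- vapply(object@regions, function(r) r$label, numeric(1))
  if (!all(lab %in% have))
    return(sprintf("labels without a TAC spec: %s",
                   paste(setdiff(lab, have), collapse = ", ")))
  TRUE
})

#' SinogramSeries: dynamic sinogram data
#'
#' Measured (or expected) counts per detector bin and time frame, plus the
#' known background term (scattered photons and random coincidences) and the
#' geometry and schedule they refer to.
#'
#' @slot y matrix, N_D x N_T counts.
#' @slot eps matrix, N_D x N_T background expectation (counts).
#' @slot geometry ScannerGeometry.
#' @slot schedule FrameSchedule.
#' @slot seed integer(1), RNG seed of the realization (NA for expected data).
#' @exportClass SinogramSeries
setClass("SinogramSeries",
  representation(y = "matrix", eps = "matrix", geometry = "ScannerGeometry",
                 schedule = "FrameSchedule", seed = "integer"))

setValidity("SinogramSeries", function(object) {
  msg <- NULL
  if (!all(dim(object@y) == dim(object@eps)))
    msg <- c(msg, "y and eps must have identical dimensions")
  if (any(object@y < 0) || any(object@eps < 0))
    msg <- c(msg, "counts and background must be >= 0")
  if (ncol(object@y) != length(object@schedule@start))
    msg <- c(msg, "ncol(y) must equal the number of frames")
  if (nrow(object@y) != object@geometry@nAngles * object@geometry@nBins)
    msg <- c(msg, "nrow(y) must equal nAngles * nBins")
  if (is.null(msg)) TRUE else msg
})

#' ImageSeries: a dynamic image sequence
#'
#' Voxel activity concentrations (Bq/cc, frame averages of the decayed TAC)
#' as an N_V x N_T matrix over an n x n grid.
#'
#' @slot values matrix, N_V x N_T activity (Bq/cc).
#' @slot n integer(1), image grid side.
#' @slot voxelSize numeric(1), voxel edge length (mm).
#' @slot schedule FrameSchedule.
#' @exportClass ImageSeries
setClass("ImageSeries",
  representation(values = "matrix", n = "integer", voxelSize = "numeric",
                 schedule = "FrameSchedule"))

setValidity("ImageSeries", function(object) {
  msg <- NULL
  if (nrow(object@values) != object@n^2)
    msg <- c(msg, "nrow(values) must equal n^2")
  if (ncol(object@values) != length(object@schedule@start))
    msg <- c(msg, "ncol(values) must equal the number of frames")
  if (is.null(msg)) TRUE else msg
})

#' ReconResult: output of a (nested-)MAP reconstruction
#'
#' @slot images ImageSeries, the final reconstructed image sequence (for
#'   nested reconstructions: the model-predicted images).
#' @slot theta matrix, N_V x N_B temporal-model coefficients (linear models),
#'   or N_V x 4 (K1, k2, k3, Vb) for the 2C3K model; 0 columns for plain MAP.
#' @slot gammaSel numeric, per-voxel selected temporal weight (length 0 when
#'   no temporal penalty was used).
#' @slot objective numeric, per-iteration Poisson log-likelihood (Eq with the
#'   constant omitted) minus the spatial penalty.
#' @slot tmse numeric, per-iteration TMSE trace (length 0 unless ground truth
#'   was supplied).
#' @slot iterates list, optional per-iteration image matrices.
#' @slot config list, the reconstruction configuration used.
#' @slot algorithm character(1), "map" or "nested".
#' @exportClass ReconResult
setClass("ReconResult",
  representation(images = "ImageSeries", theta = "matrix",
                 gammaSel = "numeric", objective = "numeric",
                 tmse = "numeric", iterates = "list", config = "list",
                 algorithm = "character"))
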