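## TAC fit weighting, model-selection diagnostics, and the image /
## parametric-map bias and noise metrics.

#' Per-frame weighted least squares weights for TAC fitting
#'
#' \eqn{w_m = \Delta T_m e^{-\lambda T_m} / a_m} with \eqn{T_m} the frame
#' midpoint and \eqn{a_m} the decay-corrected average activity in the
#' frame: longer frames and higher count levels carry more weight.
#'
#' @param sched a [FrameSchedule-class].
#' @param a per-frame decay-corrected average activity (floored at a small
#'   positive fraction of its maximum where nonpositive).
#' @return per-frame weights.
#' @export
tacFitWeights <- function(sched, a) {
  stopifnot(length(a) == nFrames(sched))
  floorA <- max(a) * 1e-6
  if (floorA <= 0) floorA <- 1
  dur <- frameDurations(sched)
  mid <- frameMidpoints(sched)
  dur * exp(-decayConstant(sched) * mid) / pmax(a, floorA)
}

## exact run-count distribution: P(R = r) given n1, n2 positives/negatives
runsPMF <- function(n1, n2) {
  rmax <- 2 * min(n1, n2) + (n1 != n2)
  r <- 2:rmax
  p <- vapply(r, function(ri) {
    if (ri %% 2 == 0) {
      k <- ri / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (ri - 1) / 2
      choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
        choose(n1 - 1, k - 1) * choose(n2 - 1, k)
    }
  }, numeric(1))
  p <- p / choose(n1 + n2, n1)
  names(p) <- r
  p
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Two-sided test for serial structure in the signs of (weighted) fit
#' residuals: too few runs indicate systematic misfit, too many indicate
#' alternation.  Zero residuals count as positive.  The exact run-count
#' distribution is used for small samples (n <= 20), the normal
#' approximation otherwise.
#'
#' @param residuals residual vector.
#' @param alpha significance level (default 0.05).
#' @return list with `pass` (TRUE if no significant structure), `p`,
#'   `runs`, `n1`, `n2`.
#' @export
runsTest <- function(residuals, alpha = 0.05) {
  sgn <- residuals >= 0
  n1 <- sum(sgn); n2 <- sum(!sgn)
  runs <- 1 + sum(sgn[-1] != sgn[-length(sgn)])
  if (n1 == 0 || n2 == 0)
    return(list(pass = FALSE, p = 0, runs = runs, n1 = n1, n2 = n2))
  n <- n1 + n2
  if (n > 20) {
    mu <- 2 * n1 * n2 / n + 1
    s2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    z <- (runs - mu) / sqrt(s2)
    p <- 2 * pnorm(-abs(z))
  } else {
    pmf <- runsPMF(n1, n2)
    rv <- as.integer(names(pmf))
    pLow <- sum(pmf[rv <= runs])
    pHigh <- sum(pmf[rv >= runs])
    p <- min(1, 2 * min(pLow, pHigh))
  }
  list(pass = p >= alpha, p = p, runs = runs, n1 = n1, n2 = n2)
}

#' Leave-one-out cross-validated weighted residual sum of squares
#'
#' Refits the model with each frame held out in turn and accumulates
#' \eqn{\sum_m w_m (a_m - f_{-m}(T_m))^2} over the held-out predictions.
#'
#' @param fitter function(values, weights, holdOut) returning the predicted
#'   full-length TAC of a model fitted without frame `holdOut`.
#' @param tac per-frame TAC values.
#' @param weights per-frame weights.
#' @return the LOO-CV weighted RSS; folds whose fit fails (error or NA
#'   prediction) are flagged via a warning and skipped.
#' @export
looCvRss <- function(fitter, tac, weights) {
  stopifnot(length(tac) == length(weights))
  total <- 0
  failed <- integer(0)
  for (m in seq_along(tac)) {
    pred <- tryCatch(fitter(tac, weights, m), error = function(e) NULL)
    if (is.null(pred) || !is.finite(pred[m])) { failed <- c(failed, m); next }
    total <- total + weights[m] * (tac[m] - pred[m])^2
  }
  if (length(failed))
    warning("LOO folds failed and were skipped: ",
            paste(failed, collapse = ", "))
  total
}

stackArray <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) return(stack)
  vals <- lapply(stack, function(s) if (is(s, "ImageSeries")) s@values else s)
  array(unlist(vals), dim = c(dim(vals[[1]]), length(vals)))
}

#' Time-weighted absolute image bias per voxel
#'
#' \eqn{[ImageBias]_j = \frac{1}{T_{scan}} \sum_m \Delta T_m
#' |\bar a_{jm} - a^{true}_{jm}|} with \eqn{\bar a} the across-realization
#' mean image; \eqn{T_{scan} = \sum_m \Delta T_m} (acquisition time).
#'
#' @param stack realizations: a list of [ImageSeries-class]/matrices, or an
#'   N_V x N_T x R array.
#' @param truth ground-truth [ImageSeries-class] or matrix.
#' @param sched a [FrameSchedule-class] (taken from `truth` if available).
#' @return per-voxel bias vector (activity units).
#' @export
imageBias <- function(stack, truth, sched = NULL) {
  if (is(truth, "ImageSeries")) { sched <- truth@schedule; truth <- truth@values }
  arr <- stackArray(stack)
  abar <- apply(arr, c(1, 2), mean)
  dur <- frameDurations(sched)
  as.numeric(abs(abar - truth) %*% dur / sum(dur))
}

#' Weighted image noise per voxel
#'
#' Per voxel-frame weighted standard deviation
#' \eqn{\sigma_{w,jm} = (\sigma^2_{jm} \Delta T_m / a^{true}_{jm})^{1/2}}
#' (sample variance over realizations, n-1 convention), averaged over
#' frames:
#' \eqn{\sigma_{w,j} = \frac{1}{N_T}\sum_m \sigma_{w,jm}}.  The printed
#' weighting multiplies by \eqn{\Delta T_m / a^{true}}; `orientation =
#' "reciprocal"` divides instead (the form the underlying dynamic-PET noise
#' model suggests).  Voxel-frames with zero true activity are excluded from
#' the frame average.
#'
#' @inheritParams imageBias
#' @param orientation "printed" (default) or "reciprocal".
#' @return per-voxel average weighted SD.
#' @export
imageNoise <- function(stack, truth, sched = NULL,
                       orientation = c("printed", "reciprocal")) {
  orientation <- match.arg(orientation)
  if (is(truth, "ImageSeries")) { sched <- truth@schedule; truth <- truth@values }
  arr <- stackArray(stack)
  stopifnot(dim(arr)[3] >= 2)
  v <- apply(arr, c(1, 2), var)
  dur <- rep(frameDurations(sched), each = nrow(truth))
  w <- if (orientation == "printed") dur / truth else truth / dur
  sw <- sqrt(v * w)
  sw[truth <= 0] <- NA
  rowMeans(sw, na.rm = TRUE)
}

#' Region summary of a per-voxel metric, normalized to ground truth
#'
#' Mean of the per-voxel values over a mask, expressed as a percentage of
#' the mean ground-truth activity over the same mask and all frames.
#'
#' @param perVoxel per-voxel metric (activity units).
#' @param mask voxel indices.
#' @param truth ground-truth [ImageSeries-class] or matrix.
#' @return percentage value.
#' @export
regionSummary <- function(perVoxel, mask, truth) {
  if (is(truth, "ImageSeries")) truth <- truth@values
  ref <- mean(truth[mask, ])
  100 * mean(perVoxel[mask], na.rm = TRUE) / ref
}

## restrict an image stack + truth + schedule to frames fully inside
## [0, tmax] (measured from scan start)
restrictToWindow <- function(sched, tmax) which(sched@end <= tmax + 1e-9)

#' TMSE convergence trace
#'
#' At each iteration n,
#' \eqn{TMSE^n = \sum_j \sum_m \Delta T_m MSE^n_{jm} / a^{true}_{jm}}
#' with \eqn{MSE^n_{jm}} the mean squared error over realizations, plus the
#' fractional changes \eqn{(TMSE^n - TMSE^{n+1}) / TMSE^n} and, when the
#' trace covers both, the iteration 30 to 40 change
#' \eqn{(TMSE^{30} - TMSE^{40}) / TMSE^{30}}.
#'
#' @param iterStacks list over iterations; element n is a list over
#'   realizations of N_V x N_T activity matrices (or a 3D array).
#' @param truth ground-truth [ImageSeries-class] or matrix.
#' @param sched a [FrameSchedule-class] (taken from `truth` if available).
#' @return list with `tmse`, `fractionalChange`, and `change30to40` (NA if
#'   the trace is shorter than 40 iterations).
#' @export
tmseTrace <- function(iterStacks, truth, sched = NULL) {
  if (is(truth, "ImageSeries")) { sched <- truth@schedule; truth <- truth@values }
  dur <- frameDurations(sched)
  ok <- truth > 0
  tm <- vapply(iterStacks, function(stack) {
    arr <- stackArray(stack)
    mse <- matrix(0, dim(arr)[1], dim(arr)[2])
    for (r in seq_len(dim(arr)[3])) mse <- mse + (arr[, , r] - truth)^2
    mse <- mse / dim(arr)[3]
    sum((sweep(mse, 2, dur, "*") / truth)[ok])
  }, numeric(1))
  fc <- if (length(tm) > 1) (head(tm, -1) - tail(tm, -1)) / head(tm, -1)
        else numeric(0)
  ch <- if (length(tm) >= 40) (tm[30] - tm[40]) / tm[30] else NA_real_
  list(tmse = tm, fractionalChange = fc, change30to40 = ch)
}

#' Voxel-by-voxel 2C3K parametric map of a reconstructed image sequence
#'
#' Fits the irreversible two-tissue model to every voxel TAC within a mask
#' (profiled weighted least squares over alpha = k2 + k3; weights from
#' [tacFitWeights()] on the voxel's own TAC) and appends the flux constant.
#'
#' @param images an [ImageSeries-class] (one realization).
#' @param aif the arterial input function used for the fits.
#' @param mask voxel indices to fit.
#' @param design optional precomputed [tcmDesign()] (in activity
#'   frame-average units) to share across realizations.
#' @param alphaGrid profile grid for k2 + k3 (1/s).
#' @param refine zoom rounds refining alpha beyond the grid (default 3,
#'   resolving k2 + k3 to well under 1 percent).
#' @return matrix (length(mask) x 5) with columns K1, k2, k3, Vb, kflux
#'   (1/s and dimensionless), rownames the voxel indices.
#' @export
parametricMap <- function(images, aif, mask, design = NULL,
                          alphaGrid = defaultAlphaGrid(), refine = 3L) {
  sched <- images@schedule
  if (is.null(design)) design <- tcmDesign(aif, sched, alphaGrid)
  A <- images@values[mask, , drop = FALSE]
  A <- pmax(A, 0)
  W <- t(apply(A, 1, function(a) tacFitWeights(sched, a)))
  fit <- fit2C3KBatch(A, W, design, refine = refine)
  out <- cbind(fit$params, kflux = kineticFlux(fit$params))
  rownames(out) <- mask
  out
}

#' Bias and noise of parametric maps over realizations
#'
#' Per-voxel signed bias \eqn{\bar q_j - q^{true}_j} and standard deviation
#' \eqn{\sigma_{qj}} (n-1 convention) of each kinetic parameter over
#' realizations, with region means.  Normalized summaries are expressed as
#' percentages of the mean ground-truth kflux (or of the corresponding
#' parameter's ground-truth mean).
#'
#' @param maps list over realizations of [parametricMap()] matrices (same
#'   mask).
#' @param truthParams matrix with the same columns giving ground-truth
#'   parameter values per masked voxel.
#' @return list with `bias` and `sd` matrices (voxel x parameter),
#'   `meanBias`, `meanAbsBias`, `meanSd` (per parameter), and
#'   `normalized`: mean signed bias and SD as percentages of the mean
#'   ground-truth value of each parameter.
#' @export
parameterBiasNoise <- function(maps, truthParams) {
  arr <- array(unlist(maps), dim = c(dim(maps[[1]]), length(maps)))
  qbar <- apply(arr, c(1, 2), mean)
  qsd <- if (dim(arr)[3] >= 2) apply(arr, c(1, 2), sd) else qbar * NA
  bias <- qbar - truthParams
  colnames(bias) <- colnames(truthParams)
  colnames(qsd) <- colnames(truthParams)
  ref <- colMeans(truthParams)
  list(bias = bias, sd = qsd,
       meanBias = colMeans(bias),
       meanAbsBias = colMeans(abs(bias)),
       meanSd = colMeans(qsd),
       normalized = list(bias = 100 * colMeans(bias) / ref,
                         sd = 100 * colMeans(qsd) / ref))
}
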