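## Frame integration, convolution and basis-matrix construction.

#' Integrate a temporal function over every frame of a schedule
#'
#' Computes \eqn{\int_{t_{ms}}^{t_{mf}} f(t) e^{-\lambda t} dt} for every
#' frame m by adaptive quadrature -- the frame-integration that turns a
#' continuous-time basis function or TAC into its per-frame measurement
#' contribution.  Units are Bq s/cc when `f` is an activity concentration.
#'
#' @param f a function of time (s), vectorized.
#' @param sched a [FrameSchedule-class] (supplies the decay constant).
#' @param lambda decay constant override (1/s); default the schedule's.
#' @param rel.tol quadrature relative tolerance.
#' @return numeric vector of length `nFrames(sched)`.
#' @export
frameIntegrate <- function(f, sched, lambda = decayConstant(sched),
                           rel.tol = 1e-9) {
  vapply(seq_along(sched@start), function(m) {
    r <- tryCatch(
      integrate(function(t) f(t) * exp(-lambda * t),
                sched@start[m], sched@end[m],
                rel.tol = rel.tol, subdivisions = 500L),
      error = function(e)
        stop(sprintf("quadrature failed on frame %d: %s", m, conditionMessage(e))))
    r$value
  }, numeric(1))
}

## Frame integration of a curve sampled on a uniform grid (trapezoidal).
## Frame boundaries need not sit on grid points; endpoint values are
## linearly interpolated.  When all boundaries sit on grid points a sparse
## per-frame weight matrix is used (and cached on the schedule's digest),
## so that integrating many curves is a single matrix product.
frameIntegrateGrid <- function(values, grid, sched,
                               lambda = decayConstant(sched)) {
  W <- frameWeightMatrix(grid, sched)
  y <- values * exp(-lambda * grid)
  if (!is.null(W)) return(as.numeric(W %*% y))
  vapply(seq_along(sched@start), function(m) {
    trapzSection(grid, y, sched@start[m], sched@end[m])
  }, numeric(1))
}

## matrix version: columns of `curves` integrated at once
frameIntegrateGridMat <- function(curves, grid, sched,
                                  lambda = decayConstant(sched)) {
  W <- frameWeightMatrix(grid, sched)
  y <- curves * exp(-lambda * grid)
  if (!is.null(W)) return(as.matrix(W %*% y))
  apply(y, 2, function(col)
    vapply(seq_along(sched@start), function(m)
      trapzSection(grid, col, sched@start[m], sched@end[m]), numeric(1)))
}

.frameWeightCache <- new.env(parent = emptyenv())

## sparse trapezoid weight matrix (frames x grid), or NULL when frame
## boundaries do not sit on grid points
frameWeightMatrix <- function(grid, sched) {
  dt <- grid[2] - grid[1]
  si <- (sched@start - grid[1]) / dt
  ei <- (sched@end - grid[1]) / dt
  if (max(abs(si - round(si)), abs(ei - round(ei))) > 1e-9) return(NULL)
  key <- paste(length(grid), dt, paste(sched@start, collapse = ","),
               paste(sched@end, collapse = ","), sep = "|")
  hit <- .frameWeightCache[[key]]
  if (!is.null(hit)) return(hit)
  si <- round(si) + 1L; ei <- round(ei) + 1L
  ii <- jj <- xx <- list()
  for (m in seq_along(si)) {
    idx <- si[m]:ei[m]
    w <- rep(dt, length(idx)); w[c(1, length(w))] <- dt / 2
    ii[[m]] <- rep.int(m, length(idx)); jj[[m]] <- idx; xx[[m]] <- w
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(si), length(grid)))
  .frameWeightCache[[key]] <- W
  W
}

trapzSection <- function(x, y, a, b) {
  ya <- approx(x, y, xout = a, rule = 2)$y
  yb <- approx(x, y, xout = b, rule = 2)$y
  keep <- x > a & x < b
  xx <- c(a, x[keep], b)
  yy <- c(ya, y[keep], yb)
  sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
}

## Causal convolution of two curves sampled on the same uniform grid,
## trapezoidal weights, returned on that grid.
convolveGrid <- function(f, g, dt) {
  n <- length(f)
  stopifnot(length(g) == n)
  z <- convolve(f, rev(g), type = "open")[seq_len(n)]
  dt * (z - 0.5 * f[1] * g - 0.5 * f * g[1])
}

## Exact convolution of a feng3exp AIF with exp(-alpha t) (alpha >= 0;
## alpha = 0 gives the running integral of the AIF).  The AIF is a sum of
## (a + b u) exp(l u) terms in u = t - tau, so the convolution is closed
## form; used for the spectral basis and compartment-model TACs.
expConvAIF <- function(aif, alpha, t) {
  stopifnot(aif@form == "feng3exp")
  p <- aif@params
  u <- t - p[["tau"]]
  out <- numeric(length(t))
  pos <- u > 0
  if (!any(pos)) return(out)
  uu <- u[pos]
  acc <- numeric(length(uu))
  ## term (a + b*u) e^{l u}: contribution
  ##   int_0^u (a + b v) e^{l v} e^{-alpha (u - v)} dv
  term <- function(a, b, l) {
    s <- l + alpha
    if (abs(s) > 1e-12) {
      e1 <- (exp(l * uu) - exp(-alpha * uu)) / s
      i1 <- a * e1
      i2 <- b * (uu * exp(l * uu) / s - (exp(l * uu) - exp(-alpha * uu)) / s^2)
    } else {
      i1 <- a * uu * exp(l * uu)
      i2 <- b * uu^2 / 2 * exp(l * uu)
    }
    i1 + i2
  }
  acc <- acc +
    term(-(p[["A2"]] + p[["A3"]]), p[["A1"]], p[["l1"]]) +
    term(p[["A2"]], 0, p[["l2"]]) +
    term(p[["A3"]], 0, p[["l3"]])
  out[pos] <- acc
  out
}

## AIF convolved with exp(-alpha t): exact for feng3exp, grid convolution
## for sampled AIFs.
aifConvExp <- function(aif, alpha, grid) {
  if (aif@form == "feng3exp") {
    expConvAIF(aif, alpha, grid)
  } else {
    ci <- evalAIF(aif, grid)
    convolveGrid(ci, exp(-alpha * grid), grid[2] - grid[1])
  }
}

#' Build a frame-integrated temporal basis matrix
#'
#' Constructs the N_T x N_B matrix of per-frame integrals (with physical
#' decay) of the chosen temporal basis family:
#' \describe{
#'   \item{spline}{cubic B-splines on the supplied knots.}
#'   \item{spectral}{a blood column (the AIF itself) followed by the AIF
#'     convolved with exponential decays over a log-spaced grid of decay
#'     constants (default 100 values from 1.1e-4 to 0.01 1/s).}
#'   \item{spline_residue}{column 1 is the frame-integrated AIF (the blood /
#'     delta-residue term); columns l >= 2 are the AIF convolved with the
#'     cubic B-splines of the residue function.}
#' }
#'
#' @param kind "spline", "spectral" or "spline_residue".
#' @param sched a [FrameSchedule-class].
#' @param aif an [AIFModel-class]; required for the convolved kinds.
#' @param knots a [KnotVector-class]; required for the spline kinds.  For
#'   `spline_residue` the default is [splineResidueKnots()] with the rise
#'   point at the AIF delay.
#' @param decays decay-constant grid (1/s) for the spectral kind.
#' @param dt convolution grid spacing (s).
#' @return a [BasisMatrix-class].
#' @examples
#' fs <- defaultFrameSchedule(lateFrames = FALSE)
#' b <- buildBasis("spline_residue", fs, aif = defaultAIF())
#' dim(basisValues(b))
#' @export
buildBasis <- function(kind = c("spline", "spectral", "spline_residue"),
                       sched, aif = NULL, knots = NULL,
                       decays = defaultSpectralGrid(), dt = 1) {
  kind <- match.arg(kind)
  grid <- timeGridFor(sched, dt)
  lam <- decayConstant(sched)
  if (kind %in% c("spectral", "spline_residue") && is.null(aif))
    stop("basis kind '", kind, "' requires an AIF")
  if (kind == "spline") {
    if (is.null(knots)) stop("spline basis requires a knot vector")
    curves <- bsplineEval(knots, grid, outside = "zero")
    B <- frameIntegrateGridMat(curves, grid, sched)
    return(new("BasisMatrix", B = B, kind = kind, timeGrid = grid,
               curves = curves, knots = knots, decays = numeric(),
               aifId = "", schedule = sched))
  }
  if (kind == "spectral") {
    curves <- cbind(evalAIF(aif, grid),
                    vapply(decays, function(a) aifConvExp(aif, a, grid),
                           numeric(length(grid))))
    colnames(curves) <- c("blood", paste0("b", seq_along(decays)))
  } else {                                # spline_residue
    if (is.null(knots)) {
      rise <- if (aif@form == "feng3exp") aif@params[["tau"]] else sched@tInj
      knots <- splineResidueKnots(sched = sched, risePoint = max(rise, 1))
    }
    zeta <- bsplineEval(knots, grid, outside = "zero")
    ci <- evalAIF(aif, grid)
    conv <- apply(zeta, 2, function(z) convolveGrid(ci, z, dt))
    curves <- cbind(ci, conv)
    colnames(curves) <- c("blood", paste0("s", seq_len(ncol(zeta))))
  }
  if (kind == "spectral" && aif@form == "feng3exp") {
    ## exact frame integration for the closed-form columns
    B <- cbind(
      frameIntegrate(function(t) evalAIF(aif, t), sched),
      vapply(decays, function(a)
        frameIntegrate(function(t) expConvAIF(aif, a, t), sched),
        numeric(nFrames(sched))))
  } else {
    B <- frameIntegrateGridMat(curves, grid, sched)
    if (aif@form == "feng3exp")   # blood column exact even for spline_residue
      B[, 1] <- frameIntegrate(function(t) evalAIF(aif, t), sched)
  }
  colnames(B) <- colnames(curves)
  new("BasisMatrix", B = B, kind = kind, timeGrid = grid, curves = curves,
      knots = if (kind == "spline_residue") knots else NULL,
      decays = if (kind == "spectral") decays else numeric(),
      aifId = aif@form, schedule = sched)
}

#' @describeIn buildBasis the default spectral decay-constant grid: 100
#'   values log-spaced between 1.1e-4 1/s (the physical decay constant of
#'   fluorine-18) and 0.01 1/s.
#' @param nDecays number of spectral decay constants.
#' @param range numeric(2), slowest and fastest decay constant (1/s).
#' @export
defaultSpectralGrid <- function(nDecays = 100L, range = c(1.1e-4, 0.01)) {
  exp(seq(log(range[1]), log(range[2]), length.out = nDecays))
}
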