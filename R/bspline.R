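#' Construct a cubic B-spline knot vector
#'
#' Builds the full knot sequence from interior knots and a span, repeating
#' the boundary knots `order` times so that the basis interpolates at the
#' endpoints.
#'
#' @param interior interior knot positions (s), may be empty; values may be
#'   repeated to lower continuity locally.
#' @param range numeric(2), the spanned interval (s).
#' @param order spline order (4 = cubic).
#' @return a [KnotVector-class].
#' @examples
#' kv <- knotVector(c(10, 20), c(0, 30))
#' bsplineEval(kv, 15)
#' @export
knotVector <- function(interior, range, order = 4L) {
  interior <- sort(as.numeric(interior))
  if (length(interior) && (any(interior <= range[1]) || any(interior >= range[2])))
    stop("interior knots must lie strictly inside the range")
  new("KnotVector",
      knots = c(rep(range[1], order), interior, rep(range[2], order)),
      order = as.integer(order))
}

nBasis <- function(kv) length(kv@knots) - kv@order

knotRange <- function(kv) {
  c(kv@knots[kv@order], kv@knots[length(kv@knots) - kv@order + 1])
}

#' Evaluate B-spline basis functions
#'
#' Cox-de Boor B-spline basis values (or derivatives) at the requested
#' times, one column per basis function.
#'
#' @param kv a [KnotVector-class].
#' @param t evaluation times (s).
#' @param derivs derivative order (0 = values, 2 = curvature).
#' @param outside "error" to reject times outside the knot span, "zero" to
#'   return zero rows there.
#' @return a length(t) x N_S matrix; basis values are >= 0 and sum to 1 at
#'   every interior time.
#' @export
bsplineEval <- function(kv, t, derivs = 0L, outside = c("error", "zero")) {
  outside <- match.arg(outside)
  rng <- knotRange(kv)
  inside <- t >= rng[1] & t <= rng[2]
  if (!all(inside) && outside == "error")
    stop("evaluation times outside the knot span")
  out <- matrix(0, length(t), nBasis(kv))
  if (any(inside)) {
    out[inside, ] <- splines::splineDesign(
      kv@knots, t[inside], ord = kv@order,
      derivs = rep(as.integer(derivs), sum(inside)))
  }
  out
}

## Pilot fit of a frame-sampled TAC: GCV-smoothed cubic smoothing spline
## through the frame-midpoint values, evaluated wherever needed.  Raw
## finite differences of noisy TACs are unusable for derivative-based knot
## placement; the pilot supplies a smooth stand-in.
pilotFit <- function(tac, sched) {
  mid <- frameMidpoints(sched)
  stopifnot(length(tac) == length(mid))
  if (length(unique(round(tac, 12))) == 1) {
    f <- function(t) rep(tac[1], length(t))
    return(f)
  }
  fit <- tryCatch(smooth.spline(mid, tac, cv = FALSE),  # GCV smoothing
                  error = function(e) NULL)
  if (is.null(fit)) {
    ## GCV's internal spar search can fail on strongly nonuniform
    ## midpoints (bolus-shaped TACs); score a df grid by GCV instead
    n <- length(mid)
    best <- NULL
    for (df in unique(pmin(seq(4, n - 1, by = 2), n - 1))) {
      cand <- tryCatch(smooth.spline(mid, tac, df = df),
                       error = function(e) NULL)
      if (is.null(cand)) next
      rss <- sum((tac - predict(cand, mid)$y)^2)
      sc <- rss / (1 - cand$df / n)^2
      if (is.null(best) || sc < best$sc) best <- list(sc = sc, fit = cand)
    }
    fit <- best$fit
  }
  if (is.null(fit)) {
    f <- splinefun(mid, tac, method = "natural")
    return(function(t) f(t))
  }
  function(t) as.numeric(predict(fit, t)$y)
}

#' Adaptive placement of free knots along a time-activity curve
#'
#' Places `nFree` interior knots so that the cumulative integral of the 4th
#' root of the absolute 4th derivative of (a smooth pilot fit of) the TAC is
#' divided into equal segments -- the knot-density rule that is
#' asymptotically optimal for cubic-spline approximation.  The 4th
#' derivative of the pilot fit is estimated by wide-stencil central
#' differences on a coarse uniform grid.
#'
#' @param tac per-frame TAC values (one per frame of `sched`).
#' @param sched a [FrameSchedule-class].
#' @param nFree number of interior knots (default 11).
#' @param gridSize fine-grid resolution for integrating the placement
#'   density.
#' @return a [KnotVector-class] with `nFree` interior knots on
#'   `[0, T_scan]`; degenerate TACs (vanishing 4th derivative) fall back to
#'   uniform spacing.
#' @export
adaptiveKnots <- function(tac, sched, nFree = 11L, gridSize = 2001L) {
  stopifnot(nFree >= 1)
  tmax <- max(sched@end)
  mid <- frameMidpoints(sched)
  uniform <- function() {
    interior <- seq(0, tmax, length.out = nFree + 2)[2:(nFree + 1)]
    knotVector(interior, c(0, tmax))
  }
  if (length(mid) < 5) return(uniform())
  f <- pilotFit(tac, sched)
  y <- f(mid)
  ## 4th derivative via 4th-order divided differences of the pilot over
  ## sliding 5-point windows of the (nonuniform) frame midpoints:
  ## f[x_i..x_{i+4}] * 4! estimates f'''' at the window centre, exactly so
  ## for polynomial TACs.
  nw <- length(mid) - 4
  d4 <- numeric(nw); ctr <- numeric(nw)
  for (i in seq_len(nw)) {
    xs <- mid[i:(i + 4)]; ys <- y[i:(i + 4)]
    dd <- sum(vapply(1:5, function(k)
      ys[k] / prod(xs[k] - xs[-k]), numeric(1)))
    d4[i] <- 24 * dd
    ctr[i] <- mean(xs)
  }
  span <- tmax
  if (max(abs(d4)) * span^4 / max(max(abs(y)), 1e-300) < 1e-5)
    return(uniform())                     # degenerate: no usable curvature
  dens <- abs(d4)^(1 / 4)
  ## TACs are not C^4 at the tracer-arrival kink, where the placement
  ## density degenerates toward a point mass; winsorizing keeps the rise
  ## cluster while guaranteeing knots for the rest of the curve
  cap <- quantile(dens, 0.98, names = FALSE)
  if (cap > 0) dens <- pmin(dens, cap)
  tt <- seq(0, tmax, length.out = gridSize)
  dv <- approx(ctr, dens, xout = tt, rule = 2)$y
  ## linear (clamped) extrapolation of the density beyond the window
  ## centres; constant extrapolation biases the edge knots inward
  if (nw >= 2) {
    sl <- (dens[2] - dens[1]) / (ctr[2] - ctr[1])
    left <- tt < ctr[1]
    dv[left] <- pmax(0, dens[1] + (tt[left] - ctr[1]) * sl)
    sr <- (dens[nw] - dens[nw - 1]) / (ctr[nw] - ctr[nw - 1])
    right <- tt > ctr[nw]
    dv[right] <- pmax(0, dens[nw] + (tt[right] - ctr[nw]) * sr)
  }
  cum <- c(0, cumsum((dv[-1] + dv[-length(dv)]) / 2 * diff(tt)))
  if (cum[length(cum)] <= 0) return(uniform())
  cum <- cum / cum[length(cum)]
  targets <- seq_len(nFree) / (nFree + 1)
  interior <- approx(cum, tt, xout = targets, ties = "ordered")$y
  interior <- sort(pmin(pmax(interior, tmax * 1e-9), tmax * (1 - 1e-9)))
  knotVector(interior, c(0, tmax))
}

## First time the pilot-fit TAC exceeds 5% of its maximum; NA if never.
detectRise <- function(tac, sched, frac = 0.05) {
  f <- pilotFit(tac, sched)
  tmax <- max(sched@end)
  tt <- seq(0, tmax, length.out = 2001)
  y <- f(tt)
  if (max(y) <= 0) return(NA_real_)
  above <- which(y > frac * max(y))
  if (!length(above)) return(NA_real_)
  tt[above[1]]
}

#' Knot placement for the spline-residue model
#'
#' Places knots of multiplicity 4 at the start of the scan, at the point
#' where the TAC starts to rise, and at the end of the scan (handling the
#' discontinuities of the residue function at those points), plus 6
#' uniformly spaced knots between the rise point and the scan end.
#'
#' @param tac per-frame TAC values; used only to detect the rise point.
#' @param sched a [FrameSchedule-class].
#' @param nUniform number of uniform knots after the rise point (default 6).
#' @param risePoint optional explicit rise time (s); when NULL it is
#'   detected as the first time the pilot-fit TAC exceeds 5% of its maximum,
#'   defaulting to the injection time if undetectable.
#' @return a [KnotVector-class].
#' @export
splineResidueKnots <- function(tac = NULL, sched, nUniform = 6L,
                               risePoint = NULL) {
  tmax <- max(sched@end)
  if (is.null(risePoint)) {
    risePoint <- if (is.null(tac)) NA_real_ else detectRise(tac, sched)
    ## undetectable (never rises, or apparent rise at the very boundary):
    ## fall back to the injection time
    if (is.na(risePoint) || risePoint <= 0 || risePoint >= tmax)
      risePoint <- sched@tInj
  }
  if (risePoint <= 0 || risePoint >= tmax)
    stop("rise point must lie strictly inside the scan")
  uni <- risePoint + seq_len(nUniform) * (tmax - risePoint) / (nUniform + 1)
  interior <- c(rep(risePoint, 4), uni)
  knotVector(interior, c(0, tmax))
}
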