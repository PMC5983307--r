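## Irreversible compartment models (2C3K, 3C5K) and their fitting.

#' Construct kinetic parameters
#'
#' @param K1,k2,k3 rate constants (1/s).
#' @param k4,k5 additional 3C5K rate constants (1/s), 0 for 2C3K.
#' @param Vb fractional blood volume in [0, 1].
#' @param model "2C3K" or "3C5K".
#' @return a [KineticParams-class].
#' @examples
#' kineticParams(0.2 / 60, 0.3 / 60, 0.1 / 60, Vb = 0.05)
#' @export
kineticParams <- function(K1, k2, k3, k4 = 0, k5 = 0, Vb = 0,
                          model = if (k4 > 0 || k5 > 0) "3C5K" else "2C3K") {
  new("KineticParams", K1 = K1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
      Vb = Vb, model = model)
}

#' Net trapping (flux) rate constant
#'
#' The macro-parameter of irreversible uptake,
#' \eqn{k_{flux} = K_1 k_3 / (k_2 + k_3)}.
#'
#' @param params a [KineticParams-class], or a numeric vector/matrix with
#'   elements (columns) K1, k2, k3.
#' @return the flux constant (1/s); 0 when `K1 * k3` is 0 even if
#'   `k2 + k3` is 0 (a voxel with no uptake), otherwise an error in that
#'   degenerate case.
#' @export
kineticFlux <- function(params) {
  if (is(params, "KineticParams")) {
    K1 <- params@K1; k2 <- params@k2; k3 <- params@k3
  } else if (is.matrix(params)) {
    K1 <- params[, 1]; k2 <- params[, 2]; k3 <- params[, 3]
  } else {
    K1 <- params[1]; k2 <- params[2]; k3 <- params[3]
  }
  den <- k2 + k3
  bad <- den == 0 & K1 * k3 != 0
  if (any(bad)) stop("kflux undefined: k2 + k3 = 0 with K1 * k3 > 0")
  out <- ifelse(den > 0, K1 * k3 / den, 0)
  as.numeric(out)
}

## Impulse response (residue x K1) of the tissue compartments as a sum of
## exponential modes: h(t) = sum_i w_i exp(s_i t), s_i <= 0, plus a constant
## trapped fraction for the irreversible sink.  Returns list(w, s) with the
## constant mode encoded as s = 0.
compartmentModes <- function(params) {
  K1 <- params@K1; k2 <- params@k2; k3 <- params@k3
  if (params@model == "2C3K") {
    al <- k2 + k3
    if (al == 0) return(list(w = K1, s = 0))  # pure integrator limit
    return(list(w = c(K1 * k2 / al, K1 * k3 / al), s = c(-al, 0)))
  }
  ## 3C5K: catenary irreversible three-tissue topology
  ##   plasma <-> C1 (K1, k2); C1 <-> C2 (k3, k4); C2 -> C3 (k5, trap)
  k4 <- params@k4; k5 <- params@k5
  M <- matrix(c(-(k2 + k3), k4, k3, -(k4 + k5)), 2, 2, byrow = TRUE)
  eg <- eigen(M)
  Vi <- solve(eg$vectors)
  cc <- Vi %*% c(K1, 0)                 # modal amplitudes of [C1, C2]
  w1 <- eg$vectors[1, ] * cc            # C1 mode weights
  w2 <- eg$vectors[2, ] * cc            # C2 mode weights
  s <- eg$values
  ## C3(t) = k5 int_0^t C2: adds k5*w2_i/s_i (e^{s_i t} - 1) per mode
  wExp <- as.numeric(w1 + w2)
  wConst <- 0
  for (i in seq_along(s)) {
    if (abs(s[i]) > 1e-14) {
      wExp[i] <- wExp[i] + k5 * w2[i] / s[i]
      wConst <- wConst - k5 * w2[i] / s[i]
    }
    ## s ~ 0 with k5 > 0 cannot occur for physical rate sets
  }
  list(w = c(wExp, wConst), s = c(as.numeric(s), 0))
}

#' Compartment-model time-activity curve
#'
#' Evaluates the tissue TAC
#' \eqn{C_T(t) = V_b C_I(t) + (C_I \otimes h)(t)} where h is the impulse
#' response of the compartment system.  For the 2C3K model
#' \eqn{h(t) = K_1 (k_2 e^{-(k_2+k_3) t} + k_3)/(k_2+k_3)}; the 3C5K model
#' uses the catenary irreversible three-tissue topology (plasma <-> C1 with
#' K1, k2; C1 <-> C2 with k3, k4; C2 -> trap with k5) solved analytically
#' through the eigen-modes of the compartment ODE system.
#'
#' With a parametric (feng3exp) AIF the convolution is evaluated in closed
#' form; with a sampled AIF it is computed on a uniform grid with
#' trapezoidal weights.
#'
#' @param params a [KineticParams-class].
#' @param aif an [AIFModel-class].
#' @param t evaluation times (s).
#' @param dt grid spacing (s) for the sampled-AIF convolution path.
#' @return activity concentrations (Bq/cc) at `t`.
#' @export
compartmentTAC <- function(params, aif, t, dt = 0.25) {
  stopifnot(is(params, "KineticParams"), is(aif, "AIFModel"))
  modes <- compartmentModes(params)
  if (aif@form == "feng3exp") {
    conv <- numeric(length(t))
    for (i in seq_along(modes$s))
      conv <- conv + modes$w[i] * expConvAIF(aif, -modes$s[i], t)
    return(params@Vb * evalAIF(aif, t) + conv)
  }
  grid <- seq(0, max(t), by = dt)
  if (grid[length(grid)] < max(t)) grid <- c(grid, max(t))
  ci <- evalAIF(aif, grid)
  conv <- numeric(length(grid))
  for (i in seq_along(modes$s))
    conv <- conv + modes$w[i] * convolveGrid(ci, exp(modes$s[i] * grid), dt)
  params@Vb * evalAIF(aif, t) + approx(grid, conv, xout = t)$y
}

## Frame-averaged (decayed) compartment TAC: the ground-truth frame values
## a_m = (1/DT_m) int_frame C_T(t) e^{-lambda t} dt.
compartmentFrameAverages <- function(params, aif, sched) {
  f <- function(t) compartmentTAC(params, aif, t)
  frameIntegrate(f, sched) / frameDurations(sched)
}

## ---- 2C3K fitting -------------------------------------------------------

## Frame averages (with physical decay) of a vectorized function of time,
## by trapezoid on a fine uniform grid: fast path used inside fitting loops.
frameAveragesOfFun <- function(fun, sched, dt = 0.5) {
  grid <- timeGridFor(sched, dt)
  frameIntegrateGrid(fun(grid), grid, sched) / frameDurations(sched)
}

## Design columns for the variable-projection parameterization of the 2C3K
## model on the frame grid (frame averages of the decayed curves):
##   f_m = Vb * A0_m + c1 * E_m(alpha) + c2 * U_m
## with alpha = k2 + k3, c1 = K1 k2 / alpha, c2 = kflux = K1 k3 / alpha.
tcmDesign <- function(aif, sched, alpha, dt = 0.5) {
  A0 <- frameAveragesOfFun(function(t) evalAIF(aif, t), sched, dt)
  U <- frameAveragesOfFun(aifConvExpFun(aif, 0), sched, dt)
  E <- vapply(alpha, function(a)
    frameAveragesOfFun(aifConvExpFun(aif, a), sched, dt),
    numeric(nFrames(sched)))
  list(A0 = A0, U = U, E = E, alpha = alpha, aif = aif, sched = sched,
       dt = dt)
}

## function-of-time view of aifConvExp (grid-backed for sampled AIFs)
aifConvExpFun <- function(aif, alpha, dt = 1) {
  if (aif@form == "feng3exp")
    return(function(t) expConvAIF(aif, alpha, t))
  grid <- seq(0, max(aif@times), by = dt)
  ci <- evalAIF(aif, grid)
  v <- convolveGrid(ci, exp(-alpha * grid), dt)
  function(t) approx(grid, v, xout = t, rule = 2)$y
}

## Box-constrained weighted least squares for a small (<= 3 column)
## design, by face enumeration of the feasible box (0 <= beta <= upper).
## Exact for this convex problem.  Returns coefficients and weighted RSS.
smallNNLS <- function(X, y, w, upper = rep(Inf, ncol(X))) {
  p <- ncol(X)
  best <- NULL
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  states <- lapply(seq_len(p), function(k)
    if (is.finite(upper[k])) c(NA, 0, upper[k]) else c(NA, 0))
  gridIdx <- do.call(expand.grid, lapply(states, seq_along))
  for (g in seq_len(nrow(gridIdx))) {
    beta <- numeric(p)
    free <- logical(p)
    for (k in seq_len(p)) {
      v <- states[[k]][gridIdx[g, k]]
      if (is.na(v)) free[k] <- TRUE else beta[k] <- v
    }
    if (any(free)) {
      rhs <- yw - Xw[, !free, drop = FALSE] %*% beta[!free]
      b <- tryCatch(qr.solve(Xw[, free, drop = FALSE], rhs),
                    error = function(e) NULL)
      if (is.null(b)) next
      beta[free] <- b
    }
    if (any(beta < -1e-12) || any(beta > upper + 1e-12)) next
    beta <- pmin(pmax(beta, 0), upper)
    rss <- sum((yw - Xw %*% beta)^2)
    if (is.null(best) || rss < best$rss) best <- list(coef = beta, rss = rss)
  }
  best
}

#' Fit the irreversible two-tissue (2C3K) model to a frame-sampled TAC
#'
#' Weighted least-squares fit of the 2C3K model to per-frame TAC values
#' (frame averages of the decayed curve, the quantity reconstructed images
#' hold).  A variable-projection search profiles the weighted RSS over
#' alpha = k2 + k3 (the only nonlinear parameter once Vb and the two
#' amplitude coefficients are profiled out by nonnegative WLS), and the
#' result optionally seeds a bounded Levenberg-Marquardt polish over
#' (K1, k2, k3, Vb).  Multi-start is inherent: every grid value of alpha is
#' a start.
#'
#' @param tac per-frame TAC values (Bq/cc frame averages).
#' @param aif an [AIFModel-class].
#' @param sched a [FrameSchedule-class].
#' @param weights per-frame WLS weights; default [tacFitWeights()] from the
#'   TAC itself.
#' @param alphaGrid profile grid for k2 + k3 (1/s).
#' @param polish run the Levenberg-Marquardt polish (default TRUE).
#' @param design optional precomputed [tcmDesign()] for `alphaGrid` (an
#'   optimization for repeated fits against one AIF/schedule).
#' @return a [KineticParams-class] with attribute `"rss"` (weighted RSS) and
#'   `"ok"` (FALSE if every start failed, in which case all-zero kinetics
#'   are returned).
#' @export
fit2C3K <- function(tac, aif, sched, weights = NULL,
                    alphaGrid = defaultAlphaGrid(), polish = TRUE,
                    design = NULL) {
  stopifnot(length(tac) == nFrames(sched))
  if (all(tac == 0))
    return(structure(kineticParams(0, 0, 0, Vb = 0), rss = 0, ok = TRUE))
  if (is.null(weights)) weights <- tacFitWeights(sched, tac)
  if (is.null(design)) design <- tcmDesign(aif, sched, alphaGrid)
  best <- NULL
  for (i in seq_along(alphaGrid)) {
    X <- cbind(design$A0, design$E[, i], design$U)
    sol <- smallNNLS(X, tac, weights, upper = c(1, Inf, Inf))
    if (is.null(sol)) next
    if (is.null(best) || sol$rss < best$rss)
      best <- list(rss = sol$rss, coef = sol$coef, alpha = alphaGrid[i], i = i)
  }
  if (is.null(best))
    return(structure(kineticParams(0, 0, 0, Vb = 0), rss = Inf, ok = FALSE))
  ## Brent refinement of alpha between the neighbouring grid points
  lo <- alphaGrid[max(1, best$i - 1)]
  hi <- alphaGrid[min(length(alphaGrid), best$i + 1)]
  if (hi > lo) {
    solveAt <- function(a) {
      E <- frameAveragesOfFun(aifConvExpFun(aif, a), sched)
      smallNNLS(cbind(design$A0, E, design$U), tac, weights,
                upper = c(1, Inf, Inf))
    }
    opt <- optimize(function(a) {
      sol <- solveAt(a)
      if (is.null(sol)) Inf else sol$rss
    }, c(lo, hi), tol = max(1e-7, lo * 1e-4))
    if (opt$objective < best$rss) {
      sol <- solveAt(opt$minimum)
      best <- list(rss = sol$rss, coef = sol$coef, alpha = opt$minimum)
    }
  }
  par <- varproToParams(best$coef, best$alpha)
  if (polish) {
    resid <- function(p) {
      kp <- kineticParams(p[1], p[2], p[3], Vb = min(max(p[4], 0), 1))
      pred <- frameAveragesOfFun(function(t) compartmentTAC(kp, aif, t), sched)
      sqrt(weights) * (tac - pred)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(par$K1, par$k2, par$k3, par$Vb), fn = resid,
                         lower = rep(0, 4), upper = c(1, 1, 1, 1),
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit$par)^2)
      if (rss <= best$rss + 1e-12) {
        p <- fit$par
        return(structure(kineticParams(p[1], p[2], p[3], Vb = p[4]),
                         rss = rss, ok = TRUE))
      }
    }
  }
  structure(kineticParams(par$K1, par$k2, par$k3, Vb = par$Vb),
            rss = best$rss, ok = TRUE)
}

varproToParams <- function(coef, alpha) {
  Vb <- coef[1]; c1 <- coef[2]; c2 <- coef[3]
  K1 <- c1 + c2
  if (K1 > 0) {
    k2 <- alpha * c1 / K1
    k3 <- alpha * c2 / K1
  } else {
    k2 <- 0; k3 <- 0
  }
  list(K1 = K1, k2 = k2, k3 = k3, Vb = Vb)
}

#' @describeIn fit2C3K the default profile grid for k2 + k3: 60 values
#'   log-spaced between 1e-5 and 0.05 1/s.
#' @export
defaultAlphaGrid <- function() exp(seq(log(1e-5), log(0.05), length.out = 60))
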