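## Temporal-model fitting inside the reconstruction: penalized weighted
## least squares (Tikhonov), GCV selection of the temporal weight, and the
## temporal roughness penalty matrices.

#' Temporal roughness penalty matrix
#'
#' For `kind = "L2"` the penalty \eqn{\Lambda(\theta) = |\theta|^2} gives
#' the identity.  For `kind = "d2"` it is the curvature penalty
#' \eqn{\Lambda(\theta) = \int_0^{T} (\partial^2 f/\partial t^2)^2 dt
#'  = \theta^T \Omega \theta} with
#' \eqn{\Omega_{ab} = \int \ddot B_a(t) \ddot B_b(t) dt} over the
#' continuous-time (un-integrated) basis functions.  For a pure spline
#' basis the Gram integrals are evaluated exactly (two-point Gauss-Legendre
#' per knot interval: the integrand is piecewise quadratic); for convolved
#' bases the second derivatives are taken by finite differences on the
#' basis sampling grid and integrated by the trapezoidal rule.
#'
#' @param basis a [BasisMatrix-class].
#' @param kind "L2" or "d2".
#' @return symmetric positive semidefinite N_B x N_B matrix.
#' @export
penaltyMatrix <- function(basis, kind = c("L2", "d2")) {
  kind <- match.arg(kind)
  nb <- ncol(basis@B)
  if (kind == "L2") return(diag(nb))
  if (basis@kind == "spline") return(d2GramSpline(basis@knots))
  if (!length(basis@curves))
    stop("d2 penalty requires a continuous-time basis form")
  d2GramGrid(basis@curves, basis@timeGrid)
}

## exact curvature Gram matrix of a B-spline basis
d2GramSpline <- function(kv) {
  brk <- unique(kv@knots)
  nb <- nBasis(kv)
  G <- matrix(0, nb, nb)
  gl <- c(-1, 1) / sqrt(3)               # 2-point Gauss-Legendre
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    if (b <= a) next
    tq <- (a + b) / 2 + (b - a) / 2 * gl
    D <- splines::splineDesign(kv@knots, tq, ord = kv@order,
                               derivs = rep(2L, length(tq)))
    G <- G + (b - a) / 2 * crossprod(D)
  }
  (G + t(G)) / 2
}

## finite-difference curvature Gram matrix of grid-sampled basis curves
d2GramGrid <- function(curves, grid) {
  dt <- grid[2] - grid[1]
  d2 <- (curves[-c(1, 2), , drop = FALSE] -
           2 * curves[-c(1, nrow(curves)), , drop = FALSE] +
           curves[-c(nrow(curves) - 1, nrow(curves)), , drop = FALSE]) / dt^2
  w <- rep(dt, nrow(d2)); w[c(1, length(w))] <- dt / 2
  G <- crossprod(d2 * sqrt(w))
  (G + t(G)) / 2
}

#' Penalized weighted least-squares fit of a linear temporal model
#'
#' Solves the Tikhonov problem
#' \eqn{\min_\theta \sum_m w_m (\hat x_m - \sum_k B_{mk}\theta_k)^2 +
#'      \gamma' \theta^T \Omega \theta}
#' exactly via a Cholesky factorization of
#' \eqn{B^T W B + \gamma' \Omega} (never an explicit inverse).  The solve is
#' unconstrained: coefficients (and hence predicted TACs) may go negative.
#'
#' @param B frame-integrated basis matrix (N_T x N_B).
#' @param xhat per-frame target values (length N_T).
#' @param w per-frame weights (length N_T), finite.
#' @param gamma temporal regularization weight (>= 0).
#' @param Omega penalty matrix (default identity).
#' @param singular.ok if TRUE, fall back to a pseudoinverse (minimum-norm)
#'   solution when the system is singular at `gamma = 0` instead of
#'   erroring.
#' @return coefficient vector theta (length N_B).
#' @export
fitLinearTAC <- function(B, xhat, w, gamma = 0, Omega = diag(ncol(B)),
                         singular.ok = FALSE) {
  stopifnot(nrow(B) == length(xhat), length(w) == length(xhat))
  M <- crossprod(B, w * B) + gamma * Omega
  cvec <- crossprod(B, w * xhat)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    if (!singular.ok)
      stop("singular normal equations: use gamma > 0 or reduce the basis")
    sv <- svd(sqrt(w) * B)
    pos <- sv$d > max(sv$d) * 1e-10
    return(as.numeric(sv$v[, pos, drop = FALSE] %*%
                        (crossprod(sv$u[, pos, drop = FALSE],
                                   sqrt(w) * xhat) / sv$d[pos])))
  }
  as.numeric(backsolve(ch, forwardsolve(t(ch), cvec)))
}

#' Select the temporal weight by generalized cross-validation
#'
#' Evaluates, for every candidate \eqn{\gamma'},
#' \deqn{GCV(\gamma') = \frac{\sum_m w_m (\hat x_m - x_m(\theta))^2}
#'   {\big(\mathrm{Tr}(I - B (B^T W B + \gamma'\Omega)^{-1} B^T W)\big)^2}}
#' (the denominator is the squared effective residual degrees of freedom)
#' and returns the minimizer and its fit.  Ties break toward the larger
#' (smoother) \eqn{\gamma'}.  If every score is non-finite the largest grid
#' value is returned with a warning.
#'
#' @inheritParams fitLinearTAC
#' @param grid candidate gamma values (nonempty, ascending).
#' @return list with `gamma`, `theta`, `scores` (one per grid value).
#' @export
gcvSelect <- function(B, xhat, w, Omega = diag(ncol(B)),
                      grid = seq(0.001, 0.01, by = 0.001)) {
  stopifnot(length(grid) >= 1)
  grid <- sort(grid)
  nt <- nrow(B)
  scores <- numeric(length(grid))
  thetas <- vector("list", length(grid))
  M0 <- crossprod(B, w * B)
  cvec <- crossprod(B, w * xhat)
  for (i in seq_along(grid)) {
    M <- M0 + grid[i] * Omega
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) { scores[i] <- Inf; next }
    th <- backsolve(ch, forwardsolve(t(ch), cvec))
    r <- xhat - as.numeric(B %*% th)
    edf <- sum(diag(backsolve(ch, forwardsolve(t(ch), M0))))
    scores[i] <- sum(w * r^2) / (nt - edf)^2
    thetas[[i]] <- as.numeric(th)
  }
  if (all(!is.finite(scores))) {
    warning("all GCV scores non-finite: falling back to the largest gamma")
    i <- length(grid)
    th <- fitLinearTAC(B, xhat, w, grid[i], Omega, singular.ok = TRUE)
    return(list(gamma = grid[i], theta = th, scores = scores))
  }
  best <- 1
  for (i in seq_along(grid))
    if (is.finite(scores[i]) && scores[i] <= scores[best]) best <- i
  list(gamma = grid[best], theta = thetas[[best]], scores = scores)
}

## ---- batch fitting over voxels (used by the nested reconstruction) ------

## Fit all voxel TACs with per-voxel weights, selecting gamma per voxel by
## GCV on the supplied grid (or using fixed gamma values / no penalty).
## Xhat, W: N_V x N_T.  Returns list(theta [N_V x N_B], gamma, pred).
## When Omega is the identity an eigendecomposition of B^T W B makes the
## whole grid cheap per voxel.
gcvFitBatch <- function(B, Xhat, W, Omega, grid, fixedGamma = NULL,
                        penalty = TRUE) {
  nv <- nrow(Xhat); nb <- ncol(B); nt <- nrow(B)
  theta <- matrix(0, nv, nb)
  gam <- numeric(nv)
  ident <- is.null(Omega) ||
    (nrow(Omega) == nb && all(Omega == diag(nb)))
  for (j in seq_len(nv)) {
    w <- W[j, ]
    xh <- Xhat[j, ]
    if (!penalty) {
      theta[j, ] <- fitLinearTAC(B, xh, w, 0, singular.ok = TRUE)
      next
    }
    if (!is.null(fixedGamma)) {
      g <- if (length(fixedGamma) == 1) fixedGamma else fixedGamma[j]
      theta[j, ] <- fitLinearTAC(B, xh, w, g, Omega, singular.ok = TRUE)
      gam[j] <- g
      next
    }
    if (ident && nb > nt) {
      ## dual (frame-space) ridge: with Omega = I the hat matrix is
      ## A(AA' + gI)^{-1}A' for A = sqrt(W) B, and AA' is only N_T x N_T
      sw <- sqrt(w)
      A <- sw * B
      eg <- eigen(tcrossprod(A), symmetric = TRUE)
      d <- pmax(eg$values, 0)
      ytil <- crossprod(eg$vectors, sw * xh)
      best <- NULL
      for (g in grid) {
        u <- ytil * (d / (d + g))         # fitted values in rotated space
        rw <- ytil - u                     # weighted residuals (rotated)
        edf <- sum(d / (d + g))
        sc <- sum(rw^2) / (nt - edf)^2
        if (is.finite(sc) && (is.null(best) || sc <= best$sc))
          best <- list(sc = sc, g = g)
      }
      if (is.null(best)) best <- list(g = grid[length(grid)])
      g <- best$g
      uvec <- eg$vectors %*% (ytil / (d + g))
      theta[j, ] <- crossprod(A, uvec)
      gam[j] <- g
    } else if (ident) {
      M <- crossprod(B, w * B)
      cv <- crossprod(B, w * xh)
      eg <- eigen(M, symmetric = TRUE)
      d <- pmax(eg$values, 0)
      ctil <- crossprod(eg$vectors, cv)
      best <- NULL
      for (g in grid) {
        th <- eg$vectors %*% (ctil / (d + g))
        r <- xh - as.numeric(B %*% th)
        edf <- sum(d / (d + g))
        sc <- sum(w * r^2) / (nt - edf)^2
        if (is.finite(sc) && (is.null(best) || sc <= best$sc))
          best <- list(sc = sc, th = th, g = g)
      }
      if (is.null(best)) {
        g <- grid[length(grid)]
        best <- list(th = eg$vectors %*% (ctil / (d + g)), g = g)
      }
      theta[j, ] <- best$th
      gam[j] <- best$g
    } else {
      ## general penalty: chol per grid value, with a relative ridge of
      ## 1e-10 to absorb directions left unidentified by frame-schedule
      ## gaps (basis support falling between late frames).  The curvature
      ## penalty applies to the amplitude-normalized TAC (penalty scaled
      ## by 1/max(xhat)^2), so one gamma grid spans all voxel intensities.
      M0 <- crossprod(B, w * B)
      cv <- crossprod(B, w * xh)
      amp2 <- max(max(abs(xh))^2, 1e-12)
      Omega <- Omega / amp2
      ridge <- 1e-10 * max(diag(M0)) * diag(nb)
      best <- NULL
      for (g in grid) {
        M <- M0 + g * Omega + ridge
        ch <- tryCatch(chol(M), error = function(e) NULL)
        if (is.null(ch)) next
        th <- backsolve(ch, forwardsolve(t(ch), cv))
        r <- xh - as.numeric(B %*% th)
        edf <- sum(diag(backsolve(ch, forwardsolve(t(ch), M0))))
        sc <- sum(w * r^2) / (nt - edf)^2
        if (is.finite(sc) && (is.null(best) || sc <= best$sc))
          best <- list(sc = sc, th = th, g = g)
      }
      if (is.null(best)) {
        g <- grid[length(grid)]
        best <- list(th = fitLinearTAC(B, xh, w, g, Omega,
                                       singular.ok = TRUE), g = g)
      }
      theta[j, ] <- best$th
      gam[j] <- best$g
    }
  }
  list(theta = theta, gamma = gam, pred = theta %*% t(B))
}
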