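## Poisson likelihood, Lange spatial prior, and the EM / MAP image updates
## (optimization transfer with a separable surrogate for the prior).

#' Poisson log-likelihood of sinogram counts
#'
#' \eqn{\sum_{im} [y_{im} \ln\langle y_{im}\rangle - \langle y_{im}\rangle]}
#' with the factorial constant omitted.  Bins with `expected == 0` and
#' `y > 0` make the likelihood \code{-Inf} (with a warning).
#'
#' @param y observed counts (vector or matrix).
#' @param expected expected counts, same shape.
#' @return scalar log-likelihood.
#' @export
poissonLogLik <- function(y, expected) {
  stopifnot(length(y) == length(expected))
  bad <- expected == 0 & y > 0
  if (any(bad)) {
    warning("expected = 0 where y > 0: log-likelihood is -Inf")
    return(-Inf)
  }
  pos <- y > 0
  sum(y[pos] * log(expected[pos])) - sum(expected)
}

## 8-neighbourhood structure on an n x n grid with inverse-distance weights
## z (1 orthogonal, 1/sqrt(2) diagonal), normalized by the full-neighbourhood
## weight sum so z is symmetric (border voxels simply have fewer terms).
neighbourStructure <- function(n) {
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  wsum <- 4 + 4 / sqrt(2)
  ix <- matrix(rep(seq_len(n), n), n, n)
  iy <- matrix(rep(seq_len(n), each = n), n, n)
  lapply(seq_len(nrow(offs)), function(k) {
    dx <- offs$dx[k]; dy <- offs$dy[k]
    jx <- ix + dx; jy <- iy + dy
    ok <- jx >= 1 & jx <= n & jy >= 1 & jy <= n
    src <- which(ok)
    dst <- jx[ok] + (jy[ok] - 1L) * n
    list(src = src, dst = dst,
         z = (1 / sqrt(dx^2 + dy^2)) / wsum)
  })
}

langePsi <- function(xi, delta) {
  a <- abs(xi) / delta
  delta * (a - log1p(a))
}
langePsiPrime <- function(xi, delta) xi / (delta + abs(xi))
langePsiSecond <- function(xi, delta) delta / (delta + abs(xi))^2

#' Lange spatial roughness prior
#'
#' \eqn{U(x) = \frac14 \sum_j \sum_{k \in N_j} z_{jk}\,\psi(x_j - x_k)}
#' over the 8-neighbourhood with normalized inverse-distance weights
#' \eqn{z_{jk}}, using the edge-preserving Lange potential
#' \eqn{\psi(\xi) = \delta(|\xi|/\delta - \ln(1 + |\xi|/\delta))}.
#' For \eqn{|\xi| \ll \delta} this behaves like \eqn{\xi^2/(2\delta)};
#' for large \eqn{|\xi|} it grows linearly, preserving edges.
#'
#' @param x image vector (length n^2) or n x n matrix.
#' @param delta Lange smoothing parameter (same units as x).
#' @param nbr optional precomputed [neighbourStructure] (internal reuse).
#' @return scalar penalty value U(x) >= 0.
#' @export
langePenalty <- function(x, delta, nbr = NULL) {
  x <- as.vector(x)
  n <- as.integer(round(sqrt(length(x))))
  stopifnot(n * n == length(x))
  if (is.null(nbr)) nbr <- neighbourStructure(n)
  u <- 0
  for (s in nbr)
    u <- u + sum(s$z * langePsi(x[s$src] - x[s$dst], delta))
  u / 4
}

#' One MLEM update of a dynamic image
#'
#' The per-frame multiplicative expectation-maximization update
#' \eqn{\hat x_{jm} = \frac{x_{jm}}{\sum_i P_{ij}}
#'   \sum_i P_{ij} \frac{y_{im}}{\langle y_{im}\rangle}}
#' with known additive background inside
#' \eqn{\langle y \rangle = Px + \epsilon}.  Nonnegativity is preserved and
#' consistent data (\eqn{y = Px + \epsilon}) are a fixed point.  Voxels
#' with zero sensitivity are left untouched (and reported via
#' [deadVoxels()]).
#'
#' @param x current count-domain image (N_V x N_T matrix, or vector for a
#'   single frame).
#' @param P system matrix.
#' @param y observed counts, same shape as the forward projection.
#' @param eps known background, same shape (or scalar).
#' @return updated image, same shape as `x`.
#' @export
mlemUpdate <- function(x, P, y, eps = 0) {
  vec <- is.null(dim(x))
  if (vec) { x <- cbind(x); y <- cbind(y); if (!is.null(dim(eps))) eps <- cbind(eps) }
  stopifnot(all(x >= 0))
  s <- as.numeric(Matrix::colSums(P))
  ybar <- as.matrix(P %*% x) + eps
  ratio <- y / ybar
  ratio[y == 0] <- 0
  if (any(!is.finite(ratio)))
    stop("expected counts are zero where y > 0; supply a positive background")
  back <- as.matrix(Matrix::crossprod(P, ratio))
  xhat <- x * back / ifelse(s > 0, s, 1)
  xhat[s == 0, ] <- x[s == 0, ]
  if (vec) xhat[, 1] else xhat
}

#' One MAP update of a dynamic image (Lange prior, optimization transfer)
#'
#' Per frame, maximizes a separable surrogate of
#' \eqn{L(x | y) - \beta U(x)}: the EM surrogate for the Poisson
#' likelihood plus the convexity (half-sum) surrogate for the Lange prior,
#' yielding a decoupled strictly concave 1-D problem per voxel solved by
#' guarded Newton iteration.  With `beta = 0` the result equals
#' [mlemUpdate()] exactly, and each update never decreases the penalized
#' objective of its frame.
#'
#' @inheritParams mlemUpdate
#' @param beta spatial regularization weight (>= 0).
#' @param delta Lange parameter (> 0), count-domain units.
#' @param nbr optional precomputed neighbour structure.
#' @param tol Newton convergence tolerance (relative).
#' @return updated count-domain image, same shape as `x`.
#' @export
mapUpdate <- function(x, P, y, eps = 0, beta = 0.1, delta = 0.1,
                      nbr = NULL, tol = 1e-9) {
  xhat <- mlemUpdate(x, P, y, eps)
  if (beta == 0) return(xhat)
  vec <- is.null(dim(x))
  if (vec) { x <- cbind(x); xhat <- cbind(xhat) }
  n <- as.integer(round(sqrt(nrow(x))))
  stopifnot(n * n == nrow(x))
  if (is.null(nbr)) nbr <- neighbourStructure(n)
  s <- as.numeric(Matrix::colSums(P))
  live <- s > 0
  nt <- ncol(x)
  ## per-shift constants 2v - (xn_j + xn_k); all frames solved jointly
  Cs <- lapply(nbr, function(sN)
    x[sN$src, , drop = FALSE] + x[sN$dst, , drop = FALSE])
  ## surrogate gradient (per voxel and frame):
  ##   g(v) = s*(xh/v - 1) - (beta/2) sum_k z psi'(2v - xn_j - xn_k)
  grad <- function(V) {
    G <- s * (xhat / V - 1)
    for (k in seq_along(nbr)) {
      sN <- nbr[[k]]
      G[sN$src, ] <- G[sN$src, , drop = FALSE] -
        (beta / 2) * sN$z *
          langePsiPrime(2 * V[sN$src, , drop = FALSE] - Cs[[k]], delta)
    }
    G
  }
  curv <- function(V) {
    H <- -s * xhat / V^2
    for (k in seq_along(nbr)) {
      sN <- nbr[[k]]
      H[sN$src, ] <- H[sN$src, , drop = FALSE] -
        beta * sN$z *
          langePsiSecond(2 * V[sN$src, , drop = FALSE] - Cs[[k]], delta)
    }
    H
  }
  zero <- xhat <= 0                 # EM surrogate pins these at 0
  track <- (!zero) & live
  ## |psi'| <= 1 bounds the penalty gradient by (beta/2) sum_k z_jk, so the
  ## root of g is bracketed inside a narrow relative band around xhat:
  ##   x* = xhat s / (s + p) with |p| <= penBound
  zsum <- numeric(nrow(xhat))
  for (sN in nbr) zsum[sN$src] <- zsum[sN$src] + sN$z
  penB <- (beta / 2) * zsum
  lo <- xhat * (s / (s + penB))
  hi <- xhat * (s / pmax(s - penB, s / 2))
  ## strong penalties (penB >= s/2) void the closed bracket: expand there
  wide <- penB >= s / 2
  if (any(wide)) {
    hi[wide, ] <- pmax(2 * xhat[wide, , drop = FALSE], delta)
    for (i in 1:60) {
      g <- grad(hi)
      bad <- g > 0 & track
      if (!any(bad)) break
      hi[bad] <- hi[bad] * 4
    }
  }
  V <- xhat
  V[!track] <- pmax(V[!track], 1e-300)
  for (it in 1:60) {                # guarded Newton, bisection fallback
    g <- grad(V)
    lo[g > 0] <- V[g > 0]
    hi[g < 0] <- V[g < 0]
    vNew <- V - g / curv(V)
    outside <- vNew < lo | vNew > hi | !is.finite(vNew)
    vNew[outside] <- (lo[outside] + hi[outside]) / 2
    conv <- abs(vNew - V) <= tol * V + 1e-300
    V <- vNew
    ## freeze converged entries by collapsing their brackets
    lo[conv] <- V[conv]
    hi[conv] <- V[conv]
    if (all(conv[track])) break
  }
  V[zero] <- 0
  V[!live, ] <- x[!live, ]
  if (vec) V[, 1] else V
}
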