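#' Construct a 2D parallel-beam scanner geometry
#'
#' The desk-scale stand-in for a clinical PET geometry: `nAngles` parallel
#' projections over 180 degrees, each with `nBins` radial bins, over an
#' n x n voxel grid centred on the scanner axis.
#'
#' @param nAngles number of projection angles.
#' @param nBins number of radial bins (odd keeps a centre bin).
#' @param n image grid side (n x n voxels).
#' @param voxelSize voxel edge length (mm).
#' @param binWidth radial bin width (mm); defaults to the voxel size.
#' @param attenuation NULL, or list(cx, cy, rx, ry, mu): a water-equivalent
#'   ellipse attenuation map (centre and semi-axes in mm, mu in 1/mm).
#' @return a [ScannerGeometry-class].
#' @examples
#' scannerGeometry(n = 32)
#' @export
scannerGeometry <- function(nAngles = 60L, nBins = 95L, n = 64L,
                            voxelSize = 3.1, binWidth = voxelSize,
                            attenuation = NULL) {
  new("ScannerGeometry", nAngles = as.integer(nAngles),
      nBins = as.integer(nBins), binWidth = as.numeric(binWidth),
      n = as.integer(n), voxelSize = as.numeric(voxelSize),
      attenuation = attenuation)
}

## chord length (mm) of a ray through an ellipse; ray = p0 + t*d, |d| = 1
ellipseChord <- function(p0, d, cx, cy, rx, ry) {
  ## scale to unit circle
  q0 <- c((p0[1] - cx) / rx, (p0[2] - cy) / ry)
  qd <- c(d[1] / rx, d[2] / ry)
  a <- sum(qd^2); b <- 2 * sum(q0 * qd); cc <- sum(q0^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(0)
  ts <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  abs(diff(ts))                 # in scanner mm because |d| = 1
}

#' Build the tomographic system matrix
#'
#' Exact strip-integral (length-of-intersection) weights: element (i, j) is
#' the length (mm) of the intersection of ray i (one angle/radial-bin pair)
#' with voxel j, traced by marching the ray through the pixel grid.  When
#' the geometry carries an attenuation ellipse, each row is additionally
#' scaled by the analytic attenuation factor exp(-mu * chord) of its ray;
#' a per-ray `normalization` vector can be folded in the same way.
#'
#' Rays are ordered bin-fastest: row (a - 1) * nBins + r is angle a, bin r.
#' Voxels are ordered column-major over the n x n grid.
#'
#' @param geom a [ScannerGeometry-class].
#' @param normalization optional per-ray multiplicative factor.
#' @return a sparse `dgCMatrix` (N_D x N_V) of nonnegative weights.
#' @seealso [deadVoxels()] for voxels outside every strip.
#' @export
buildSystemMatrix <- function(geom, normalization = NULL) {
  n <- geom@n; w <- geom@voxelSize
  nA <- geom@nAngles; nB <- geom@nBins
  half <- n * w / 2
  offs <- (seq_len(nB) - (nB + 1) / 2) * geom@binWidth
  angs <- (seq_len(nA) - 1) * pi / nA
  ii <- vector("list", nA * nB)
  jj <- vector("list", nA * nB)
  xx <- vector("list", nA * nB)
  ray <- 0L
  for (a in seq_len(nA)) {
    ct <- cos(angs[a]); st <- sin(angs[a])
    d <- c(-st, ct)
    for (r in seq_len(nB)) {
      ray <- ray + 1L
      p0 <- c(offs[r] * ct, offs[r] * st)
      seg <- traceRay(p0, d, n, w, half)
      if (is.null(seg)) next
      fac <- 1
      if (!is.null(geom@attenuation)) {
        at <- geom@attenuation
        fac <- exp(-at$mu * ellipseChord(p0, d, at$cx, at$cy, at$rx, at$ry))
      }
      if (!is.null(normalization)) fac <- fac * normalization[ray]
      ii[[ray]] <- rep.int(ray, length(seg$j))
      jj[[ray]] <- seg$j
      xx[[ray]] <- seg$len * fac
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nA * nB, n * n))
}

## march a unit-direction ray through the n x n grid; returns voxel indices
## (column-major) and intersection lengths (mm), or NULL if it misses
traceRay <- function(p0, d, n, w, half) {
  ts <- numeric(0)
  ## parameter values at every grid-line crossing
  if (abs(d[1]) > 1e-12) {
    xs <- seq(-half, half, by = w)
    ts <- c(ts, (xs - p0[1]) / d[1])
  }
  if (abs(d[2]) > 1e-12) {
    ys <- seq(-half, half, by = w)
    ts <- c(ts, (ys - p0[2]) / d[2])
  }
  if (!length(ts)) return(NULL)
  ## clip to the bounding box
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    if (abs(d[k]) > 1e-12) {
      t1 <- (-half - p0[k]) / d[k]; t2 <- (half - p0[k]) / d[k]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    } else if (p0[k] < -half || p0[k] >= half) {
      ## half-open grid convention: the lower/left boundary is inside
      return(NULL)
    }
  }
  if (tmax <= tmin) return(NULL)
  ts <- sort(unique(c(ts[ts > tmin & ts < tmax], tmin, tmax)))
  if (length(ts) < 2) return(NULL)
  len <- diff(ts)
  tm <- (head(ts, -1) + tail(ts, -1)) / 2
  px <- p0[1] + tm * d[1]
  py <- p0[2] + tm * d[2]
  ix <- pmin(pmax(floor((px + half) / w) + 1, 1), n)
  iy <- pmin(pmax(floor((py + half) / w) + 1, 1), n)
  keep <- len > 1e-12
  if (!any(keep)) return(NULL)
  j <- ix[keep] + (iy[keep] - 1L) * n
  len <- len[keep]
  ## merge duplicate voxels (can arise from corner crossings)
  agg <- rowsum(len, j)
  list(j = as.integer(rownames(agg)), len = as.numeric(agg))
}

#' Voxels with zero sensitivity
#'
#' @param P a system matrix from [buildSystemMatrix()].
#' @return integer indices of voxels intersected by no strip (these carry no
#'   information and are excluded from reconstruction updates and metrics).
#' @export
deadVoxels <- function(P) which(Matrix::colSums(P) == 0)
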