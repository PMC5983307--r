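## shared fixtures, built lazily once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tinySchedule <- function()
  frameSchedule(c(0, 30, 60, 120, 300, 600),
                c(30, 60, 120, 300, 600, 1200), tInj = 10)

## small thoracic phantom + scan shared across reconstruction tests
smallSim <- function() fixture("smallSim", function() {
  ph <- makeReferencePhantom("simplified", n = 16L)
  sched <- defaultFrameSchedule()
  geom <- scannerGeometry(nAngles = 24L, nBins = 23L, n = 16L)
  simulateScan(ph, sched, geom, targetCounts = 8e5)
})

## independent line-through-square intersection length (Liang-Barsky),
## used as the geometric oracle for the strip projector
clipLineSquare <- function(p0, d, xlo, xhi, ylo, yhi) {
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    lo <- if (k == 1) xlo else ylo
    hi <- if (k == 1) xhi else yhi
    if (abs(d[k]) < 1e-14) {
      ## half-open pixel convention [lo, hi): a ray on the shared edge
      ## belongs to the right/upper pixel
      if (p0[k] < lo || p0[k] >= hi) return(0)
    } else {
      t1 <- (lo - p0[k]) / d[k]; t2 <- (hi - p0[k]) / d[k]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  max(0, tmax - tmin)
}

## independent Lange penalty oracle: explicit double loop over pairs
langeOracle <- function(img, delta) {
  n <- nrow(img)
  psi <- function(xi) delta * (abs(xi) / delta - log1p(abs(xi) / delta))
  wsum <- 4 + 4 / sqrt(2)
  u <- 0
  for (ix in 1:n) for (iy in 1:n)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      jx <- ix + dx; jy <- iy + dy
      if (jx < 1 || jx > n || jy < 1 || jy > n) next
      z <- (1 / sqrt(dx^2 + dy^2)) / wsum
      u <- u + z * psi(img[ix, iy] - img[jx, jy])
    }
  u / 4
}
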