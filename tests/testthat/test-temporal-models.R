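## Temporal models: AIF, B-splines, knot placement, frame integration and
## basis construction.

test_that("parametric AIF evaluates the closed bolus form and is causal", {
  aif <- aifModel("feng3exp",
                  params = c(A1 = 800, A2 = 20, A3 = 21, l1 = -0.05,
                             l2 = -0.001, l3 = -1e-4, tau = 30))
  ## zero before the delay, continuous after it
  expect_equal(evalAIF(aif, c(0, 15, 30)), c(0, 0, 0))
  expect_lt(evalAIF(aif, 30 + 1e-9), 1e-5)
  ## independent arithmetic at t = 60 s
  u <- 30
  byHand <- (800 * u - 20 - 21) * exp(-0.05 * u) +
    20 * exp(-0.001 * u) + 21 * exp(-1e-4 * u)
  expect_equal(evalAIF(aif, 60), byHand, tolerance = 1e-12)
  ## physical validity of the default over the scan
  tt <- seq(0, 15030, by = 5)
  expect_true(all(evalAIF(defaultAIF(), tt) >= 0))
})

test_that("sampled AIF interpolates its nodes and is zero before them", {
  aif <- aifModel("sampled", times = c(10, 20, 40), values = c(0, 100, 50))
  expect_equal(evalAIF(aif, 20), 100)
  expect_equal(evalAIF(aif, 30), 75)
  expect_equal(evalAIF(aif, 5), 0)
})

test_that("B-spline basis: partition of unity, endpoints, closed form", {
  ## partition of unity over random interior knot sets
  set.seed(11)
  for (rep in 1:5) {
    kv <- knotVector(sort(runif(rep + 1, 5, 95)), c(0, 100))
    v <- bsplineEval(kv, seq(0.5, 99.5, length.out = 37))
    expect_lt(max(abs(rowSums(v) - 1)), 1e-12)
    expect_true(all(v >= 0))
  }
  ## endpoint interpolation with full boundary multiplicity
  kv <- knotVector(c(30, 60), c(0, 90))
  v0 <- bsplineEval(kv, 0)
  expect_equal(as.numeric(v0), c(1, rep(0, ncol(v0) - 1)))
  ## uniform cubic B-spline at the midpoint of its central interval:
  ## values (1, 23, 23, 1)/48 (classical closed form)
  kvu <- knotVector(1:7, c(0, 8))
  vm <- bsplineEval(kvu, 3.5)
  nz <- vm[vm > 1e-14]
  expect_equal(as.numeric(nz), c(1, 23, 23, 1) / 48, tolerance = 1e-12)
  ## outside-span behaviour
  expect_error(bsplineEval(kv, 95), "outside")
  expect_equal(sum(bsplineEval(kv, 95, outside = "zero")), 0)
})

test_that("frame integration: closed forms, linearity, quadrature oracle", {
  fs <- frameSchedule(0, 30, lambda = 0)
  expect_equal(frameIntegrate(function(t) rep(1, length(t)), fs), 30)
  lam <- log(2) / 6586
  fsd <- frameSchedule(0, 600, lambda = lam)
  expect_equal(frameIntegrate(function(t) rep(1, length(t)), fsd),
               (1 - exp(-600 * lam)) / lam, tolerance = 1e-10)
  ## linearity
  fs2 <- tinySchedule()
  f <- function(t) exp(-t / 300)
  g <- function(t) sqrt(t + 1)
  lhs <- frameIntegrate(function(t) 2 * f(t) + 3 * g(t), fs2)
  rhs <- 2 * frameIntegrate(f, fs2) + 3 * frameIntegrate(g, fs2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  ## spline column vs composite Simpson oracle
  kv <- knotVector(c(200, 500, 800), c(0, 1200))
  sfun <- function(t) bsplineEval(kv, t, outside = "zero")[, 3]
  got <- frameIntegrate(sfun, fs2, lambda = 0)
  simpson <- vapply(seq_len(nFrames(fs2)), function(m) {
    x <- seq(frameStarts(fs2)[m], frameEnds(fs2)[m], length.out = 2001)
    h <- x[2] - x[1]
    y <- sfun(x)
    h / 3 * (y[1] + y[2001] + 4 * sum(y[seq(2, 2000, 2)]) +
               2 * sum(y[seq(3, 1999, 2)]))
  }, numeric(1))
  expect_equal(got, simpson, tolerance = 1e-10)
})

test_that("adaptive knots follow the curvature-density law", {
  ## f(t) = t^5: |f''''|^{1/4} ~ t^{1/4}, cumulative ~ t^{5/4}, so interior
  ## knot q of n (n+1 equal segments) sits at T (q/(n+1))^{4/5}
  T <- 100
  br <- seq(0, T, length.out = 101)
  sch <- frameSchedule(head(br, -1), tail(br, -1), lambda = 0)
  tac <- frameMidpoints(sch)^5
  kv <- adaptiveKnots(tac, sch, nFree = 5)
  interior <- kv@knots[5:9]
  law <- T * ((1:5) / 6)^(4 / 5)
  expect_true(!is.unsorted(interior))
  expect_lt(max(abs(interior - law) / law), 0.01)
  ## cubic TAC: vanishing 4th derivative, uniform fallback
  tac3 <- 2 + 0.1 * frameMidpoints(sch)^3
  kv3 <- adaptiveKnots(tac3, sch, nFree = 4)
  expect_equal(kv3@knots[5:8], seq(0, T, length.out = 6)[2:5],
               tolerance = 1e-9)
})

test_that("adaptive knots on a noisy tumour-like TAC concentrate early", {
  sched <- defaultFrameSchedule()
  ph <- makeReferencePhantom("simplified", n = 16L)
  f <- dpet4d:::regionTACFun(ph@regions$hypoxic_tumour, ph@aif)
  am <- frameIntegrate(f, sched) / frameDurations(sched)
  set.seed(7)
  noisy <- am + rnorm(length(am), sd = 0.05 * max(am))
  kv <- adaptiveKnots(noisy, sched, nFree = 11)
  interior <- kv@knots[5:15]
  expect_length(interior, 11)
  expect_true(!is.unsorted(interior))
  ## oracle: cumulative fine-grid quadrature of the pilot's placement
  ## density must be (nearly) equally split by the knots
  expect_gt(sum(interior < 2700), sum(interior >= 2700))
})

test_that("spline-residue knot rule: multiplicities and uniform spacing", {
  sched <- defaultFrameSchedule()
  T <- max(frameEnds(sched))
  kv <- splineResidueKnots(sched = sched, risePoint = 30)
  expect_equal(sum(kv@knots == 0), 4)
  expect_equal(sum(kv@knots == 30), 4)
  expect_equal(sum(kv@knots == T), 4)
  uni <- kv@knots[kv@knots > 30 & kv@knots < T]
  expect_equal(uni, 30 + (1:6) * (T - 30) / 7)
  ## identically zero TAC: rise point falls back to the injection time
  kv0 <- splineResidueKnots(rep(0, nFrames(sched)), sched)
  expect_equal(sum(kv0@knots == sched@tInj), 4)
  ## noiseless step TAC rising at frame 2 of a uniform schedule: the
  ## detected rise sits within one frame of the step
  brs <- seq(0, 3600, by = 60)
  schu <- frameSchedule(head(brs, -1), tail(brs, -1), tInj = 60)
  tacStep <- c(0, rep(100, nFrames(schu) - 1))
  kvs <- splineResidueKnots(tacStep, schu)
  rise <- unique(kvs@knots[kvs@knots > 0 & kvs@knots < 3600])[1]
  expect_lt(abs(rise - 60), 60)
})

test_that("basis construction: provenance, exact blood column, causality", {
  sched <- defaultFrameSchedule(lateFrames = FALSE)
  aif <- defaultAIF()
  b <- buildBasis("spline_residue", sched, aif = aif)
  expect_s4_class(b, "BasisMatrix")
  ## column 1 is exactly the frame-integrated AIF
  expect_equal(basisValues(b)[, 1],
               frameIntegrate(function(t) evalAIF(aif, t), sched))
  ## causality: convolved columns vanish before the AIF delay (tau = 30);
  ## frame 1 covers [0, 30) (tolerance at FFT round-off scale)
  expect_true(all(abs(basisValues(b)[1, ]) <
                    1e-6 * apply(abs(basisValues(b)), 2, max)))
  expect_true(all(is.finite(basisValues(b))))
  ## spectral grid endpoints as configured by default
  bs <- buildBasis("spectral", sched, aif = aif)
  expect_equal(range(bs@decays), c(1.1e-4, 1e-2))
  expect_equal(ncol(basisValues(bs)), 101)  # blood column + 100 decays
  dl <- diff(log(bs@decays))
  expect_lt(diff(range(dl)), 1e-12)         # log-uniform
  expect_error(buildBasis("spectral", sched), "AIF")
})

test_that("spline-residue basis approaches the plain spline basis for a
           narrow bolus AIF", {
  sched <- tinySchedule()
  ## near-Dirac unit-area pulse at t = 0 (width 2 s)
  pulse <- aifModel("sampled", times = c(0, 1, 2, 1200),
                    values = c(1, 0, 0, 0))
  kv <- knotVector(c(150, 400, 800), c(0, 1200))
  bSpline <- buildBasis("spline", sched, knots = kv)
  bConv <- buildBasis("spline_residue", sched, aif = pulse, knots = kv)
  A <- basisValues(bSpline)
  B <- basisValues(bConv)[, -1]           # drop the blood column
  ## the pulse has unit height, area 1/2 on the convolution grid
  area <- sum(evalAIF(pulse, 0:1200)) - 0.5 * evalAIF(pulse, 0)
  rel <- abs(B - area * A) / max(abs(A) * area)
  expect_lt(max(rel), 0.02)
})

test_that("compartment TACs: topology collapses and the ODE oracle", {
  skip_if_not_installed("deSolve")
  aif <- defaultAIF()
  tt <- seq(0, 2700, by = 1)
  ## blood-only voxel
  kp0 <- kineticParams(0, 0, 0, Vb = 1)
  expect_equal(compartmentTAC(kp0, aif, tt), evalAIF(aif, tt))
  ## k3 = 0 reduces to the one-tissue model K1 C_I (x) e^{-k2 t} + Vb C_I
  kp1 <- kineticParams(0.2 / 60, 0.3 / 60, 0, Vb = 0.04)
  oneT <- 0.04 * evalAIF(aif, tt) +
    0.2 / 60 * dpet4d:::expConvAIF(aif, 0.3 / 60, tt)
  expect_equal(compartmentTAC(kp1, aif, tt), oneT, tolerance = 1e-12)
  ## stated example vs stiff ODE oracle on a 1 s grid
  oracle2c <- function(K1, k2, k3, Vb) {
    f <- function(t, y, p)
      list(c(K1 * evalAIF(aif, t) - (k2 + k3) * y[1], k3 * y[1]))
    sol <- deSolve::ode(c(0, 0), tt, f, NULL, rtol = 1e-10, atol = 1e-10)
    Vb * evalAIF(aif, tt) + sol[, 2] + sol[, 3]
  }
  kp <- kineticParams(0.2 / 60, 0.3 / 60, 0.1 / 60, Vb = 0.05)
  ref <- oracle2c(0.2 / 60, 0.3 / 60, 0.1 / 60, 0.05)
  got <- compartmentTAC(kp, aif, tt)
  expect_lt(max(abs(got - ref)) / max(ref), 1e-6)
})

test_that("kflux arithmetic and degenerate limits", {
  expect_equal(kineticFlux(kineticParams(0.2, 0.3, 0.1)), 0.05)
  expect_equal(kineticFlux(kineticParams(0.2, 0.3, 0)), 0)
  expect_equal(kineticFlux(kineticParams(0.2, 0, 0.1)), 0.2)
  expect_equal(kineticFlux(kineticParams(0, 0, 0)), 0)
  expect_error(kineticFlux(c(0.2, 0, 0)), NA)   # K1*k3 = 0: defined as 0
})

test_that("2C3K fitting recovers generating parameters", {
  aif <- defaultAIF()
  sched <- defaultFrameSchedule()
  kp <- kineticParams(0.2 / 60, 0.3 / 60, 0.1 / 60, Vb = 0.05)
  am <- dpet4d:::frameAveragesOfFun(function(t) compartmentTAC(kp, aif, t),
                                    sched)
  fit <- fit2C3K(am, aif, sched, polish = FALSE)
  got <- c(fit@K1, fit@k2, fit@k3, fit@Vb)
  tru <- c(kp@K1, kp@k2, kp@k3, kp@Vb)
  expect_lt(max(abs(got - tru) / tru), 0.01)
  expect_true(attr(fit, "ok"))
  ## zero TAC: all parameters zero with a clean flag
  f0 <- fit2C3K(rep(0, nFrames(sched)), aif, sched)
  expect_equal(c(f0@K1, f0@k2, f0@k3, f0@Vb), rep(0, 4))
  expect_true(attr(f0, "ok"))
  ## nested-model recovery: one-tissue truth gives k3 ~ 0
  kp1 <- kineticParams(0.15 / 60, 0.25 / 60, 0, Vb = 0.03)
  am1 <- dpet4d:::frameAveragesOfFun(function(t) compartmentTAC(kp1, aif, t),
                                     sched)
  fit1 <- fit2C3K(am1, aif, sched, polish = FALSE)
  expect_lt(fit1@k3, 1e-4)
})

test_that("compartment TACs agree with the ODE oracle over random draws", {
  skip_if_not_installed("deSolve")
  aif <- defaultAIF()
  tt <- seq(0, 1800, by = 2)
  set.seed(99)
  worst <- 0
  for (i in 1:50) {
    K1 <- runif(1, 0.02, 0.5) / 60
    k2 <- runif(1, 0.05, 0.6) / 60
    k3 <- runif(1, 0.001, 0.2) / 60
    Vb <- runif(1, 0, 0.3)
    if (i %% 2 == 0) {
      k4 <- runif(1, 0.005, 0.3) / 60
      k5 <- runif(1, 0.001, 0.1) / 60
      kp <- kineticParams(K1, k2, k3, k4, k5, Vb = Vb, model = "3C5K")
      f <- function(t, y, p)
        list(c(K1 * evalAIF(aif, t) - (k2 + k3) * y[1] + k4 * y[2],
               k3 * y[1] - (k4 + k5) * y[2], k5 * y[2]))
      sol <- deSolve::ode(c(0, 0, 0), tt, f, NULL, rtol = 1e-9, atol = 1e-9)
      ref <- Vb * evalAIF(aif, tt) + rowSums(sol[, 2:4])
    } else {
      kp <- kineticParams(K1, k2, k3, Vb = Vb)
      f <- function(t, y, p)
        list(c(K1 * evalAIF(aif, t) - (k2 + k3) * y[1], k3 * y[1]))
      sol <- deSolve::ode(c(0, 0), tt, f, NULL, rtol = 1e-9, atol = 1e-9)
      ref <- Vb * evalAIF(aif, tt) + sol[, 2] + sol[, 3]
    }
    got <- compartmentTAC(kp, aif, tt)
    worst <- max(worst, sqrt(sum((got - ref)^2) / sum(ref^2)))
  }
  expect_lt(worst, 1e-5)
})
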