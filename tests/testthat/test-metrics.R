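## TAC weighting, model-selection diagnostics, image and parametric
## quality metrics.

test_that("TAC fit weights follow the frame-duration/decay/activity rule", {
  fs <- frameSchedule(c(0, 30, 60), c(30, 60, 120), lambda = 0)
  ## lambda = 0, constant activity, equal durations: uniform DT/c
  fse <- frameSchedule(c(0, 30), c(30, 60), lambda = 0)
  expect_equal(tacFitWeights(fse, c(4, 4)), c(30 / 4, 30 / 4))
  ## doubling DT doubles the weight
  w1 <- tacFitWeights(frameSchedule(0, 30, lambda = 0), 5)
  w2 <- tacFitWeights(frameSchedule(0, 60, lambda = 0), 5)
  expect_equal(w2, 2 * w1)
  ## three-frame spreadsheet arithmetic with decay
  lam <- 1e-3
  fs3 <- frameSchedule(c(0, 30, 60), c(30, 60, 120), lambda = lam)
  a <- c(10, 25, 15)
  byHand <- c(30 * exp(-lam * 15) / 10,
              30 * exp(-lam * 45) / 25,
              60 * exp(-lam * 90) / 15)
  expect_equal(tacFitWeights(fs3, a), byHand, tolerance = 1e-12)
})

test_that("runs test: exact distribution cases and degenerate inputs", {
  ## perfectly alternating signs, n = 20: maximal runs, two-sided rejection
  alt <- rep(c(1, -1), 10)
  rt <- runsTest(alt)
  expect_equal(rt$runs, 20)
  expect_lt(rt$p, 0.05)
  expect_false(rt$pass)
  ## 10 positives then 10 negatives: 2 runs, overwhelming structure
  blk <- c(rep(1, 10), rep(-1, 10))
  rt2 <- runsTest(blk)
  expect_equal(rt2$runs, 2)
  expect_lt(rt2$p, 1e-4)
  ## exact pmf sums to one for assorted sample splits
  for (nn in list(c(5, 5), c(8, 3), c(10, 10)))
    expect_equal(sum(dpet4d:::runsPMF(nn[1], nn[2])), 1, tolerance = 1e-12)
  ## all one sign: fail with p = 0
  expect_false(runsTest(rep(1, 12))$pass)
  ## zeros count as positive (documented tie rule)
  expect_equal(runsTest(c(0, 0, -1, -1, 0, 0))$runs, 3)
})

test_that("LOO cross-validation scores held-out prediction error", {
  ## frame-wise mean model on (1, 2, 3) with unit-ish weights: held-out
  ## prediction is the mean of the other two
  w <- rep(0.7, 3)
  meanFitter <- function(values, weights, hold)
    rep(mean(values[-hold]), length(values))
  expect_equal(looCvRss(meanFitter, c(1, 2, 3), w), 4.5 * 0.7,
               tolerance = 1e-12)
  ## an interpolating model has zero in-sample RSS but positive LOO-RSS
  set.seed(2)
  y <- rnorm(8)
  interpFitter <- function(values, weights, hold) {
    idx <- seq_along(values)[-hold]
    approx(idx, values[idx], xout = seq_along(values), rule = 2)$y
  }
  expect_gt(looCvRss(interpFitter, y, rep(1, 8)), 0)
  ## failing folds are skipped with a warning
  bomb <- function(values, weights, hold)
    if (hold == 2) stop("boom") else rep(mean(values[-hold]), length(values))
  expect_warning(looCvRss(bomb, c(1, 2, 3), w), "skipped")
})

test_that("flexible models out-rank the 2C3K fit on realistic-like TACs", {
  sched <- defaultFrameSchedule()
  ph <- makeReferencePhantom("realistic_like", n = 16L)
  aif <- ph@aif
  f <- dpet4d:::regionTACFun(ph@regions$hypoxic_tumour, aif)
  am <- frameIntegrate(f, sched) / frameDurations(sched)
  w <- tacFitWeights(sched, am)
  fit2c <- function(values, weights, hold) {
    idx <- seq_along(values)[-hold]
    schedH <- frameSchedule(frameStarts(sched)[idx], frameEnds(sched)[idx],
                            decayConstant(sched), sched@tInj)
    ft <- fit2C3K(values[idx], aif, schedH, weights = weights[idx],
                  polish = FALSE)
    dpet4d:::frameAveragesOfFun(function(t) compartmentTAC(ft, aif, t),
                                sched)
  }
  ## 3C5K competitor: bounded Levenberg-Marquardt refit per fold, seeded
  ## from a single full-data fit
  pTrue <- ph@regions$hypoxic_tumour$params
  p0 <- c(pTrue@K1, pTrue@k2, pTrue@k3, pTrue@k4, pTrue@k5, pTrue@Vb) * 1.3
  fit3c <- function(values, weights, hold) {
    idx <- seq_along(values)[-hold]
    resid <- function(p) {
      kp <- kineticParams(p[1], p[2], p[3], p[4], p[5],
                          Vb = min(max(p[6], 0), 1), model = "3C5K")
      pred <- dpet4d:::frameAveragesOfFun(
        function(t) compartmentTAC(kp, aif, t), sched)
      sqrt(weights[idx]) * (values[idx] - pred[idx])
    }
    fit <- minpack.lm::nls.lm(par = p0, fn = resid, lower = rep(0, 6),
                              upper = c(rep(1, 5), 1),
                              control = minpack.lm::nls.lm.control(
                                maxiter = 60))
    kp <- kineticParams(fit$par[1], fit$par[2], fit$par[3], fit$par[4],
                        fit$par[5], Vb = fit$par[6], model = "3C5K")
    dpet4d:::frameAveragesOfFun(function(t) compartmentTAC(kp, aif, t),
                                sched)
  }
  rss2c <- looCvRss(fit2c, am, w)
  rss3c <- looCvRss(fit3c, am, w)
  expect_lt(rss3c, rss2c)
})

test_that("image bias: zero at truth, offset identity, hand example", {
  fs <- frameSchedule(c(0, 30), c(30, 90), lambda = 0)
  truth <- matrix(c(5, 7, 9, 11), 2, 2)
  ## recon == truth
  expect_equal(imageBias(list(truth, truth), truth, fs), c(0, 0))
  ## constant offset +c in every frame gives bias c
  expect_equal(imageBias(list(truth + 2.5), truth, fs), c(2.5, 2.5))
  ## hand example: DT = (30, 60), errors (1, -2) -> (30 + 120)/90 = 5/3
  one <- truth; one[1, ] <- truth[1, ] + c(1, -2)
  expect_equal(imageBias(list(one), truth, fs)[1], 5 / 3)
})

test_that("image noise: weighted SD arithmetic and scaling", {
  fs <- frameSchedule(c(0, 30), c(30, 90), lambda = 0)
  truth <- matrix(c(4, 4, 16, 16), 2, 2)
  ## identical realizations: zero noise
  expect_equal(imageNoise(list(truth, truth), truth, fs), c(0, 0))
  ## two realizations +/- d in one frame: sigma2 = 2 d^2 (n-1), and the
  ## printed weighting gives sigma_w = d sqrt(2 DT / a_true)
  d <- 3
  r1 <- truth; r2 <- truth
  r1[1, 1] <- truth[1, 1] + d; r2[1, 1] <- truth[1, 1] - d
  got <- imageNoise(list(r1, r2), truth, fs)
  expect_equal(got[1], (d * sqrt(2) * sqrt(30 / 4)) / 2)  # mean over 2 frames
  expect_equal(got[2], 0)
  ## doubling DT of the affected frame scales its sigma_w by sqrt(2)
  fs2 <- frameSchedule(c(0, 60), c(60, 120), lambda = 0)
  got2 <- imageNoise(list(r1, r2), truth, fs2)
  expect_equal(got2[1], got[1] * sqrt(2))
  ## reciprocal orientation inverts the weighting
  gotR <- imageNoise(list(r1, r2), truth, fs, orientation = "reciprocal")
  expect_equal(gotR[1], (d * sqrt(2) * sqrt(4 / 30)) / 2)
})

test_that("TMSE trace: hand values and monotone shrinkage", {
  fs <- frameSchedule(0, 30, lambda = 0)
  truth <- matrix(8, 1, 1)
  ## single voxel/frame, two realizations with errors (1, -1): MSE = 1
  s1 <- truth + 1; s2 <- truth - 1
  tt <- tmseTrace(list(list(s1, s2)), truth, fs)
  expect_equal(tt$tmse, 30 / 8)
  ## perfect reconstruction
  expect_equal(tmseTrace(list(list(truth, truth)), truth, fs)$tmse, 0)
  ## proportional error shrinkage shrinks TMSE and the fractional change
  ## is positive
  tt3 <- tmseTrace(list(list(truth + 2), list(truth + 1),
                        list(truth + 0.5)), truth, fs)
  expect_true(all(diff(tt3$tmse) < 0))
  expect_true(all(tt3$fractionalChange > 0))
  expect_true(is.na(tt3$change30to40))
})

test_that("ordering invariance of the metric reductions", {
  fs <- frameSchedule(c(0, 30, 60), c(30, 60, 120), lambda = 0)
  set.seed(14)
  truth <- matrix(runif(12, 5, 10), 4, 3)
  stack <- lapply(1:3, function(r) truth + matrix(rnorm(12), 4, 3))
  bias <- imageBias(stack, truth, fs)
  noise <- imageNoise(stack, truth, fs)
  perm <- c(3, 1, 2)
  expect_equal(imageBias(stack[perm], truth, fs), bias)
  expect_equal(imageNoise(stack[perm], truth, fs), noise)
  vperm <- c(4, 2, 1, 3)
  stackV <- lapply(stack, function(m) m[vperm, ])
  expect_equal(imageBias(stackV, truth[vperm, ], fs), bias[vperm])
  ## region summaries sit between the per-voxel extremes (up to the
  ## normalization constant)
  s <- regionSummary(bias, 1:4, truth)
  ref <- mean(truth)
  expect_gte(s, 100 * min(bias) / ref)
  expect_lte(s, 100 * max(bias) / ref)
})

test_that("restriction to an early window is consistent", {
  ## truncating the schedule to its own full span reproduces the
  ## full-scan metric values
  fs <- frameSchedule(c(0, 30, 60), c(30, 60, 120), lambda = 0)
  sel <- dpet4d:::restrictToWindow(fs, 120)
  expect_equal(sel, 1:3)
  expect_equal(dpet4d:::restrictToWindow(fs, 60), 1:2)
})

test_that("parametric maps recover noiseless kinetics and flag masks", {
  ph <- makeReferencePhantom("simplified", n = 32L)
  sched <- defaultFrameSchedule()
  tr <- groundTruthActivity(ph, sched)
  sub <- phantomSubRegion(ph)
  pm <- parametricMap(tr, ph@aif, sub)
  expect_equal(nrow(pm), length(sub))
  lab <- as.vector(regionLabels(ph))[sub]
  for (L in c(5, 6)) {
    nm <- if (L == 5) "normoxic_tumour" else "hypoxic_tumour"
    p <- ph@regions[[nm]]$params
    tru <- c(p@K1, p@k2, p@k3, p@Vb, kineticFlux(p))
    est <- colMeans(pm[lab == L, , drop = FALSE])
    expect_lt(max(abs(est - tru) / pmax(tru, 1e-9)), 0.01)
  }
  ## blood voxels: Vb = 1, vanishing flux
  trFull <- groundTruthActivity(ph, sched)
  blood <- which(as.vector(regionLabels(ph)) == 4L)
  pmB <- parametricMap(trFull, ph@aif, blood)
  expect_true(all(pmB[, "kflux"] < 1e-5))
  expect_true(all(pmB[, "Vb"] > 0.99))
  ## masked-out voxels are absent
  expect_equal(rownames(pm), as.character(sub))
})

test_that("parameter bias/noise summaries follow the n-1 convention", {
  truthP <- cbind(K1 = c(0.1, 0.2), kflux = c(0.01, 0.02))
  ## maps identical to truth
  pb <- parameterBiasNoise(list(truthP, truthP), truthP)
  expect_equal(unname(pb$meanBias), c(0, 0))
  expect_equal(unname(pb$meanSd), c(0, 0))
  ## q = truth +/- d: zero bias, SD = d sqrt(2)
  d <- 0.003
  pb2 <- parameterBiasNoise(list(truthP + d, truthP - d), truthP)
  expect_equal(unname(pb2$meanBias), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(pb2$meanSd), rep(d * sqrt(2), 2), tolerance = 1e-12)
  ## self-normalization of any algorithm against itself is unity
  expect_equal(unname(pb2$meanSd / pb2$meanSd), c(1, 1))
})
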