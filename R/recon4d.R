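## Conventional MAP and nested-MAP 4D reconstruction drivers.

#' Reconstruction configuration
#'
#' @param nIter number of outer iterations (default 30).
#' @param beta spatial regularization weight (default 0.1).
#' @param delta Lange parameter (default 0.1, count-domain units).
#' @param penalty temporal penalty kind: "L2", "d2" or "none".
#' @param gammaGrid candidate temporal weights for per-voxel GCV selection
#'   (default 0.001, 0.002, ..., 0.01).
#' @param fixedGamma NULL for GCV selection, or a scalar / per-voxel vector
#'   of fixed temporal weights.
#' @param init initial activity concentration (Bq/cc, default 100).
#' @param weightFloorFrac floor for the WLS weights 1/x, as a fraction of
#'   each frame's mean predicted value (default 1e-3).
#' @param calibration counts/activity calibration (the `calibration`
#'   element of [simulateScan()]); [defaultCalibration()] if NULL.
#' @param keepIterates store the activity image of every iteration.
#' @param knots for the spline model: "adaptive" (voxel-specific knots from
#'   a conventional-MAP prepass) or a shared [KnotVector-class].
#' @param nFreeKnots free knots for adaptive placement (default 11).
#' @param prepassIter iterations of the conventional-MAP prepass used for
#'   adaptive knot placement (default 30, a fully run conventional
#'   reconstruction: knot densities read from an under-iterated prepass
#'   concentrate pathologically in the bolus and destabilize the fit).
#' @param alphaGrid profile grid for the 2C3K temporal model.
#' @return a validated configuration list.
#' @export
reconConfig <- function(nIter = 30L, beta = 0.1, delta = 0.1,
                        penalty = c("L2", "none", "d2"),
                        gammaGrid = seq(0.001, 0.01, by = 0.001),
                        fixedGamma = NULL, init = 100,
                        weightFloorFrac = 1e-3, calibration = NULL,
                        keepIterates = FALSE, knots = "adaptive",
                        nFreeKnots = 11L, prepassIter = 30L,
                        alphaGrid = defaultAlphaGrid()) {
  penalty <- match.arg(penalty)
  stopifnot(nIter >= 1, beta >= 0, delta > 0, init >= 0,
            all(gammaGrid > 0), penalty == "none" || length(gammaGrid) >= 1)
  list(nIter = as.integer(nIter), beta = beta, delta = delta,
       penalty = penalty, gammaGrid = sort(gammaGrid),
       fixedGamma = fixedGamma, init = init,
       weightFloorFrac = weightFloorFrac, calibration = calibration,
       keepIterates = keepIterates, knots = knots,
       nFreeKnots = as.integer(nFreeKnots),
       prepassIter = as.integer(prepassIter), alphaGrid = alphaGrid)
}

#' @describeIn reconConfig a unit calibration in which count-domain images
#'   equal activity times frame duration (scal = voxelVolume = 1).
#' @param sched a [FrameSchedule-class].
#' @export
defaultCalibration <- function(sched) {
  list(scal = 1, voxelVolume = 1, frameFactors = frameDurations(sched))
}

## single-realization squared-error trace entry (time-weighted, truth-
## normalized; the multi-realization TMSE averages squared errors first)
tmseSingle <- function(a, atrue, dur) {
  ok <- atrue > 0
  sum((rep(dur, each = nrow(a)) * (a - atrue)^2 / pmax(atrue, 1e-300))[ok])
}

#' Conventional (frame-independent) MAP reconstruction
#'
#' Reconstructs every frame independently with the optimization-transfer
#' MAP update ([mapUpdate()]): no temporal model, no coupling between
#' frames beyond the shared initialization.
#'
#' @param sino a [SinogramSeries-class].
#' @param P system matrix.
#' @param config a [reconConfig()] list.
#' @param truth optional [ImageSeries-class] ground truth for error traces.
#' @return a [ReconResult-class].
#' @export
conventionalMAPReconstruct <- function(sino, P, config = reconConfig(),
                                       truth = NULL) {
  sched <- schedule(sino)
  cal <- config$calibration
  if (is.null(cal)) cal <- defaultCalibration(sched)
  y <- counts(sino); eps <- background(sino)
  nv <- ncol(P)
  n <- as.integer(round(sqrt(nv)))
  nbr <- neighbourStructure(n)
  dead <- deadVoxels(P)
  X <- activityToCounts(matrix(config$init, nv, nFrames(sched)), cal)
  X[dead, ] <- 0
  obj <- numeric(config$nIter)
  tmse <- numeric(0)
  iters <- list()
  dur <- frameDurations(sched)
  for (it in seq_len(config$nIter)) {
    X <- mapUpdate(X, P, y, eps, beta = config$beta, delta = config$delta,
                   nbr = nbr)
    ll <- poissonLogLik(y, as.matrix(P %*% X) + eps)
    pen <- if (config$beta > 0)
      sum(vapply(seq_len(ncol(X)), function(m)
        langePenalty(X[, m], config$delta, nbr), numeric(1)))
    else 0
    obj[it] <- ll - config$beta * pen
    a <- countsToActivity(X, cal)
    if (!is.null(truth)) tmse <- c(tmse, tmseSingle(a, truth@values, dur))
    if (config$keepIterates) iters[[it]] <- a
  }
  new("ReconResult",
      images = new("ImageSeries", values = countsToActivity(X, cal), n = n,
                   voxelSize = geometry(sino)@voxelSize, schedule = sched),
      theta = matrix(0, 0, 0), gammaSel = numeric(0), objective = obj,
      tmse = tmse, iterates = iters,
      config = c(config, list(algorithm = "map")), algorithm = "map")
}

## Vectorized bounded least squares for the 3-coefficient 2C3K design:
## minimize -2 b'c + c'Mc subject to c1 in [0, 1] (blood fraction),
## c2, c3 >= 0.  The convex QP optimum lies on one of the 12 faces of the
## feasible box; every face solve is closed form and vectorized over
## voxels.  M given as columns (11, 12, 13, 22, 23, 33) per voxel.
## Returns coef (nv x 3) and the minimized quadratic form -2b'c + c'Mc.
boundedLS3 <- function(M, b) {
  nv <- nrow(M)
  a11 <- M[, 1]; a12 <- M[, 2]; a13 <- M[, 3]
  a22 <- M[, 4]; a23 <- M[, 5]; a33 <- M[, 6]
  b1 <- b[, 1]; b2 <- b[, 2]; b3 <- b[, 3]
  bestQ <- rep(0, nv)                  # face c = 0 is always feasible
  bestC <- matrix(0, nv, 3)
  tol <- 1e-9
  consider <- function(c1, c2, c3) {
    feas <- is.finite(c1) & is.finite(c2) & is.finite(c3) &
      c1 >= -tol & c1 <= 1 + tol & c2 >= -tol & c3 >= -tol
    c1 <- pmin(pmax(c1, 0), 1); c2 <- pmax(c2, 0); c3 <- pmax(c3, 0)
    q <- -2 * (b1 * c1 + b2 * c2 + b3 * c3) +
      c1^2 * a11 + c2^2 * a22 + c3^2 * a33 +
      2 * (c1 * c2 * a12 + c1 * c3 * a13 + c2 * c3 * a23)
    take <- feas & q < bestQ
    if (any(take)) {
      bestQ[take] <<- q[take]
      bestC[take, ] <<- cbind(c1, c2, c3)[take, , drop = FALSE]
    }
  }
  solve2 <- function(p, q, r, u, v) {    # [[p, q], [q, r]] c = (u, v)
    det <- p * r - q^2
    det[abs(det) < 1e-300] <- NA
    list(x = (r * u - q * v) / det, y = (p * v - q * u) / det)
  }
  ## full interior (Cramer)
  c11 <- a22 * a33 - a23^2; c12 <- a13 * a23 - a12 * a33
  c13 <- a12 * a23 - a13 * a22; c22 <- a11 * a33 - a13^2
  c23 <- a12 * a13 - a11 * a23; c33 <- a11 * a22 - a12^2
  det3 <- a11 * c11 + a12 * c12 + a13 * c13
  det3[abs(det3) < 1e-300] <- NA
  consider((c11 * b1 + c12 * b2 + c13 * b3) / det3,
           (c12 * b1 + c22 * b2 + c23 * b3) / det3,
           (c13 * b1 + c23 * b2 + c33 * b3) / det3)
  ## one coefficient pinned
  s <- solve2(a22, a23, a33, b2, b3);           consider(rep(0, nv), s$x, s$y)
  s <- solve2(a22, a23, a33, b2 - a12, b3 - a13); consider(rep(1, nv), s$x, s$y)
  s <- solve2(a11, a13, a33, b1, b3);           consider(s$x, rep(0, nv), s$y)
  s <- solve2(a11, a12, a22, b1, b2);           consider(s$x, s$y, rep(0, nv))
  ## two pinned
  z <- rep(0, nv); o <- rep(1, nv)
  consider(b1 / ifelse(a11 > 0, a11, NA), z, z)
  consider(z, b2 / ifelse(a22 > 0, a22, NA), z)
  consider(z, z, b3 / ifelse(a33 > 0, a33, NA))
  consider(o, (b2 - a12) / ifelse(a22 > 0, a22, NA), z)
  consider(o, z, (b3 - a13) / ifelse(a33 > 0, a33, NA))
  consider(o, z, z)
  list(coef = bestC, qform = bestQ)
}

## one E(alpha) design column (counts units when design carries `fac`)
designColumn <- function(design, alpha) {
  col <- frameAveragesOfFun(aifConvExpFun(design$aif, alpha), design$sched,
                            design$dt)
  if (!is.null(design$fac)) col <- col * design$fac
  col
}

## batch 2C3K variable-projection fit for all voxels; design from
## tcmDesign() in counts units.  `refine` zoom rounds shrink the alpha
## bracket around each voxel's best grid value (each round narrows the
## spacing by the cube root).  Returns list(params, pred).
fit2C3KBatch <- function(Xhat, W, design, refine = 0L) {
  nv <- nrow(Xhat); nt <- ncol(Xhat)
  WX <- W * Xhat
  sumWX2 <- rowSums(W * Xhat^2)
  bestRSS <- rep(Inf, nv)
  bestCoef <- matrix(0, nv, 3)
  bestAlpha <- rep(design$alpha[1], nv)
  bestE <- matrix(0, nv, nt)
  scan <- function(alphas, Ecols, rows) {
    for (i in seq_along(alphas)) {
      X <- cbind(design$A0, Ecols[, i], design$U)
      XX <- cbind(X[, 1]^2, X[, 1] * X[, 2], X[, 1] * X[, 3],
                  X[, 2]^2, X[, 2] * X[, 3], X[, 3]^2)
      M <- W[rows, , drop = FALSE] %*% XX   # (11,12,13,22,23,33)
      b <- WX[rows, , drop = FALSE] %*% X
      sol <- boundedLS3(M, b)
      rss <- sumWX2[rows] + sol$qform
      better <- rss < bestRSS[rows] - 1e-12
      if (any(better)) {
        rb <- rows[better]
        bestRSS[rb] <<- rss[better]
        bestCoef[rb, ] <<- sol$coef[better, , drop = FALSE]
        bestAlpha[rb] <<- alphas[i]
        bestE[rb, ] <<- matrix(Ecols[, i], length(rb), nt, byrow = TRUE)
      }
    }
  }
  scan(design$alpha, design$E, seq_len(nv))
  step <- (design$alpha[2] / design$alpha[1])
  for (round in seq_len(refine)) {
    for (a in unique(bestAlpha)) {
      rows <- which(bestAlpha == a)
      alphas <- exp(seq(log(a / step), log(a * step), length.out = 7))
      Ecols <- vapply(alphas, function(x) designColumn(design, x),
                      numeric(nt))
      scan(alphas, Ecols, rows)
    }
    step <- step^(1 / 3)
  }
  K1 <- bestCoef[, 2] + bestCoef[, 3]
  k2 <- ifelse(K1 > 0, bestAlpha * bestCoef[, 2] / K1, 0)
  k3 <- ifelse(K1 > 0, bestAlpha * bestCoef[, 3] / K1, 0)
  params <- cbind(K1 = K1, k2 = k2, k3 = k3, Vb = bestCoef[, 1])
  pred <- bestCoef[, 1] %o% design$A0 + bestCoef[, 2] * bestE +
    bestCoef[, 3] %o% design$U
  list(params = params, pred = pred)
}

#' Nested-MAP 4D reconstruction
#'
#' Alternates one MAP image update per frame with a per-voxel temporal-model
#' fit, re-seeding the next MAP update with the model-predicted TACs:
#' \enumerate{
#'   \item initialize every voxel at `config$init` Bq/cc;
#'   \item update each frame with one optimization-transfer MAP iteration;
#'   \item fit the temporal model to every voxel TAC by penalized weighted
#'     least squares (weights 1/x from the current model prediction,
#'     floored), selecting the temporal weight per voxel by GCV for linear
#'     models; the 2C3K model is fitted by its profiled WLS solver with no
#'     temporal penalty;
#'   \item replace the voxel TACs by the fitted model predictions and
#'     return to step 2.
#' }
#' Basis columns are normalized to unit maximum in the count domain before
#' fitting, which keeps one gamma grid meaningful across models; the d2
#' penalty matrix is rescaled accordingly and normalized to unit maximal
#' diagonal.  If the data objective drops for 5 consecutive iterations the
#' loop stops early with a warning (convergence of the WLS-coupled
#' iteration is empirical, not guaranteed).
#'
#' @param sino a [SinogramSeries-class].
#' @param P system matrix.
#' @param model "spline_residue", "spectral", "spline" or "2c3k".
#' @param config a [reconConfig()] list.
#' @param aif the arterial input function (required for all models except
#'   "spline").
#' @param truth optional [ImageSeries-class] for error traces.
#' @param basis optional pre-built [BasisMatrix-class] overriding the
#'   model's default basis construction.
#' @return a [ReconResult-class]; for linear models `theta` holds the
#'   normalized-basis coefficients and the normalized count-domain basis is
#'   returned in `config$basisNormalized`; for "2c3k", `theta` has columns
#'   (K1, k2, k3, Vb) in 1/s.
#' @export
nestedMAPReconstruct <- function(sino, P,
                                 model = c("spline_residue", "spectral",
                                           "spline", "2c3k"),
                                 config = reconConfig(), aif = NULL,
                                 truth = NULL, basis = NULL) {
  model <- match.arg(model)
  sched <- schedule(sino)
  cal <- config$calibration
  if (is.null(cal)) cal <- defaultCalibration(sched)
  y <- counts(sino); eps <- background(sino)
  nv <- ncol(P); nt <- nFrames(sched)
  n <- as.integer(round(sqrt(nv)))
  nbr <- neighbourStructure(n)
  dead <- deadVoxels(P)
  live <- setdiff(seq_len(nv), dead)
  countScale <- cal$scal * cal$voxelVolume
  dur <- frameDurations(sched)

  if (model != "spline" && model != "2c3k" && is.null(basis) && is.null(aif))
    stop("model '", model, "' requires an AIF")
  if (model == "2c3k" && is.null(aif))
    stop("the 2C3K temporal model requires an AIF")

  perVoxelBases <- NULL
  design <- NULL
  Bn <- NULL; On <- NULL; colScale <- NULL
  if (model == "2c3k") {
    design <- tcmDesign(aif, sched, config$alphaGrid)
    ## convert the design columns to count-domain frame values
    design$fac <- cal$frameFactors
    design$A0 <- design$A0 * design$fac
    design$U <- design$U * design$fac
    design$E <- design$E * design$fac
  } else if (model == "spline" && is.null(basis) &&
             identical(config$knots, "adaptive")) {
    ## conventional-MAP prepass supplies the per-voxel TACs for knots
    pre <- conventionalMAPReconstruct(sino, P, modifyList(
      config, list(nIter = config$prepassIter, keepIterates = FALSE)))
    preA <- pre@images@values
    perVoxelBases <- lapply(seq_len(nv), function(j) {
      if (!(j %in% live)) return(NULL)
      kv <- adaptiveKnots(preA[j, ], sched, nFree = config$nFreeKnots)
      bs <- buildBasis("spline", sched, knots = kv)
      ## the global count scaling cancels in the unit-diagonal normalization
      normalizeBasis(bs@B * countScale,
                     if (config$penalty == "d2") d2GramSpline(kv) else NULL,
                     config$penalty)
    })
  } else {
    if (is.null(basis)) {
      basis <- switch(model,
        spline_residue = buildBasis("spline_residue", sched, aif = aif),
        spectral = buildBasis("spectral", sched, aif = aif),
        spline = buildBasis("spline", sched, knots = config$knots))
    }
    Om <- if (config$penalty == "d2") penaltyMatrix(basis, "d2") else NULL
    nb <- normalizeBasis(basis@B * countScale, Om, config$penalty)
    Bn <- nb$B; On <- nb$Omega; colScale <- nb$scale
  }

  Xpred <- activityToCounts(matrix(config$init, nv, nt), cal)
  Xpred[dead, ] <- 0
  obj <- numeric(0)
  tmse <- numeric(0)
  iters <- list()
  theta <- NULL; gam <- numeric(0)
  drops <- 0
  for (it in seq_len(config$nIter)) {
    Xcur <- pmax(Xpred, 0)
    Xhat <- mapUpdate(Xcur, P, y, eps, beta = config$beta,
                      delta = config$delta, nbr = nbr)
    ## Eq-17-style weights from the current model prediction, floored
    floorM <- config$weightFloorFrac *
      pmax(colMeans(Xcur[live, , drop = FALSE]), 1e-12)
    W <- 1 / pmax(Xcur, rep(floorM, each = nv))
    if (model == "2c3k") {
      fit <- fit2C3KBatch(Xhat[live, , drop = FALSE],
                          W[live, , drop = FALSE], design)
      theta <- matrix(0, nv, 4, dimnames = list(NULL, colnames(fit$params)))
      theta[live, ] <- fit$params
      predLive <- fit$pred
    } else if (!is.null(perVoxelBases)) {
      theta <- NULL                      # per-voxel bases: thetas not square
      predLive <- matrix(0, length(live), nt)
      gam <- numeric(nv)
      for (q in seq_along(live)) {
        j <- live[q]
        bs <- perVoxelBases[[j]]
        f <- gcvFitBatch(bs$B, Xhat[j, , drop = FALSE],
                         W[j, , drop = FALSE], bs$Omega, config$gammaGrid,
                         fixedGamma = config$fixedGamma,
                         penalty = config$penalty != "none")
        predLive[q, ] <- f$pred
        gam[j] <- f$gamma
      }
    } else {
      f <- gcvFitBatch(Bn, Xhat[live, , drop = FALSE],
                       W[live, , drop = FALSE], On, config$gammaGrid,
                       fixedGamma = config$fixedGamma,
                       penalty = config$penalty != "none")
      theta <- matrix(0, nv, ncol(Bn))
      theta[live, ] <- f$theta
      predLive <- f$pred
      gam <- numeric(nv); gam[live] <- f$gamma
    }
    Xpred <- matrix(0, nv, nt)
    Xpred[live, ] <- predLive
    ll <- poissonLogLik(y, as.matrix(P %*% pmax(Xpred, 0)) + eps)
    obj <- c(obj, ll)
    if (length(obj) > 1 && ll < obj[length(obj) - 1]) {
      drops <- drops + 1
      if (drops >= 5) {
        warning("objective decreased for 5 consecutive iterations; stopping")
        a <- countsToActivity(Xpred, cal)
        if (!is.null(truth)) tmse <- c(tmse, tmseSingle(a, truth@values, dur))
        if (config$keepIterates) iters[[it]] <- a
        break
      }
    } else drops <- 0
    a <- countsToActivity(Xpred, cal)
    if (!is.null(truth)) tmse <- c(tmse, tmseSingle(a, truth@values, dur))
    if (config$keepIterates) iters[[it]] <- a
  }
  if (is.null(theta)) theta <- matrix(0, 0, 0)
  new("ReconResult",
      images = new("ImageSeries", values = countsToActivity(Xpred, cal),
                   n = n, voxelSize = geometry(sino)@voxelSize,
                   schedule = sched),
      theta = theta, gammaSel = gam, objective = obj, tmse = tmse,
      iterates = iters,
      config = c(config, list(algorithm = "nested", model = model,
                              basisNormalized = Bn, basisScale = colScale)),
      algorithm = "nested")
}

## normalize count-domain basis columns to unit maximum absolute value and
## rescale/normalize the d2 penalty consistently (unit maximal diagonal)
normalizeBasis <- function(Bc, Omega, penalty) {
  sc <- apply(abs(Bc), 2, max)
  sc[sc == 0] <- 1
  Bn <- sweep(Bc, 2, sc, "/")
  On <- NULL
  if (penalty == "d2") {
    if (is.null(Omega)) stop("d2 penalty needs a penalty matrix")
    On <- Omega / outer(sc, sc)
    m <- max(diag(On))
    if (m > 0) On <- On / m
  } else if (penalty == "L2") {
    On <- diag(ncol(Bn))
  }
  list(B = Bn, Omega = On, scale = sc)
}
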