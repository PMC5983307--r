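## End-to-end experiment driver: simulate -> reconstruct (algorithm grid,
## shared sinograms) -> metrics, reproducible from a manifest.

#' Specify a reconstruction comparison experiment
#'
#' @param phantom "simplified" or "realistic_like".
#' @param n image grid side (desk default 32; 64 matches the full phantom).
#' @param realizations number of Poisson noise realizations R (desk default
#'   10; >= 2 whenever noise metrics are requested).
#' @param nIter reconstruction iterations (desk default 10).
#' @param algorithms list of algorithm descriptors: each a list with unique
#'   `id`, `algo` ("map" or "nested"), and for nested ones `model`
#'   ("spline_residue", "spectral", "spline", "2c3k") and optional
#'   `penalty` ("L2", "none", "d2") and `fixedGamma`.
#' @param seed base RNG seed; realization r draws with seed + r.
#' @param nAngles,nBins scanner geometry (defaults scale with n).
#' @param targetCounts expected total counts per realization.
#' @param bgFrac background fraction.
#' @param computeTMSE record per-iteration images and TMSE traces.
#' @param parametric compute 2C3K parametric maps over the tumour
#'   sub-region.
#' @param noiseMetrics compute across-realization image noise (needs R >= 2).
#' @param outDir optional directory for per-(algorithm, realization)
#'   checkpoints, making interrupted runs resumable.
#' @return a validated experiment specification list.
#' @export
experimentSpec <- function(phantom = c("simplified", "realistic_like"),
                           n = 32L, realizations = 10L, nIter = 10L,
                           algorithms = defaultAlgorithms(),
                           seed = 1L,
                           nAngles = max(48L, as.integer(round(n * 0.94))),
                           nBins = 2L * (n %/% 2L) + 31L,
                           targetCounts = 3.5e6, bgFrac = 0.2,
                           computeTMSE = FALSE, parametric = TRUE,
                           noiseMetrics = TRUE, outDir = NULL) {
  phantom <- match.arg(phantom)
  ids <- vapply(algorithms, function(a) a$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate algorithm ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  if (noiseMetrics && realizations < 2)
    stop("noise metrics need at least 2 realizations; set noiseMetrics = FALSE",
         " or raise `realizations`")
  list(phantom = phantom, n = as.integer(n),
       realizations = as.integer(realizations), nIter = as.integer(nIter),
       algorithms = algorithms, seed = as.integer(seed),
       nAngles = as.integer(nAngles), nBins = as.integer(nBins),
       targetCounts = targetCounts, bgFrac = bgFrac,
       computeTMSE = computeTMSE, parametric = parametric,
       noiseMetrics = noiseMetrics, outDir = outDir)
}

#' @describeIn experimentSpec the full algorithm roster: conventional MAP
#'   plus nested-MAP with the 2C3K, adaptive-knot spline (d2 penalty),
#'   spectral (L2) and spline-residue (L2) temporal models, each with its
#'   preferred temporal penalty.
#' @export
defaultAlgorithms <- function() {
  list(list(id = "map", algo = "map"),
       list(id = "nested_2c3k", algo = "nested", model = "2c3k"),
       list(id = "nested_spline", algo = "nested", model = "spline",
            penalty = "d2"),
       list(id = "nested_spectral", algo = "nested", model = "spectral",
            penalty = "L2"),
       list(id = "nested_spline_residue", algo = "nested",
            model = "spline_residue", penalty = "L2"))
}

#' Run a reconstruction comparison experiment
#'
#' Simulates the phantom once, draws `realizations` Poisson realizations of
#' the sinograms (seeds bound to the realization index, so any scheduling
#' or resumption yields identical results), reconstructs each with every
#' algorithm in the grid, and assembles the image-quality and parametric
#' metrics.
#'
#' @param spec an [experimentSpec()] list.
#' @return a list with elements `spec`, `sim` (the [simulateScan()] bundle),
#'   `truthParams`, per-algorithm `results` (final images, image bias/noise
#'   summaries, kflux bias/noise, TMSE traces when requested), and
#'   `manifest` (seeds and configuration for replay).  Per-stage failures
#'   are recorded per (algorithm, realization) in `failures` without
#'   aborting the grid.
#' @export
runExperiment <- function(spec) {
  ph <- makeReferencePhantom(spec$phantom, n = spec$n)
  sched <- defaultFrameSchedule()
  geom <- scannerGeometry(nAngles = spec$nAngles, nBins = spec$nBins,
                          n = spec$n)
  sim <- simulateScan(ph, sched, geom, targetCounts = spec$targetCounts,
                      bgFrac = spec$bgFrac)
  aif <- ph@aif
  masks <- phantomMasks(ph)
  sub <- phantomSubRegion(ph)
  ## pre-build shared bases once
  bases <- list()
  models <- unique(unlist(lapply(spec$algorithms, function(a) a$model)))
  if ("spline_residue" %in% models)
    bases$spline_residue <- buildBasis("spline_residue", sched, aif = aif)
  if ("spectral" %in% models)
    bases$spectral <- buildBasis("spectral", sched, aif = aif)
  design <- if (spec$parametric) tcmDesign(aif, sched, defaultAlphaGrid())
            else NULL
  truthParams <- if (spec$parametric)
    parametricMap(sim$truth, aif, sub, design = design) else NULL

  failures <- list()
  recons <- list()    # recons[[id]]: list over realizations
  for (r in seq_len(spec$realizations)) {
    sino <- samplePoisson(sim, seed = spec$seed + r)
    for (a in spec$algorithms) {
      key <- a$id
      ckpt <- if (!is.null(spec$outDir))
        file.path(spec$outDir, sprintf("%s_r%03d.rds", key, r)) else NULL
      res <- NULL
      if (!is.null(ckpt) && file.exists(ckpt)) {
        res <- readRDS(ckpt)
      } else {
        cfg <- reconConfig(nIter = spec$nIter,
                           penalty = if (is.null(a$penalty)) "L2" else a$penalty,
                           fixedGamma = a$fixedGamma,
                           calibration = sim$calibration,
                           keepIterates = spec$computeTMSE)
        res <- tryCatch({
          if (a$algo == "map") {
            conventionalMAPReconstruct(sino, sim$P, cfg)
          } else {
            nestedMAPReconstruct(sino, sim$P, model = a$model, config = cfg,
                                 aif = aif, basis = bases[[a$model]])
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            list(algorithm = key, realization = r,
                 message = conditionMessage(res))
          next
        }
        if (!is.null(ckpt)) {
          dir.create(dirname(ckpt), showWarnings = FALSE, recursive = TRUE)
          saveRDS(res, ckpt)
        }
      }
      recons[[key]] <- c(recons[[key]], list(res))
    }
  }

  results <- list()
  for (a in spec$algorithms) {
    rl <- recons[[a$id]]
    if (is.null(rl)) next
    finals <- lapply(rl, function(x) x@images@values)
    out <- list(id = a$id, finalImages = finals)
    out$imageBias <- imageBias(finals, sim$truth)
    out$summary <- list(
      biasPatientPct = regionSummary(out$imageBias, masks$patient, sim$truth),
      biasTumourPct = regionSummary(out$imageBias, masks$tumour, sim$truth))
    if (spec$noiseMetrics && length(finals) >= 2) {
      out$imageNoise <- imageNoise(finals, sim$truth)
      out$summary$noisePatientPct <-
        regionSummary(out$imageNoise, masks$patient, sim$truth)
      out$summary$noiseTumourPct <-
        regionSummary(out$imageNoise, masks$tumour, sim$truth)
      ## first-120 s variants
      sel <- restrictToWindow(sched, 120)
      schedEarly <- frameSchedule(sched@start[sel], sched@end[sel],
                                  decayConstant(sched), sched@tInj)
      truthEarly <- sim$truth@values[, sel, drop = FALSE]
      stacksEarly <- lapply(finals, function(m) m[, sel, drop = FALSE])
      biasE <- imageBias(stacksEarly, truthEarly, schedEarly)
      noiseE <- imageNoise(stacksEarly, truthEarly, schedEarly)
      refE <- mean(truthEarly[masks$patient, ])
      out$summary$biasPatientEarlyPct <-
        100 * mean(biasE[masks$patient]) / refE
      out$summary$noisePatientEarlyPct <-
        100 * mean(noiseE[masks$patient], na.rm = TRUE) / refE
    }
    if (spec$computeTMSE) {
      nIt <- min(vapply(rl, function(x) length(x@iterates), integer(1)))
      iterStacks <- lapply(seq_len(nIt), function(it)
        lapply(rl, function(x) x@iterates[[it]]))
      out$tmse <- tmseTrace(iterStacks, sim$truth)
    }
    if (spec$parametric) {
      maps <- lapply(finals, function(m) {
        img <- new("ImageSeries", values = m, n = spec$n,
                   voxelSize = ph@voxelSize, schedule = sched)
        parametricMap(img, aif, sub, design = design)
      })
      pb <- parameterBiasNoise(maps, truthParams)
      kref <- mean(truthParams[, "kflux"])
      out$kflux <- list(
        biasPct = 100 * pb$meanBias[["kflux"]] / kref,
        absBiasPct = 100 * mean(abs(pb$bias[, "kflux"])) / kref,
        sdPct = if (spec$realizations >= 2)
          100 * pb$meanSd[["kflux"]] / kref else NA_real_,
        perParameter = pb)
    }
    results[[a$id]] <- out
  }
  list(spec = spec, sim = sim, truthParams = truthParams,
       results = results, failures = failures,
       manifest = list(seed = spec$seed,
                       realizationSeeds = spec$seed + seq_len(spec$realizations),
                       phantom = spec$phantom, n = spec$n,
                       nIter = spec$nIter, timestamp = format(Sys.time())))
}

#' Generate small pinned test fixtures
#'
#' Deterministic tiny instances (8 x 8 phantom, 6 frames, 12 x 17 sinogram)
#' written as plain-text files, together with a dense-matrix forward
#' projection oracle and a JSON manifest, for use by unit tests.
#'
#' @param seed RNG seed for the Poisson draw.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest list (also written as manifest.json).
#' @export
makeFixtures <- function(seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sched <- frameSchedule(c(0, 30, 60, 120, 300, 600),
                         c(30, 60, 120, 300, 600, 1200), tInj = 10)
  ph <- makeReferencePhantom("simplified", n = 8L, sched = sched)
  geom <- scannerGeometry(nAngles = 12L, nBins = 17L, n = 8L)
  sim <- simulateScan(ph, sched, geom, targetCounts = 2e4)
  sino <- samplePoisson(sim, seed = seed)
  writeMat <- function(m, f)
    write.table(format(as.matrix(m), digits = 17), file.path(dir, f),
                row.names = FALSE, col.names = FALSE, quote = FALSE,
                sep = "\t")
  writeMat(ph@labels, "labels.tsv")
  writeMat(sim$truth@values, "truth_activity.tsv")
  writeMat(counts(sino), "sinogram_counts.tsv")
  writeMat(background(sino), "sinogram_background.tsv")
  ## dense forward-projection oracle of the count-domain truth
  Xc <- activityToCounts(sim$truth@values, sim$calibration)
  dense <- as.matrix(sim$P)
  writeMat(dense %*% Xc + sim$eps, "forward_oracle.tsv")
  manifest <- list(seed = seed, n = 8L, frames = nFrames(sched),
                   nAngles = 12L, nBins = 17L,
                   schedule = list(start = sched@start, end = sched@end,
                                   lambda = decayConstant(sched),
                                   tInj = sched@tInj),
                   calibration = sim$calibration,
                   files = c("labels.tsv", "truth_activity.tsv",
                             "sinogram_counts.tsv",
                             "sinogram_background.tsv",
                             "forward_oracle.tsv"),
                   totalCounts = sum(counts(sino)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}
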