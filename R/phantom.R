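## Digital dynamic phantoms: thoracic-like 2D slice with blood, lung, bone,
## normoxic and hypoxic tumour regions plus soft-tissue background.

regionTACFun <- function(spec, aif) {
  switch(spec$model,
         aif = function(t) evalAIF(aif, t),
         `2C3K` = ,
         `3C5K` = {
           p <- spec$params
           function(t) compartmentTAC(p, aif, t)
         },
         tabulated = {
           f <- splinefun(spec$times, spec$values, method = "natural")
           rng <- range(spec$times)
           function(t) pmax(f(pmin(pmax(t, rng[1]), rng[2])), 0)
         },
         stop("region '", spec$name, "' has unknown TAC model: ", spec$model))
}

#' Ground-truth activity of a phantom over a frame schedule
#'
#' Frame-averaged, physically decayed activity per voxel:
#' \eqn{a_{jm} = \frac{1}{\Delta T_m}\int_{t_{ms}}^{t_{mf}} f_j(t)
#' e^{-\lambda t} dt}, with \eqn{f_j} the region TAC of voxel j.
#'
#' @param phantom a [Phantom-class].
#' @param sched a [FrameSchedule-class].
#' @return an [ImageSeries-class] of noise-free activity (Bq/cc).
#' @export
groundTruthActivity <- function(phantom, sched) {
  lab <- as.vector(phantom@labels)
  vals <- matrix(0, length(lab), nFrames(sched))
  for (r in phantom@regions) {
    hit <- lab == r$label
    if (!any(hit)) next          # region absent at this grid resolution
    f <- regionTACFun(r, phantom@aif)
    am <- frameIntegrate(f, sched) / frameDurations(sched)
    vals[hit, ] <- matrix(am, sum(hit), nFrames(sched), byrow = TRUE)
  }
  new("ImageSeries", values = vals, n = nrow(phantom@labels),
      voxelSize = phantom@voxelSize, schedule = sched)
}

## Region TAC frame averages as a named matrix (regions x frames)
regionFrameAverages <- function(phantom, sched) {
  t(vapply(phantom@regions, function(r)
    frameIntegrate(regionTACFun(r, phantom@aif), sched) / frameDurations(sched),
    numeric(nFrames(sched))))
}

inEllipse <- function(x, y, cx, cy, a, b) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1

## default per-region kinetics, rates in 1/min (converted to 1/s at use)
simplifiedKineticsTable <- function() {
  list(
    background = c(K1 = 0.09, k2 = 0.12, k3 = 0.002, Vb = 0.05),
    lung       = c(K1 = 0.06, k2 = 0.10, k3 = 0.001, Vb = 0.15),
    bone       = c(K1 = 0.07, k2 = 0.11, k3 = 0.003, Vb = 0.04),
    normoxic_tumour = c(K1 = 0.22, k2 = 0.25, k3 = 0.004, Vb = 0.08),
    hypoxic_tumour  = c(K1 = 0.20, k2 = 0.18, k3 = 0.012, Vb = 0.06))
}

realisticKineticsTable <- function() {
  ## tumours: irreversible three-tissue with a strongly reversible middle
  ## exchange, giving peaked TACs the 2C3K model cannot follow; normal
  ## tissues: reversible two-tissue shapes, tabulated
  list(
    background = c(K1 = 0.09, k2 = 0.12, k3 = 0.05, k4 = 0.035, k5 = 0),
    lung       = c(K1 = 0.06, k2 = 0.10, k3 = 0.06, k4 = 0.030, k5 = 0),
    bone       = c(K1 = 0.07, k2 = 0.11, k3 = 0.05, k4 = 0.025, k5 = 0),
    normoxic_tumour = c(K1 = 0.22, k2 = 0.25, k3 = 0.10, k4 = 0.12, k5 = 0.004),
    hypoxic_tumour  = c(K1 = 0.20, k2 = 0.18, k3 = 0.12, k4 = 0.08, k5 = 0.012))
}

vbTable <- c(background = 0.05, lung = 0.15, bone = 0.04,
             normoxic_tumour = 0.08, hypoxic_tumour = 0.06)

#' Generate a reference digital phantom
#'
#' A thoracic-like 2D slice with soft-tissue background (label 1), two lungs
#' (2), spine (3), descending-aorta blood pool (4), and a tumour in the
#' right lung with a normoxic rim (5) and hypoxic core (6); air outside the
#' body is label 0.
#'
#' The `simplified` phantom fills every region with irreversible two-tissue
#' (2C3K) kinetics.  The `realistic_like` phantom uses irreversible
#' three-tissue (3C5K) kinetics for the tumour regions and tabulated
#' reversible-exchange TAC shapes for the normal tissues, so that -- by
#' construction -- the 2C3K model describes its curves poorly while more
#' flexible models fit them well.
#'
#' @param kind "simplified" or "realistic_like".
#' @param n image grid side (default 64).
#' @param voxelSize voxel edge length in mm (default 3.1).
#' @param aif the ground-truth [AIFModel-class] (blood TAC).
#' @param sched schedule used to tabulate the normal-tissue curves of the
#'   realistic_like phantom.
#' @return a [Phantom-class].
#' @examples
#' ph <- makeReferencePhantom("simplified", n = 32)
#' table(regionLabels(ph))
#' @export
makeReferencePhantom <- function(kind = c("simplified", "realistic_like"),
                                 n = 64L, voxelSize = 3.1,
                                 aif = defaultAIF(),
                                 sched = defaultFrameSchedule()) {
  kind <- match.arg(kind)
  H <- 1                                     # work in normalized units
  cx <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  gx <- matrix(cx, n, n)
  gy <- matrix(cx, n, n, byrow = TRUE)
  lab <- matrix(0L, n, n)
  lab[inEllipse(gx, gy, 0, 0, 0.92, 0.75)] <- 1L
  lung <- inEllipse(gx, gy, -0.42, 0.05, 0.30, 0.45) |
    inEllipse(gx, gy, 0.42, 0.05, 0.30, 0.45)
  lab[lung & lab > 0] <- 2L
  lab[inEllipse(gx, gy, 0, -0.55, 0.14, 0.14) & lab > 0] <- 3L
  lab[inEllipse(gx, gy, 0, -0.28, 0.10, 0.10) & lab > 0] <- 4L
  lab[inEllipse(gx, gy, 0.42, 0.10, 0.20, 0.20) & lab > 0] <- 5L
  lab[inEllipse(gx, gy, 0.42, 0.10, 0.10, 0.10) & lab > 0] <- 6L

  toSec <- function(v, model) {
    if (model == "2C3K")
      kineticParams(v[["K1"]] / 60, v[["k2"]] / 60, v[["k3"]] / 60,
                    Vb = v[["Vb"]])
    else
      kineticParams(v[["K1"]] / 60, v[["k2"]] / 60, v[["k3"]] / 60,
                    v[["k4"]] / 60, v[["k5"]] / 60, Vb = v[["Vb"]],
                    model = "3C5K")
  }
  names4 <- c(background = 1L, lung = 2L, bone = 3L)
  regions <- list(blood = list(name = "blood", label = 4L, model = "aif"))
  if (kind == "simplified") {
    tab <- simplifiedKineticsTable()
    for (nm in names(tab)) {
      labId <- switch(nm, background = 1L, lung = 2L, bone = 3L,
                      normoxic_tumour = 5L, hypoxic_tumour = 6L)
      regions[[nm]] <- list(name = nm, label = labId, model = "2C3K",
                            params = toSec(c(tab[[nm]]), "2C3K"))
    }
  } else {
    tab <- realisticKineticsTable()
    for (nm in c("normoxic_tumour", "hypoxic_tumour")) {
      v <- c(tab[[nm]], Vb = unname(vbTable[nm]))
      labId <- if (nm == "normoxic_tumour") 5L else 6L
      regions[[nm]] <- list(name = nm, label = labId, model = "3C5K",
                            params = toSec(v, "3C5K"))
    }
    ## normal tissues: tabulate the reversible-exchange shape on a coarse
    ## time mesh and interpolate -- a spline-like non-compartmental truth
    tmax <- max(sched@end)
    tt <- sort(unique(c(seq(0, 120, by = 10), seq(150, 600, by = 50),
                        seq(700, 2700, by = 200),
                        seq(3000, tmax, length.out = 12), tmax)))
    for (nm in c("background", "lung", "bone")) {
      v <- c(tab[[nm]], Vb = unname(vbTable[nm]))
      p <- toSec(v, "3C5K")
      vals <- compartmentTAC(p, aif, tt)
      regions[[nm]] <- list(name = nm, label = names4[[nm]],
                            model = "tabulated", times = tt, values = vals)
    }
  }
  new("Phantom", labels = lab, regions = regions, voxelSize = voxelSize,
      aif = aif, kind = kind)
}

#' Analysis sub-region of a phantom
#'
#' The rectangular sub-region used for parametric mapping: the bounding box
#' of the tumour labels expanded by a margin, intersected with the body.
#'
#' @param phantom a [Phantom-class].
#' @param margin expansion margin in voxels.
#' @return integer voxel indices (column-major) of the sub-region.
#' @export
phantomSubRegion <- function(phantom, margin = 3L) {
  lab <- phantom@labels
  n <- nrow(lab)
  idx <- which(lab >= 5L, arr.ind = TRUE)
  if (!nrow(idx)) stop("phantom has no tumour labels")
  rows <- max(1L, min(idx[, 1]) - margin):min(n, max(idx[, 1]) + margin)
  cols <- max(1L, min(idx[, 2]) - margin):min(n, max(idx[, 2]) + margin)
  sub <- matrix(FALSE, n, n)
  sub[rows, cols] <- TRUE
  which(as.vector(sub & lab > 0L))
}

#' Region masks of a phantom
#'
#' @param phantom a [Phantom-class].
#' @return a list of integer voxel-index vectors: `patient` (all body
#'   voxels), `tumour` (normoxic + hypoxic), `hypoxic`.
#' @export
phantomMasks <- function(phantom) {
  lab <- as.vector(phantom@labels)
  list(patient = which(lab > 0L),
       tumour = which(lab >= 5L),
       hypoxic = which(lab == 6L))
}
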