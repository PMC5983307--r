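## Plain-text / NIfTI input-output helpers.

#' Export a basis matrix with provenance
#'
#' Writes the frame-integrated basis as a TSV matrix and a JSON sidecar
#' with its provenance (kind, knots or decay grid, AIF id, schedule).
#'
#' @param basis a [BasisMatrix-class].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return invisibly, the sidecar list.
#' @export
exportBasisMatrix <- function(basis, prefix) {
  write.table(format(basis@B, digits = 17), paste0(prefix, ".tsv"),
              row.names = FALSE, col.names = FALSE, quote = FALSE,
              sep = "\t")
  side <- list(kind = basis@kind,
               nBasis = ncol(basis@B),
               knots = if (!is.null(basis@knots)) basis@knots@knots,
               decays = if (length(basis@decays)) basis@decays,
               aif = basis@aifId,
               schedule = list(start = basis@schedule@start,
                               end = basis@schedule@end,
                               lambda = decayConstant(basis@schedule)))
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(prefix, ".json"))
  invisible(side)
}

#' Write an image series as NIfTI volumes
#'
#' One 2D volume per frame (`<prefix>_frame###.nii.gz` via the RNifti
#' package) plus a JSON sidecar holding the frame schedule.
#'
#' @param images an [ImageSeries-class].
#' @param prefix output path prefix.
#' @return invisibly, the written file names.
#' @export
writeImageSeriesNIfTI <- function(images, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI requires the RNifti package")
  n <- images@n
  files <- character(0)
  for (m in seq_len(ncol(images@values))) {
    img <- matrix(images@values[, m], n, n)
    f <- sprintf("%s_frame%03d.nii.gz", prefix, m)
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = rep(images@voxelSize, 2)),
                       f)
    files <- c(files, f)
  }
  sched <- images@schedule
  writeLines(jsonlite::toJSON(list(start = sched@start, end = sched@end,
                                   lambda = decayConstant(sched),
                                   tInj = sched@tInj),
                              auto_unbox = TRUE, digits = NA),
             paste0(prefix, "_schedule.json"))
  invisible(files)
}

#' Read an experiment specification from a YAML or JSON config file
#'
#' Top-level keys mirror the arguments of [experimentSpec()].
#'
#' @param path config file (.yaml/.yml needs the yaml package; .json uses
#'   jsonlite).
#' @return an [experimentSpec()] list.
#' @export
readExperimentConfig <- function(path) {
  cfg <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  do.call(experimentSpec, cfg)
}
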