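#' Accessors for rgnet objects
#'
#' Small accessor generics so slots never need to be touched directly:
#' \code{plaques()} and \code{cells()} return the tables of a
#' [GliaCohort-class] (and \code{cells()} the per-cell table of a
#' [TessellationResult-class]), \code{groundTruth()} the generator sidecar,
#' \code{channelNames()} and \code{voxelSize()} the image metadata.
#'
#' @param x an rgnet object.
#' @return the corresponding slot value (a data.frame, list, character or
#'   numeric vector).
#' @name accessors
#' @aliases plaques cells groundTruth channelNames voxelSize
#' @examples
#' co <- generateCohort(makePreset("mouse-mid"), nPlaques = 1, seed = 1)
#' nrow(plaques(co))
#' head(cells(co))
NULL

#' @rdname accessors
#' @export
setGeneric("plaques", function(x) standardGeneric("plaques"))

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
setMethod("plaques", "GliaCohort", function(x) x@plaques)

#' @rdname accessors
setMethod("cells", "GliaCohort", function(x) x@cells)

#' @rdname accessors
setMethod("cells", "TessellationResult", function(x) x@cells)

#' @rdname accessors
setMethod("groundTruth", "GliaCohort", function(x) x@groundTruth)

#' @rdname accessors
setMethod("channelNames", "VoxelStack", function(x) x@channelNames)

#' @rdname accessors
setMethod("voxelSize", "VoxelStack", function(x) x@voxelSizeUm)

#' @rdname accessors
setMethod("voxelSize", "LabeledVolume", function(x) x@voxelSizeUm)

setMethod("show", "RGNPreset", function(object) {
  cat(sprintf("RGNPreset '%s' (%s)\n", object@name, object@plaqueClass))
  cat(sprintf("  microglia shell: %.1f um (sd %.1f), base %g, slope %g/um^3\n",
              object@microgliaShellMeanUm, object@microgliaShellSdUm,
              object@microgliaBaseCount, object@microgliaSlopePerUm3))
  cat(sprintf("  astrocyte shell: %.1f um (sd %.1f, max %.0f), base %g, slope %g/um^3\n",
              object@astroShellMeanUm, object@astroShellSdUm,
              object@astroMaxUm, object@gfapBaseCount,
              object@gfapSlopePerUm3))
  cat(sprintf("  target population r: iba1 %.3f, gfap %.3f; background %g/mm^3\n",
              object@targetR[["iba1"]], object@targetR[["gfap"]],
              object@backgroundDensityPerMm3))
})

setMethod("show", "GliaCohort", function(object) {
  cat(sprintf("GliaCohort: %d plaque(s) [%s], %d cells (%d iba1, %d gfap)\n",
              nrow(object@plaques), object@preset@name, nrow(object@cells),
              sum(object@cells$marker == "iba1"),
              sum(object@cells$marker == "gfap")))
  cat(sprintf("  field %g x %g x %g um, master seed %d\n",
              object@fieldUm[1], object@fieldUm[2], object@fieldUm[3],
              object@seed))
})

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelStack: %d channel(s) [%s], %d x %d x %d voxels (z,y,x)\n",
              d[1], paste(object@channelNames, collapse = ", "),
              d[2], d[3], d[4]))
  cat(sprintf("  voxel size %g x %g x %g um (x,y,z)\n",
              object@voxelSizeUm[1], object@voxelSizeUm[2],
              object@voxelSizeUm[3]))
})

setMethod("show", "LabeledVolume", function(object) {
  cat(sprintf("LabeledVolume: %d component(s), %d x %d x %d voxels (z,y,x)\n",
              object@nComponents, dim(object@labels)[1],
              dim(object@labels)[2], dim(object@labels)[3]))
})

setMethod("show", "RGNProfile", function(object) {
  cat(sprintf("RGNProfile for %s (%s), volume %.0f um^3\n",
              object@plaqueId, object@plaqueClass, object@volumeUm3))
  if (object@gfapDefined) {
    cat(sprintf("  interval max GFAP+: [%g, %g) um -> net boundary %g um\n",
                object@intervalMaxGfapUm[1], object@intervalMaxGfapUm[2],
                object@rgnBoundaryUm))
    cat(sprintf("  iba1: %d total, %d intra-net; gfap: %d\n",
                object@nIba1Total, object@nIba1IntraRgn, object@nGfap))
  } else {
    cat("  net undefined: no GFAP+ cell within the maximum radius\n")
  }
})

setMethod("show", "TessellationResult", function(object) {
  s <- object@summary
  cat(sprintf("TessellationResult: %d seeds in %g x %g um ROI, %d complete cells\n",
              s$n_seeds, object@roiUm[1], object@roiUm[2], s$n_complete))
  if (!is.na(s$median_complete_area_um2))
    cat(sprintf("  median complete-cell area %.1f um^2, median NN distance %.2f um\n",
                s$median_complete_area_um2, s$median_nn_um))
})

setMethod("show", "LandscapeSpec", function(object) {
  cat(sprintf("LandscapeSpec: %s, %d microglia in %g x %g um ROI\n",
              object@mode, object@nMicroglia, object@roiUm[1],
              object@roiUm[2]))
  if (object@mode == "plaque_perturbed")
    cat(sprintf("  %d plaque(s); aggregation %g um, depletion %g um, fraction %.2f\n",
                nrow(object@plaqueCenters), object@aggregationRadiusUm,
                object@depletionOuterUm, object@aggregationFraction))
})
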