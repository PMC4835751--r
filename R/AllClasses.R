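#' @import methods
NULL

PLAQUE_CLASSES <- c("dense_core", "fibrillar", "phf_nft")
MARKERS <- c("iba1", "gfap")

#' RGNPreset: generative parameters for one plaque/glia condition
#'
#' An \code{RGNPreset} bundles the parameters the synthetic generator uses for
#' one condition: the plaque class, the radial shell geometry of the two glial
#' populations (microglia inner, astrocytes outer), base counts and
#' volume-recruitment slopes per marker, the population count--volume
#' correlations the count noise is calibrated to, and the background (non-net)
#' glial density. All lengths are micrometers, volumes cubic micrometers.
#'
#' @slot name preset label.
#' @slot plaqueClass one of \code{"dense_core"}, \code{"fibrillar"},
#'   \code{"phf_nft"}.
#' @slot coreRadiusUm lower truncation of shell distances (plaque core).
#' @slot microgliaShellMeanUm,microgliaShellSdUm radial law of microglial
#'   somata (truncated normal), micrometers from the plaque center.
#' @slot astroShellMeanUm,astroShellSdUm radial law of astrocyte somata.
#' @slot astroMaxUm upper truncation of astrocyte distances (outer limit of
#'   astrocyte reactivity).
#' @slot microgliaBaseCount,gfapBaseCount volume-independent part of the
#'   expected shell counts.
#' @slot microgliaSlopePerUm3,gfapSlopePerUm3 recruitment slopes: expected
#'   extra cells per cubic micrometer of plaque volume.
#' @slot targetR named numeric (\code{iba1}, \code{gfap}): population Pearson
#'   correlation between shell count and plaque volume the generator's count
#'   noise is calibrated to.
#' @slot backgroundDensityPerMm3 density of background somata per marker,
#'   cells per cubic millimeter.
#' @seealso [makePreset()], [sampleGlia()], [generateCohort()]
#' @exportClass RGNPreset
setClass("RGNPreset",
  representation(
    name = "character",
    plaqueClass = "character",
    coreRadiusUm = "numeric",
    microgliaShellMeanUm = "numeric",
    microgliaShellSdUm = "numeric",
    astroShellMeanUm = "numeric",
    astroShellSdUm = "numeric",
    astroMaxUm = "numeric",
    microgliaBaseCount = "numeric",
    gfapBaseCount = "numeric",
    microgliaSlopePerUm3 = "numeric",
    gfapSlopePerUm3 = "numeric",
    targetR = "numeric",
    backgroundDensityPerMm3 = "numeric"
  )
)

setValidity("RGNPreset", function(object) {
  msg <- character(0)
  if (!object@plaqueClass %in% PLAQUE_CLASSES)
    msg <- c(msg, sprintf("plaqueClass must be one of: %s",
                          paste(PLAQUE_CLASSES, collapse = ", ")))
  lens <- c(coreRadiusUm = object@coreRadiusUm,
            microgliaShellMeanUm = object@microgliaShellMeanUm,
            microgliaShellSdUm = object@microgliaShellSdUm,
            astroShellMeanUm = object@astroShellMeanUm,
            astroShellSdUm = object@astroShellSdUm,
            astroMaxUm = object@astroMaxUm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all shell lengths must be finite and > 0")
  if (object@astroMaxUm < object@astroShellMeanUm ||
      object@astroShellMeanUm < object@microgliaShellMeanUm)
    msg <- c(msg, paste("shell ordering violated: need astroMaxUm >=",
                        "astroShellMeanUm >= microgliaShellMeanUm"))
  cnts <- c(object@microgliaBaseCount, object@gfapBaseCount,
            object@microgliaSlopePerUm3, object@gfapSlopePerUm3,
            object@backgroundDensityPerMm3)
  if (any(cnts < 0)) msg <- c(msg, "counts, slopes and densities must be >= 0")
  if (!all(MARKERS %in% names(object@targetR)))
    msg <- c(msg, "targetR must be named with 'iba1' and 'gfap'")
  if (any(abs(object@targetR) > 1))
    msg <- c(msg, "|targetR| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' GliaCohort: simulated plaques with surrounding glia and ground truth
#'
#' One cohort of independently simulated plaque fields. Each plaque sits at
#' the center of its own cubic field; its cells carry the plaque id. The
#' ground-truth list records every generator parameter so recovery can be
#' tested.
#'
#' @slot plaques data.frame: \code{plaque_id}, \code{plaque_class},
#'   \code{cx_um}, \code{cy_um}, \code{cz_um}, \code{volume_um3},
#'   \code{equivalent_radius_um}.
#' @slot cells data.frame: \code{cell_id}, \code{marker}, \code{x_um},
#'   \code{y_um}, \code{z_um}, \code{plaque_id}, \code{origin}
#'   (\code{"shell"} or \code{"background"}).
#' @slot preset the [RGNPreset-class] used.
#' @slot fieldUm field-of-view side lengths (x, y, z) in micrometers.
#' @slot seed master seed.
#' @slot groundTruth list of generator parameters (per-plaque seeds, count
#'   noise SDs, volume range).
#' @exportClass GliaCohort
setClass("GliaCohort",
  representation(
    plaques = "data.frame",
    cells = "data.frame",
    preset = "RGNPreset",
    fieldUm = "numeric",
    seed = "integer",
    groundTruth = "list"
  )
)

setValidity("GliaCohort", function(object) {
  msg <- character(0)
  needP <- c("plaque_id", "plaque_class", "cx_um", "cy_um", "cz_um",
             "volume_um3", "equivalent_radius_um")
  needC <- c("cell_id", "marker", "x_um", "y_um", "z_um", "plaque_id",
             "origin")
  if (!all(needP %in% names(object@plaques)))
    msg <- c(msg, "plaques table misses required columns")
  if (!all(needC %in% names(object@cells)))
    msg <- c(msg, "cells table misses required columns")
  if (length(object@fieldUm) != 3 || any(object@fieldUm <= 0))
    msg <- c(msg, "fieldUm must be 3 positive lengths")
  if (nrow(object@plaques) && any(object@plaques$volume_um3 <= 0))
    msg <- c(msg, "plaque volumes must be > 0")
  if (nrow(object@cells) && !all(object@cells$marker %in% MARKERS))
    msg <- c(msg, "cell markers must be 'iba1' or 'gfap'")
  if (length(msg)) msg else TRUE
})

#' LandscapeSpec: parameters for a 2D microglial landscape
#'
#' Describes a rectangular region of interest populated by microglial somata,
#' either homogeneously or perturbed by plaques (aggregation discs surrounded
#' by depletion annuli), emulating the territory maps used for Voronoi
#' analysis of cortical tissue.
#'
#' @slot roiUm ROI width and height in micrometers.
#' @slot mode \code{"homogeneous"} or \code{"plaque_perturbed"}.
#' @slot nMicroglia number of somata (>= 3; tessellation needs 3 seeds).
#' @slot plaqueCenters matrix (n x 2) of plaque centers, micrometers.
#' @slot aggregationRadiusUm disc radius cells are relocated into.
#' @slot depletionOuterUm outer radius of the annulus cells are drawn from.
#' @slot aggregationFraction fraction of annulus cells relocated, in [0, 1].
#' @exportClass LandscapeSpec
setClass("LandscapeSpec",
  representation(
    roiUm = "numeric",
    mode = "character",
    nMicroglia = "integer",
    plaqueCenters = "matrix",
    aggregationRadiusUm = "numeric",
    depletionOuterUm = "numeric",
    aggregationFraction = "numeric"
  )
)

setValidity("LandscapeSpec", function(object) {
  msg <- character(0)
  if (length(object@roiUm) != 2 || any(object@roiUm <= 0))
    msg <- c(msg, "roiUm must be two positive lengths")
  if (!object@mode %in% c("homogeneous", "plaque_perturbed"))
    msg <- c(msg, "mode must be 'homogeneous' or 'plaque_perturbed'")
  if (object@nMicroglia < 3)
    msg <- c(msg, "nMicroglia must be >= 3 (tessellation needs 3 seeds)")
  if (object@mode == "plaque_perturbed") {
    if (object@depletionOuterUm <= object@aggregationRadiusUm)
      msg <- c(msg, "depletionOuterUm must exceed aggregationRadiusUm")
    if (object@aggregationFraction < 0 || object@aggregationFraction > 1)
      msg <- c(msg, "aggregationFraction must be in [0, 1]")
    if (!nrow(object@plaqueCenters))
      msg <- c(msg, "plaque_perturbed mode needs at least one plaque center")
  }
  if (length(msg)) msg else TRUE
})

#' VoxelStack: a multi-channel 3D intensity image
#'
#' @slot data 4D numeric array indexed (channel, z, y, x).
#' @slot channelNames one label per channel.
#' @slot voxelSizeUm voxel edge lengths (x, y, z) in micrometers. Voxel
#'   (i, j, k) (1-based) spans the half-open box
#'   \code{[(i-1)*dx, i*dx) x ...}; its center is at \code{(i - 0.5)*dx}.
#' @exportClass VoxelStack
setClass("VoxelStack",
  representation(
    data = "array",
    channelNames = "character",
    voxelSizeUm = "numeric"
  )
)

setValidity("VoxelStack", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 4)
    msg <- c(msg, "data must be a 4D array (channel, z, y, x)")
  else if (dim(object@data)[1] != length(object@channelNames))
    msg <- c(msg, "channelNames length must equal the channel count")
  if (length(object@voxelSizeUm) != 3 || any(object@voxelSizeUm <= 0))
    msg <- c(msg, "voxelSizeUm must be 3 positive lengths")
  if (length(msg)) msg else TRUE
})

#' LabeledVolume: connected components of a binary volume
#'
#' @slot labels 3D integer array (z, y, x); 0 is background, components are
#'   numbered 1..nComponents by decreasing volume.
#' @slot nComponents number of retained components.
#' @slot voxelSizeUm voxel edge lengths (x, y, z), micrometers.
#' @exportClass LabeledVolume
setClass("LabeledVolume",
  representation(
    labels = "array",
    nComponents = "integer",
    voxelSizeUm = "numeric"
  )
)

setValidity("LabeledVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@labels)) != 3)
    msg <- c(msg, "labels must be a 3D array (z, y, x)")
  if (length(object@labels) &&
      (min(object@labels) < 0 || max(object@labels) > object@nComponents))
    msg <- c(msg, "labels must lie in [0, nComponents]")
  if (length(object@voxelSizeUm) != 3 || any(object@voxelSizeUm <= 0))
    msg <- c(msg, "voxelSizeUm must be 3 positive lengths")
  if (length(msg)) msg else TRUE
})

#' RadialHistogram: binned radial distances per marker
#'
#' Half-open bins \code{[k*w, (k+1)*w)} from the plaque center; the outermost
#' bin is closed above so distances equal to the maximum radius are conserved.
#'
#' @slot binEdgesUm strictly increasing edges starting at 0.
#' @slot counts integer matrix, bins x markers (columns \code{iba1},
#'   \code{gfap}).
#' @slot truncatedLastBin TRUE when the bin width did not divide the maximum
#'   radius and the last bin was shortened.
#' @exportClass RadialHistogram
setClass("RadialHistogram",
  representation(
    binEdgesUm = "numeric",
    counts = "matrix",
    truncatedLastBin = "logical"
  )
)

setValidity("RadialHistogram", function(object) {
  msg <- character(0)
  e <- object@binEdgesUm
  if (length(e) < 2 || e[1] != 0 || any(diff(e) <= 0))
    msg <- c(msg, "binEdgesUm must start at 0 and be strictly increasing")
  if (nrow(object@counts) != length(e) - 1)
    msg <- c(msg, "counts must have one row per bin")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RGNProfile: per-plaque reactive-glial-net measurements
#'
#' The per-plaque measurement bundle: radial distances per marker, their
#' histogram, the interval-max-GFAP bin, the net boundary (outer edge of that
#' bin), and the derived counts. When the plaque has no GFAP+ cell within the
#' maximum radius the net is undefined: \code{gfapDefined} is FALSE and the
#' interval/boundary/intra-net fields are NA.
#'
#' @slot plaqueId,plaqueClass identifiers copied from the plaque record.
#' @slot volumeUm3 plaque volume.
#' @slot intervalMaxGfapUm numeric (lo, hi): the radial bin holding the
#'   maximum GFAP+ count (ties broken toward the innermost bin).
#' @slot rgnBoundaryUm outer edge of that bin; the net limit.
#' @slot nIba1Total,nIba1IntraRgn,nGfap counts within the maximum radius /
#'   within the boundary.
#' @slot distances named list (\code{iba1}, \code{gfap}) of sorted radial
#'   distances within the maximum radius.
#' @slot histogram the [RadialHistogram-class].
#' @slot gfapDefined FALSE when no GFAP+ cell was found (profile excluded
#'   from cohort statistics).
#' @exportClass RGNProfile
setClass("RGNProfile",
  representation(
    plaqueId = "character",
    plaqueClass = "character",
    volumeUm3 = "numeric",
    intervalMaxGfapUm = "numeric",
    rgnBoundaryUm = "numeric",
    nIba1Total = "integer",
    nIba1IntraRgn = "integer",
    nGfap = "integer",
    distances = "list",
    histogram = "RadialHistogram",
    gfapDefined = "logical"
  )
)

setValidity("RGNProfile", function(object) {
  msg <- character(0)
  if (object@gfapDefined) {
    iv <- object@intervalMaxGfapUm
    if (length(iv) != 2 || iv[1] >= iv[2])
      msg <- c(msg, "intervalMaxGfapUm must be (lo, hi) with lo < hi")
    else if (!isTRUE(all.equal(object@rgnBoundaryUm, iv[2])))
      msg <- c(msg, "rgnBoundaryUm must equal the interval's outer edge")
    if (!is.na(object@nIba1IntraRgn) &&
        object@nIba1IntraRgn > object@nIba1Total)
      msg <- c(msg, "intra-net count cannot exceed the total count")
  }
  if (length(msg)) msg else TRUE
})

#' TessellationResult: Voronoi tessellation of somata in a rectangular ROI
#'
#' @slot cells data.frame: \code{seed_index}, \code{x_um}, \code{y_um},
#'   \code{area_um2}, \code{complete}, \code{nn_distance_um}. Areas are of
#'   the ROI-clipped cell; \code{complete} marks cells whose unclipped
#'   Voronoi cell is bounded and lies inside the ROI.
#' @slot polygons list of n x 2 vertex matrices (counter-clockwise), one per
#'   seed, clipped to the ROI.
#' @slot roiUm ROI width and height, micrometers.
#' @slot summary list: \code{n_seeds}, \code{n_complete},
#'   \code{median_complete_area_um2}, \code{mean_nn_um}, \code{median_nn_um}.
#' @exportClass TessellationResult
setClass("TessellationResult",
  representation(
    cells = "data.frame",
    polygons = "list",
    roiUm = "numeric",
    summary = "list"
  )
)

setValidity("TessellationResult", function(object) {
  msg <- character(0)
  if (length(object@roiUm) != 2 || any(object@roiUm <= 0))
    msg <- c(msg, "roiUm must be two positive lengths")
  if (nrow(object@cells) != length(object@polygons))
    msg <- c(msg, "one polygon per cell row required")
  if (nrow(object@cells) && any(object@cells$area_um2 <= 0))
    msg <- c(msg, "cell areas must be positive")
  if (length(msg)) msg else TRUE
})
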