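PRESET_NAMES <- c("human-dense-core", "human-fibrillar", "human-phf-nft",
                  "mouse-mid", "mouse-late")

#' Built-in generative presets for plaque/glia conditions
#'
#' Returns the documented parameter set for one of the five built-in
#' conditions. The shell geometry encodes the reported anatomy of reactive
#' glial nets: microglial somata concentrated ~20--30 um from the plaque
#' center (modeled as a truncated normal with mean 25, sd 4), astrocyte
#' somata at ~30--50 um (mean 40, sd 6) with astrocyte reactivity truncated
#' at 80 um for the human dense-core condition; the mouse mid-stage preset
#' centers the astrocyte shell at 40 um and the late-stage preset at 60 um.
#' The fibrillar preset doubles microglial recruitment (base count and slope)
#' relative to dense-core while keeping the astrocyte shell unchanged, and
#' carries a population count--volume correlation of 0.561 for total Iba1+
#' cells; the PHF/NFT preset has no microglial recruitment slope (counts
#' uncorrelated with aggregate extent) but keeps a weak astrocytic corona.
#'
#' Base counts, slopes and the background density are package defaults (the
#' source observations report correlations and shell positions, not absolute
#' densities); see the methods vignette for the rationale.
#'
#' @param name one of \code{"human-dense-core"}, \code{"human-fibrillar"},
#'   \code{"human-phf-nft"}, \code{"mouse-mid"}, \code{"mouse-late"}.
#' @param ... named overrides for any [RGNPreset-class] slot, e.g.
#'   \code{gfapBaseCount = 40}.
#' @return an [RGNPreset-class].
#' @examples
#' makePreset("mouse-mid")
#' makePreset("human-dense-core", gfapBaseCount = 40)
#' @export
makePreset <- function(name, ...) {
  if (length(name) != 1 || !name %in% PRESET_NAMES)
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(PRESET_NAMES, collapse = ", "))
  base <- switch(name,
    "human-dense-core" = list(
      plaqueClass = "dense_core",
      microgliaShellMeanUm = 25, microgliaShellSdUm = 4,
      astroShellMeanUm = 40, astroShellSdUm = 6, astroMaxUm = 80,
      microgliaBaseCount = 12, microgliaSlopePerUm3 = 8e-4,
      gfapBaseCount = 10, gfapSlopePerUm3 = 6e-4,
      targetR = c(iba1 = 0.45, gfap = 0.479)
    ),
    "human-fibrillar" = list(
      plaqueClass = "fibrillar",
      microgliaShellMeanUm = 25, microgliaShellSdUm = 4,
      astroShellMeanUm = 40, astroShellSdUm = 6, astroMaxUm = 80,
      # doubled microglial recruitment (base and slope) vs dense-core
      microgliaBaseCount = 24, microgliaSlopePerUm3 = 1.6e-3,
      gfapBaseCount = 10, gfapSlopePerUm3 = 6e-4,
      targetR = c(iba1 = 0.561, gfap = 0.479)
    ),
    "human-phf-nft" = list(
      plaqueClass = "phf_nft",
      microgliaShellMeanUm = 25, microgliaShellSdUm = 4,
      astroShellMeanUm = 40, astroShellSdUm = 6, astroMaxUm = 80,
      # microglia do not cluster at PHF/NFT aggregates: sparse, slope 0
      microgliaBaseCount = 3, microgliaSlopePerUm3 = 0,
      gfapBaseCount = 8, gfapSlopePerUm3 = 6e-4,
      targetR = c(iba1 = 0, gfap = 0.281)
    ),
    "mouse-mid" = list(
      plaqueClass = "dense_core",
      microgliaShellMeanUm = 25, microgliaShellSdUm = 4,
      astroShellMeanUm = 40, astroShellSdUm = 6, astroMaxUm = 80,
      microgliaBaseCount = 15, microgliaSlopePerUm3 = 8e-4,
      gfapBaseCount = 15, gfapSlopePerUm3 = 6e-4,
      targetR = c(iba1 = 0.264, gfap = 0.561)
    ),
    "mouse-late" = list(
      plaqueClass = "dense_core",
      microgliaShellMeanUm = 25, microgliaShellSdUm = 4,
      astroShellMeanUm = 60, astroShellSdUm = 6, astroMaxUm = 100,
      microgliaBaseCount = 20, microgliaSlopePerUm3 = 1.2e-3,
      gfapBaseCount = 20, gfapSlopePerUm3 = 6e-4,
      targetR = c(iba1 = 0.264, gfap = 0.561)
    )
  )
  args <- c(list("RGNPreset", name = name, coreRadiusUm = 5,
                 backgroundDensityPerMm3 = 1000), base)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), slotNames("RGNPreset"))
    if (length(bad))
      stop("unknown preset field(s): ", paste(bad, collapse = ", "))
    args[names(over)] <- over
  }
  do.call(new, args)
}
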