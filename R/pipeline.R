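defaultRunConfig <- function() {
  list(
    mode = "full",
    seed = 1L,
    cohorts = list(
      list(preset = "human-dense-core", n_plaques = 50),
      list(preset = "human-fibrillar", n_plaques = 50)
    ),
    volume_range_um3 = DEFAULT_VOLUME_RANGE_UM3,
    rgn = list(bin_width_um = 10, max_radius_um = 100, min_gfap = 1),
    landscape = list(enabled = TRUE, n_microglia = 300,
                     roi_um = c(1000, 1000), n_plaques = 3,
                     aggregation_radius_um = 50, depletion_outer_um = 150,
                     aggregation_fraction = 0.7),
    output_dir = "rgnet_run"
  )
}

#' Read a pipeline run configuration from JSON
#'
#' Missing fields fall back to the documented defaults; unknown top-level
#' fields raise an error so typos do not silently disable stages.
#'
#' @param path JSON file; when NULL, returns the defaults.
#' @return a run-config list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}

# Stage seeds derived from the master seed with fixed documented offsets, so
# stages can be re-run in isolation and still reproduce.
stageSeed <- function(masterSeed, stage) {
  offs <- c(simulate = 11L, landscape = 23L, render = 37L)
  (as.integer(masterSeed) * 1000L + offs[[stage]]) %% (.Machine$integer.max)
}

#' Run the end-to-end pipeline from a single configuration
#'
#' Orchestrates simulate -> profile -> correlate -> class comparison ->
#' landscape tessellation into a deterministic output directory: per-cohort
#' cell/plaque tables with ground truth, a per-plaque profile table, a JSON
#' report (correlations, plaque-class ANOVA/Tukey triplet on boundary
#' interval, intra-net Iba1 count and plaque volume, Voronoi summary) and a
#' manifest of versions, seeds and parameters. In \code{"simulate"} mode
#' only the tables are written; \code{"analyze"} mode profiles existing
#' tables in \code{output_dir} instead of simulating.
#'
#' @param config run-config list from [readRunConfig()].
#' @param outputDir overrides \code{config$output_dir}.
#' @return invisibly, the report list.
#' @export
runPipeline <- function(config = readRunConfig(), outputDir = NULL) {
  if (!is.null(outputDir)) config$output_dir <- outputDir
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  report <- list(parameters = config["rgn"], seeds = list(master = seed))
  cohortTabs <- list()

  if (config$mode %in% c("simulate", "full")) {
    simSeed <- stageSeed(seed, "simulate")
    for (i in seq_along(config$cohorts)) {
      cs <- config$cohorts[[i]]
      preset <- makePreset(cs$preset)
      co <- generateCohort(preset, cs$n_plaques,
                           volumeRangeUm3 = as.numeric(config$volume_range_um3),
                           seed = simSeed + i)
      d <- file.path(config$output_dir, gsub("[^a-z0-9]+", "_", cs$preset))
      writeCohort(co, d)
      cohortTabs[[cs$preset]] <- list(plaques = co@plaques, cells = co@cells)
    }
  }
  if (config$mode == "analyze") {
    dirs <- list.dirs(config$output_dir, recursive = FALSE)
    for (d in dirs) {
      cellsPath <- file.path(d, "cells.tsv")
      plaquesPath <- file.path(d, "plaques.tsv")
      if (file.exists(cellsPath) && file.exists(plaquesPath))
        cohortTabs[[basename(d)]] <- list(
          plaques = readPlaqueTable(plaquesPath),
          cells = readCellTable(cellsPath))
    }
    if (!length(cohortTabs))
      stop("analyze mode found no cohort tables under ", config$output_dir)
  }

  if (config$mode %in% c("analyze", "full")) {
    profs <- list()
    correl <- list()
    for (nm in names(cohortTabs)) {
      pr <- profileCohort(cohortTabs[[nm]],
                          binWidthUm = config$rgn$bin_width_um,
                          maxRadiusUm = config$rgn$max_radius_um)
      pr <- pr[!pr$gfap_defined | pr$n_gfap >= config$rgn$min_gfap, ]
      profs[[nm]] <- pr
      utils::write.table(pr, file.path(config$output_dir,
                                       paste0("profiles_",
                                              gsub("[^a-z0-9]+", "_", nm),
                                              ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (sum(pr$gfap_defined) >= 3)
        correl[[nm]] <- recruitmentCorrelations(pr)
    }
    report$correlations <- correl
    report$excluded_plaques <- lapply(profs, function(p) attr(p, "excluded"))

    if (length(profs) >= 2) {
      valid <- lapply(profs, function(p) p[p$gfap_defined, ])
      cmp <- list()
      for (what in c("rgn_boundary_um", "n_iba1_intra_rgn", "volume_um3")) {
        gl <- lapply(valid, `[[`, what)
        gl <- gl[vapply(gl, length, 1L) >= 2]
        if (length(gl) >= 2) {
          a <- oneWayAnova(gl)
          entry <- list(anova = a)
          # post hoc convention: only when ANOVA rejects and k > 2
          if (a$p_value < 0.05 && length(gl) > 2)
            entry$tukey <- tukeyKramer(gl)
          cmp[[what]] <- entry
        }
      }
      report$class_comparison <- cmp
    }
  }

  ls <- config$landscape
  if (isTRUE(ls$enabled) && config$mode %in% c("analyze", "full")) {
    lseed <- stageSeed(seed, "landscape")
    set.seed(lseed)
    centers <- cbind(stats::runif(ls$n_plaques, 0.2, 0.8) * ls$roi_um[1],
                     stats::runif(ls$n_plaques, 0.2, 0.8) * ls$roi_um[2])
    spec <- landscapeSpec(roiUm = as.numeric(ls$roi_um),
                          mode = "plaque_perturbed",
                          nMicroglia = ls$n_microglia,
                          plaqueCenters = centers,
                          aggregationRadiusUm = ls$aggregation_radius_um,
                          depletionOuterUm = ls$depletion_outer_um,
                          aggregationFraction = ls$aggregation_fraction)
    pts <- generateLandscape(spec, seed = lseed + 1L)
    tess <- tessellate(pts, roiUm = spec@roiUm)
    utils::write.table(tess@cells,
                       file.path(config$output_dir, "voronoi_cells.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$voronoi <- tess@summary
  }

  manifest <- list(package = "rgnet",
                   version = as.character(utils::packageVersion("rgnet")),
                   seeds = list(master = seed),
                   config = config)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (config$mode %in% c("analyze", "full"))
    writeReport(report, file.path(config$output_dir, "report.json"))
  invisible(report)
}
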