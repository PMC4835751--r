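CELL_COLUMNS <- c("cell_id", "marker", "x_um", "y_um", "z_um", "plaque_id",
                  "origin")
PLAQUE_COLUMNS <- c("plaque_id", "class", "cx", "cy", "cz", "volume_um3")

checkNumericColumn <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at line(s) %s",
                 path, col,
                 paste(utils::head(bad + 1L, 5), collapse = ", ")))
  v
}

#' Read / write glial cell tables
#'
#' Tab-delimited tables with columns \code{cell_id}, \code{marker},
#' \code{x_um}, \code{y_um}, \code{z_um}, \code{plaque_id}, \code{origin};
#' coordinates in micrometers. Marker labels are normalized to lower case
#' (so \code{"IBA1"} is accepted); unknown markers, missing columns and
#' non-numeric coordinates raise schema errors naming the offending column
#' and line.
#'
#' @param path file path.
#' @param cellTab a cell data.frame (for the writer).
#' @return the reader returns the validated data.frame; the writer returns
#'   \code{path} invisibly.
#' @export
readCellTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(CELL_COLUMNS, names(df))
  if (length(missing))
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("x_um", "y_um", "z_um"))
    df[[col]] <- checkNumericColumn(df, col, path)
  df$marker <- tolower(df$marker)
  badm <- which(!df$marker %in% MARKERS)
  if (length(badm))
    stop(sprintf("%s: unknown marker label(s) at line(s) %s (expected iba1/gfap)",
                 path, paste(utils::head(badm + 1L, 5), collapse = ", ")))
  df[CELL_COLUMNS]
}

#' @rdname readCellTable
#' @export
writeCellTable <- function(cellTab, path) {
  missing <- setdiff(CELL_COLUMNS, names(cellTab))
  if (length(missing))
    stop("cell table misses column(s): ", paste(missing, collapse = ", "))
  utils::write.table(cellTab[CELL_COLUMNS], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write plaque tables
#'
#' Tab-delimited tables with columns \code{plaque_id}, \code{class},
#' \code{cx}, \code{cy}, \code{cz}, \code{volume_um3} (micrometers /
#' cubic micrometers). The reader re-derives the equivalent spherical
#' radius and returns the internal column names.
#'
#' @param path file path.
#' @param plaqueTab a plaque data.frame (internal schema) for the writer.
#' @return reader: validated plaque data.frame (internal schema); writer:
#'   \code{path}, invisibly.
#' @export
readPlaqueTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(PLAQUE_COLUMNS, names(df))
  if (length(missing))
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("cx", "cy", "cz", "volume_um3"))
    df[[col]] <- checkNumericColumn(df, col, path)
  badc <- which(!df$class %in% PLAQUE_CLASSES)
  if (length(badc))
    stop(sprintf("%s: unknown plaque class at line(s) %s",
                 path, paste(utils::head(badc + 1L, 5), collapse = ", ")))
  if (any(df$volume_um3 <= 0))
    stop(path, ": plaque volumes must be > 0")
  data.frame(plaque_id = df$plaque_id, plaque_class = df$class,
             cx_um = df$cx, cy_um = df$cy, cz_um = df$cz,
             volume_um3 = df$volume_um3,
             equivalent_radius_um = (3 * df$volume_um3 / (4 * pi))^(1 / 3),
             stringsAsFactors = FALSE)
}

#' @rdname readPlaqueTable
#' @export
writePlaqueTable <- function(plaqueTab, path) {
  out <- data.frame(plaque_id = plaqueTab$plaque_id,
                    class = plaqueTab$plaque_class,
                    cx = plaqueTab$cx_um, cy = plaqueTab$cy_um,
                    cz = plaqueTab$cz_um,
                    volume_um3 = plaqueTab$volume_um3,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to a directory (tables + ground-truth sidecar)
#'
#' Emits \code{cells.tsv}, \code{plaques.tsv} and \code{ground_truth.json}.
#'
#' @param cohort a [GliaCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "GliaCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCellTable(cohort@cells, file.path(dir, "cells.tsv"))
  writePlaqueTable(cohort@plaques, file.path(dir, "plaques.tsv"))
  gt <- cohort@groundTruth
  gt$master_seed <- cohort@seed
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a voxel stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...).
#' Intensities are scaled into [0, 1] for 16-bit storage; the scale factor,
#' channel names, voxel size and dimensions live in a JSON sidecar next to
#' the TIFF (same basename, extension \code{.json}), since the TIFF writer
#' exposes no custom-tag interface.
#'
#' @param stack a [VoxelStack-class].
#' @param path TIFF path.
#' @return writer: \code{path}, invisibly; reader: the reconstructed
#'   [VoxelStack-class].
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "VoxelStack"))
  d <- dim(stack@data)
  maxI <- max(stack@data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  p <- 0L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      p <- p + 1L
      pages[[p]] <- pmin(pmax(matrix(stack@data[ch, z, , ],
                                     d[3], d[4]) / maxI, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = stack@channelNames,
               voxel_size_um = stack@voxelSizeUm,
               dim_czyx = d, max_intensity = maxI)
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  metaPath <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(metaPath))
    stop("metadata sidecar not found: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim_czyx)
  vol <- array(0, d)
  p <- 0L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      p <- p + 1L
      vol[ch, z, , ] <- pages[[p]] * meta$max_intensity
    }
  }
  new("VoxelStack", data = vol, channelNames = meta$channels,
      voxelSizeUm = as.numeric(meta$voxel_size_um))
}

#' Write an analysis report as JSON plus a human-readable summary
#'
#' @param report a named list (as assembled by [runPipeline()]).
#' @param path JSON output path; a \code{.txt} twin with a short summary is
#'   written alongside.
#' @return invisibly, the JSON path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  txt <- c("rgnet analysis report", "=====================")
  if (!is.null(report$correlations)) {
    for (nm in names(report$correlations)) {
      co <- report$correlations[[nm]]
      txt <- c(txt, sprintf(
        "%s: n = %d, r(iba1 total) = %.3f, r(iba1 intra) = %.3f, r(gfap) = %.3f",
        nm, co$n_plaques, co$r_iba1_total, co$r_iba1_intra_rgn, co$r_gfap))
    }
  }
  if (!is.null(report$class_comparison)) {
    for (nm in names(report$class_comparison)) {
      a <- report$class_comparison[[nm]]$anova
      txt <- c(txt, sprintf("ANOVA on %s: F(%d, %d) = %.3f, p = %.4g",
                            nm, a$df_between, a$df_within, a$f_statistic,
                            a$p_value))
    }
  }
  if (!is.null(report$voronoi))
    txt <- c(txt, sprintf(
      "Voronoi: %d seeds, %d complete cells, median area %.1f um^2",
      report$voronoi$n_seeds, report$voronoi$n_complete,
      report$voronoi$median_complete_area_um2))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}
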