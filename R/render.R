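#' Render a synthetic confocal-like voxel stack
#'
#' Rasterizes somata and plaques into a 3-channel stack (\code{iba1},
#' \code{gfap}, \code{plaque}). Each soma becomes an isotropic Gaussian blob
#' of amplitude 1 at its position; a dense-core (or PHF/NFT) plaque becomes a
#' filled sphere of its equivalent radius, a fibrillar plaque an annular
#' shell (inner radius half the equivalent radius), intensity 1. Optional
#' additive Gaussian noise emulates detector noise. Voxel (1,1,1) spans the
#' half-open box \code{[0, dx) x [0, dy) x [0, dz)}; array axes are ordered
#' (channel, z, y, x).
#'
#' @param x a [GliaCohort-class] (renders one of its plaque fields), a cell
#'   data.frame as produced by [sampleGlia()], or an n x 2 matrix of 2D
#'   landscape points (rendered as a single-slice \code{iba1} channel).
#' @param plaqueId for cohorts with several plaques: which field to render
#'   (defaults to the first).
#' @param fieldUm field extent (x, y, z), micrometers; defaults to the
#'   cohort's field.
#' @param voxelSizeUm voxel edge lengths (x, y, z); the default
#'   \code{c(0.5, 0.5, 1)} mirrors a confocal stack with 1 um z-step.
#' @param blobSigmaUm Gaussian sigma of a soma blob, micrometers.
#' @param noiseSd additive Gaussian noise sd (0 = noiseless).
#' @param seed seed for the noise.
#' @param plaque optional one-row plaque data.frame when \code{x} is a cell
#'   table.
#' @return a [VoxelStack-class].
#' @examples
#' co <- generateCohort(makePreset("human-dense-core"), 1, seed = 7,
#'                      fieldUm = c(60, 60, 40))
#' st <- renderStack(co, voxelSizeUm = c(1, 1, 2))
#' st
#' @export
renderStack <- function(x, plaqueId = NULL, fieldUm = NULL,
                        voxelSizeUm = c(0.5, 0.5, 1), blobSigmaUm = 1.5,
                        noiseSd = 0, seed = 1L, plaque = NULL) {
  if (is(x, "GliaCohort")) {
    if (is.null(plaqueId)) plaqueId <- x@plaques$plaque_id[1]
    plaque <- x@plaques[x@plaques$plaque_id == plaqueId, , drop = FALSE]
    if (!nrow(plaque)) stop("no plaque with id '", plaqueId, "' in cohort")
    cellTab <- x@cells[x@cells$plaque_id == plaqueId, , drop = FALSE]
    if (is.null(fieldUm)) fieldUm <- x@fieldUm
  } else if (is.matrix(x)) {
    if (ncol(x) != 2) stop("landscape input must be an n x 2 matrix")
    if (is.null(fieldUm))
      fieldUm <- c(max(x[, 1]) + 4 * blobSigmaUm,
                   max(x[, 2]) + 4 * blobSigmaUm, voxelSizeUm[3])
    cellTab <- data.frame(marker = rep("iba1", nrow(x)),
                          x_um = x[, 1], y_um = x[, 2],
                          z_um = fieldUm[3] / 2)
  } else if (is.data.frame(x)) {
    cellTab <- x
    if (is.null(fieldUm)) stop("fieldUm is required for a cell table input")
  } else stop("unsupported input type")
  if (any(voxelSizeUm <= 0)) stop("voxel sizes must be > 0")
  if (blobSigmaUm < max(voxelSizeUm) / 2)
    warning("blob sigma finer than the voxel grid; blobs may alias")

  nx <- max(1L, as.integer(round(fieldUm[1] / voxelSizeUm[1])))
  ny <- max(1L, as.integer(round(fieldUm[2] / voxelSizeUm[2])))
  nz <- max(1L, as.integer(round(fieldUm[3] / voxelSizeUm[3])))
  chans <- c("iba1", "gfap", "plaque")
  vol <- array(0, c(3L, nz, ny, nx))

  # voxel centers along each axis
  cx <- (seq_len(nx) - 0.5) * voxelSizeUm[1]
  cy <- (seq_len(ny) - 0.5) * voxelSizeUm[2]
  cz <- (seq_len(nz) - 0.5) * voxelSizeUm[3]

  addBlob <- function(ch, px, py, pz) {
    ext <- 4 * blobSigmaUm
    ix <- which(abs(cx - px) <= ext)
    iy <- which(abs(cy - py) <= ext)
    iz <- which(abs(cz - pz) <= ext)
    if (!length(ix) || !length(iy) || !length(iz)) return()
    gx <- exp(-(cx[ix] - px)^2 / (2 * blobSigmaUm^2))
    gy <- exp(-(cy[iy] - py)^2 / (2 * blobSigmaUm^2))
    gz <- exp(-(cz[iz] - pz)^2 / (2 * blobSigmaUm^2))
    blob <- outer(outer(gz, gy), gx)  # dims (z, y, x)
    vol[ch, iz, iy, ix] <<- vol[ch, iz, iy, ix] + as.numeric(blob)
  }
  if (nrow(cellTab)) {
    chIdx <- match(cellTab$marker, chans)
    for (i in seq_len(nrow(cellTab)))
      addBlob(chIdx[i], cellTab$x_um[i], cellTab$y_um[i], cellTab$z_um[i])
  }

  if (!is.null(plaque) && nrow(plaque)) {
    for (i in seq_len(nrow(plaque))) {
      R <- plaque$equivalent_radius_um[i]
      p <- c(plaque$cx_um[i], plaque$cy_um[i], plaque$cz_um[i])
      ix <- which(abs(cx - p[1]) <= R)
      iy <- which(abs(cy - p[2]) <= R)
      iz <- which(abs(cz - p[3]) <= R)
      if (!length(ix) || !length(iy) || !length(iz)) next
      d2 <- outer(outer((cz[iz] - p[3])^2, (cy[iy] - p[2])^2, "+"),
                  (cx[ix] - p[1])^2, "+")
      inner <- if (plaque$plaque_class[i] == "fibrillar") (R / 2)^2 else 0
      mask <- d2 <= R^2 & d2 >= inner
      sub <- array(vol[3L, iz, iy, ix], dim(mask))
      sub[mask] <- pmax(sub[mask], 1)
      vol[3L, iz, iy, ix] <- sub
    }
  }

  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    vol <- vol + stats::rnorm(length(vol), 0, noiseSd)
  }
  new("VoxelStack", data = vol, channelNames = chans,
      voxelSizeUm = as.numeric(voxelSizeUm))
}
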