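#' Threshold one channel of a voxel stack
#'
#' Produces a binary mask by either a fixed cutoff or Otsu's method (the
#' threshold maximizing between-class variance over a 256-bin intensity
#' histogram; voxels strictly above the threshold are foreground).
#'
#' @param stack a [VoxelStack-class].
#' @param channel channel name.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param fixedValue cutoff intensity, required when \code{method = "fixed"}.
#' @return logical 3D array (z, y, x).
#' @examples
#' co <- generateCohort(makePreset("human-dense-core"), 1, seed = 3,
#'                      fieldUm = c(50, 50, 30))
#' st <- renderStack(co, voxelSizeUm = c(1, 1, 1))
#' mask <- thresholdChannel(st, "plaque", method = "fixed", fixedValue = 0.5)
#' @export
thresholdChannel <- function(stack, channel, method = c("otsu", "fixed"),
                             fixedValue = NULL) {
  stopifnot(is(stack, "VoxelStack"))
  method <- match.arg(method)
  ci <- match(channel, stack@channelNames)
  if (is.na(ci)) stop("no channel named '", channel, "'")
  d <- dim(stack@data)
  v <- array(stack@data[ci, , , ], d[2:4])
  if (method == "fixed") {
    if (is.null(fixedValue)) stop("fixedValue is required for method 'fixed'")
    return(v > fixedValue)
  }
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("channel has constant intensity; Otsu undefined - use a fixed threshold")
  v > otsuThreshold(v)
}

# Otsu's threshold on a 256-bin histogram: exhaustive search of the
# between-class variance. Returns the threshold on the intensity scale.
otsuThreshold <- function(v, nBins = 256L) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nBins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nBins]
  sb2 <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)
  br[k + 1L]
}

#' Label 26-connected components of a binary volume
#'
#' Foreground voxels touching by face, edge or corner (26-connectivity; for a
#' single-slice input this reduces to 8-connectivity) form one component.
#' Components smaller than \code{minVolumeUm3} are discarded; survivors are
#' renumbered 1..n by decreasing voxel volume. The adjacency graph is built
#' explicitly and resolved with \code{igraph::components}.
#'
#' @param mask logical 3D array (z, y, x); a 2D matrix is treated as one
#'   slice.
#' @param voxelSizeUm voxel edge lengths (x, y, z), micrometers.
#' @param minVolumeUm3 minimum component volume retained; the default 8 um^3
#'   rejects specks far below soma size.
#' @return a [LabeledVolume-class].
#' @export
labelComponents <- function(mask, voxelSizeUm, minVolumeUm3 = 8) {
  if (is.matrix(mask)) mask <- array(mask, c(1L, dim(mask)))
  stopifnot(length(dim(mask)) == 3, is.logical(mask))
  d <- dim(mask)
  labels <- array(0L, d)
  fg <- which(mask)
  if (!length(fg)) {
    return(new("LabeledVolume", labels = labels, nComponents = 0L,
               voxelSizeUm = as.numeric(voxelSizeUm)))
  }
  rank <- array(0L, d)
  rank[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)  # columns: z, y, x (1-based)

  # 13 of the 26 neighbor offsets (lexicographically positive half)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nz <- co[, 1] + offs[k, 1]
    ny <- co[, 2] + offs[k, 2]
    nx <- co[, 3] + offs[k, 3]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    if (!any(ok)) next
    nbIdx <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
    nbRank <- rank[nbIdx]
    hit <- nbRank > 0L
    if (!any(hit)) next
    edges[[k]] <- cbind(rank[fg[ok][hit]], nbRank[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership

  voxVol <- prod(voxelSizeUm)
  sizes <- tabulate(memb)
  keep <- which(sizes * voxVol >= minVolumeUm3)
  if (!length(keep)) {
    return(new("LabeledVolume", labels = labels, nComponents = 0L,
               voxelSizeUm = as.numeric(voxelSizeUm)))
  }
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  labels[fg] <- remap[memb]
  new("LabeledVolume", labels = labels, nComponents = length(ord),
      voxelSizeUm = as.numeric(voxelSizeUm))
}

#' Extract soma centroids from a labeled volume
#'
#' One cell record per component; the position is the unweighted mean of the
#' member voxel centers (voxel center of 1-based index i at
#' \code{(i - 0.5) * voxel size}), respecting anisotropic voxels.
#'
#' @param labeled a [LabeledVolume-class] from a glial channel.
#' @param marker marker label to attach (\code{"iba1"} or \code{"gfap"}).
#' @return cell data.frame (\code{cell_id}, \code{marker}, \code{x_um},
#'   \code{y_um}, \code{z_um}).
#' @export
extractCentroids <- function(labeled, marker) {
  stopifnot(is(labeled, "LabeledVolume"))
  n <- labeled@nComponents
  if (n == 0L)
    return(data.frame(cell_id = character(0), marker = character(0),
                      x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), stringsAsFactors = FALSE))
  idx <- which(labeled@labels > 0L)
  lab <- labeled@labels[idx]
  co <- arrayInd(idx, dim(labeled@labels))  # z, y, x
  vs <- labeled@voxelSizeUm
  pos <- cbind((co[, 3] - 0.5) * vs[1],
               (co[, 2] - 0.5) * vs[2],
               (co[, 1] - 0.5) * vs[3])
  sums <- rowsum(pos, lab)
  cnts <- tabulate(lab, n)
  cent <- sums / cnts
  data.frame(cell_id = sprintf("%s_%03d", marker, seq_len(n)),
             marker = marker,
             x_um = cent[, 1], y_um = cent[, 2], z_um = cent[, 3],
             stringsAsFactors = FALSE)
}

#' Measure the plaque in a labeled plaque channel
#'
#' Takes the largest component as the plaque (warning when smaller ones are
#' ignored); volume is voxel count times voxel volume and the center the
#' unweighted voxel centroid.
#'
#' @param labeled a [LabeledVolume-class] of the plaque channel.
#' @param plaqueClass plaque class label for the record.
#' @param plaqueId identifier.
#' @return one-row plaque data.frame as from [samplePlaque()].
#' @export
measurePlaque <- function(labeled, plaqueClass = "dense_core",
                          plaqueId = "plaque_1") {
  stopifnot(is(labeled, "LabeledVolume"))
  if (labeled@nComponents == 0L) stop("no plaque detected")
  if (labeled@nComponents > 1L)
    warning(labeled@nComponents - 1L,
            " smaller component(s) ignored; largest taken as the plaque")
  idx <- which(labeled@labels == 1L)
  co <- arrayInd(idx, dim(labeled@labels))
  vs <- labeled@voxelSizeUm
  vol <- length(idx) * prod(vs)
  data.frame(
    plaque_id = plaqueId, plaque_class = plaqueClass,
    cx_um = mean((co[, 3] - 0.5) * vs[1]),
    cy_um = mean((co[, 2] - 0.5) * vs[2]),
    cz_um = mean((co[, 1] - 0.5) * vs[3]),
    volume_um3 = vol,
    equivalent_radius_um = (3 * vol / (4 * pi))^(1 / 3),
    stringsAsFactors = FALSE
  )
}

#' Maximum intensity projection of one channel
#'
#' Per-pixel maximum over z, the 2D substrate for Voronoi and
#' nearest-neighbor analysis.
#'
#' @param stack a [VoxelStack-class].
#' @param channel channel name.
#' @return numeric matrix (y, x).
#' @seealso [projectCentroids()] for the companion coordinate mapping.
#' @export
maxProjection <- function(stack, channel) {
  stopifnot(is(stack, "VoxelStack"))
  ci <- match(channel, stack@channelNames)
  if (is.na(ci)) stop("no channel named '", channel, "'")
  d <- dim(stack@data)
  v <- array(stack@data[ci, , , ], d[2:4])
  apply(v, c(2, 3), max)
}

#' Project 3D centroids into the 2D maximum-projection plane
#'
#' Drops the z coordinate; the (x, y) positions are unchanged by the
#' projection.
#'
#' @param cellTab cell data.frame with \code{x_um}, \code{y_um} columns.
#' @return n x 2 matrix (columns \code{x_um}, \code{y_um}).
#' @export
projectCentroids <- function(cellTab) {
  cbind(x_um = cellTab$x_um, y_um = cellTab$y_um)
}

#' Run the full detection stage on a rendered stack
#'
#' Thresholds the two glial channels and the plaque channel, labels
#' components, and returns the recovered cell and plaque tables in the same
#' schema the synthetic generator emits, making downstream stages
#' source-agnostic.
#'
#' @param stack a [VoxelStack-class].
#' @param method threshold method for the glial channels.
#' @param fixedValue cutoff when \code{method = "fixed"}.
#' @param minVolumeUm3 minimum soma component volume, um^3.
#' @param plaqueClass class recorded for the measured plaque.
#' @param plaqueThreshold fixed cutoff for the plaque channel.
#' @return list with elements \code{cells} (data.frame) and \code{plaque}
#'   (one-row data.frame, or NULL when the plaque channel is empty).
#' @export
detectStack <- function(stack, method = c("fixed", "otsu"),
                        fixedValue = 0.25, minVolumeUm3 = 8,
                        plaqueClass = "dense_core", plaqueThreshold = 0.5) {
  method <- match.arg(method)
  vs <- stack@voxelSizeUm
  getCells <- function(channel) {
    mask <- thresholdChannel(stack, channel, method = method,
                             fixedValue = fixedValue)
    extractCentroids(labelComponents(mask, vs, minVolumeUm3), channel)
  }
  cellTab <- rbind(getCells("iba1"), getCells("gfap"))
  plaqueMask <- thresholdChannel(stack, "plaque", method = "fixed",
                                 fixedValue = plaqueThreshold)
  plaqueTab <- if (any(plaqueMask)) {
    measurePlaque(labelComponents(plaqueMask, vs, minVolumeUm3 = 0),
                  plaqueClass = plaqueClass)
  } else NULL
  list(cells = cellTab, plaque = plaqueTab)
}
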