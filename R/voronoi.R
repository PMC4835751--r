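# Clip a convex polygon (n x 2, counter-clockwise) by the half-plane
# {x : a . x <= b} (Sutherland-Hodgman, one edge).
clipHalfPlane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  d <- as.numeric(poly %*% a) - b
  eps <- 1e-9 * (abs(b) + 1)
  inside <- d <= eps
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

shoelaceArea <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Voronoi tessellation of somata clipped to a rectangular ROI
#'
#' Builds each seed's Voronoi cell by intersecting the ROI rectangle with the
#' perpendicular-bisector half-planes against the other seeds (nearest seeds
#' first, stopping once no farther seed can cut the current cell). Cells are
#' clipped to the ROI, so clipped areas partition the ROI exactly; a cell is
#' \emph{complete} when its unclipped cell is bounded and contained in the
#' ROI (operationally: no clipped vertex lies on the ROI boundary). Only
#' complete cells enter area statistics. Duplicate seeds are merged with a
#' warning.
#'
#' @param points n x 2 matrix of soma positions, micrometers, all inside the
#'   ROI; n >= 3 and not all collinear.
#' @param roiUm ROI width and height (origin at (0, 0)).
#' @return a [TessellationResult-class].
#' @examples
#' pts <- rbind(c(250, 250), c(750, 250), c(250, 750), c(750, 750))
#' tessellate(pts, roiUm = c(1000, 1000))
#' @export
tessellate <- function(points, roiUm = c(1000, 1000)) {
  points <- rbind(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) stop("points must be an n x 2 matrix")
  dup <- duplicated(points)
  if (any(dup)) {
    warning(sum(dup), " duplicate seed(s) merged")
    points <- points[!dup, , drop = FALSE]
  }
  n <- nrow(points)
  if (n < 3) stop("tessellation needs at least 3 seeds")
  if (any(points[, 1] < 0 | points[, 1] > roiUm[1] |
          points[, 2] < 0 | points[, 2] > roiUm[2]))
    stop("all seeds must lie inside the ROI")
  cen <- sweep(points, 2, colMeans(points))
  if (abs(cen[, 1] %*% cen[, 2])^2 >=
      (sum(cen[, 1]^2) * sum(cen[, 2]^2)) * (1 - 1e-12) ||
      max(abs(cen)) == 0) {
    # all points collinear iff the centered coordinates are rank 1
    cross <- cen[1, 1] * cen[, 2] - cen[1, 2] * cen[, 1]
    if (all(abs(cross) < 1e-9)) stop("all seeds are collinear")
  }

  roiPoly <- rbind(c(0, 0), c(roiUm[1], 0), c(roiUm[1], roiUm[2]),
                   c(0, roiUm[2]))
  nn <- nearestNeighborDistances(points)
  polys <- vector("list", n)
  areas <- numeric(n)
  complete <- logical(n)
  bEps <- 1e-7 * max(roiUm)
  for (i in seq_len(n)) {
    s <- points[i, ]
    d2 <- (points[, 1] - s[1])^2 + (points[, 2] - s[2])^2
    ord <- order(d2)[-1]
    poly <- roiPoly
    for (j in ord) {
      dj <- sqrt(d2[j])
      # prune: a seed farther than twice the cell's circumradius cannot cut
      maxd <- sqrt(max((poly[, 1] - s[1])^2 + (poly[, 2] - s[2])^2))
      if (dj / 2 > maxd) break
      q <- points[j, ]
      a <- q - s
      b <- sum(a * (s + q)) / 2
      poly <- clipHalfPlane(poly, a, b)
      if (nrow(poly) == 0) break
    }
    polys[[i]] <- poly
    areas[i] <- shoelaceArea(poly)
    onBorder <- any(poly[, 1] < bEps | poly[, 1] > roiUm[1] - bEps |
                    poly[, 2] < bEps | poly[, 2] > roiUm[2] - bEps)
    complete[i] <- !onBorder
  }
  cellsDf <- data.frame(seed_index = seq_len(n),
                        x_um = points[, 1], y_um = points[, 2],
                        area_um2 = areas, complete = complete,
                        nn_distance_um = nn, stringsAsFactors = FALSE)
  compArea <- areas[complete]
  new("TessellationResult",
      cells = cellsDf, polygons = polys, roiUm = as.numeric(roiUm),
      summary = list(
        n_seeds = n,
        n_complete = sum(complete),
        median_complete_area_um2 = if (length(compArea))
          stats::median(compArea) else NA_real_,
        mean_nn_um = mean(nn),
        median_nn_um = stats::median(nn)))
}

#' Classify complete Voronoi cells by area
#'
#' Assigns each complete cell an area class, either by fixed breaks or (by
#' default) by area quantiles; incomplete border cells are excluded (class
#' NA), mirroring analyses that only color-code complete cells.
#'
#' @param result a [TessellationResult-class].
#' @param paletteBreaks optional increasing break points (um^2); when NULL,
#'   \code{nClasses} quantile classes of the complete-cell areas are used.
#' @param nClasses number of quantile classes when no breaks are given.
#' @return integer vector (one entry per seed): class in 1..k, NA for
#'   incomplete cells.
#' @export
areaCode <- function(result, paletteBreaks = NULL, nClasses = 5L) {
  stopifnot(is(result, "TessellationResult"))
  areas <- result@cells$area_um2
  comp <- result@cells$complete
  if (is.null(paletteBreaks)) {
    qs <- stats::quantile(areas[comp],
                          probs = seq(0, 1, length.out = nClasses + 1L),
                          names = FALSE)
    paletteBreaks <- qs[-c(1, length(qs))]
  }
  if (is.unsorted(paletteBreaks, strictly = FALSE))
    stop("paletteBreaks must be increasing")
  cls <- findInterval(areas, paletteBreaks) + 1L
  cls[!comp] <- NA_integer_
  cls
}

#' Nearest-neighbor distances between somata
#'
#' For each point, the Euclidean distance to the closest other point.
#'
#' @param points n x 2 matrix, n >= 2.
#' @return numeric vector of length n.
#' @examples
#' nearestNeighborDistances(rbind(c(0, 0), c(30, 0)))  # 30, 30
#' @export
nearestNeighborDistances <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 2) stop("nearest-neighbor distances need >= 2 points")
  dm <- as.matrix(stats::dist(points))
  diag(dm) <- Inf
  unname(apply(dm, 1, min))
}

#' Render an area-coded tessellation to PNG
#'
#' Visual companion to [tessellate()]: complete cells filled by area class
#' (darker = smaller territory), incomplete border cells hatched grey, seeds
#' overdrawn as points.
#'
#' @param result a [TessellationResult-class].
#' @param path output PNG path.
#' @param nClasses number of area classes.
#' @return invisibly, the path.
#' @export
plotTessellation <- function(result, path, nClasses = 5L) {
  cls <- areaCode(result, nClasses = nClasses)
  pal <- grDevices::hcl.colors(nClasses, "Blues", rev = TRUE)
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = c(0, result@roiUm[1]),
                 ylim = c(0, result@roiUm[2]), asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = "Voronoi territories (area-coded)")
  for (i in seq_along(result@polygons)) {
    p <- result@polygons[[i]]
    if (nrow(p) < 3) next
    col <- if (is.na(cls[i])) "grey85" else pal[cls[i]]
    graphics::polygon(p[, 1], p[, 2], col = col, border = "grey40")
  }
  graphics::points(result@cells$x_um, result@cells$y_um, pch = 16,
                   cex = 0.6)
  invisible(path)
}
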