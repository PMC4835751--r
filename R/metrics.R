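#' Radial distances of somata from a plaque center
#'
#' Euclidean 3D distances from the plaque center to every cell of the given
#' marker, restricted to the stated maximum radius, sorted ascending.
#' Distances are measured to the plaque center, not its surface.
#'
#' @param cellTab cell data.frame (\code{marker}, \code{x_um}, \code{y_um},
#'   \code{z_um}).
#' @param centerUm plaque center, length-3 (x, y, z), micrometers.
#' @param marker \code{"iba1"} or \code{"gfap"}.
#' @param maxRadiusUm maximum radius retained, > 0; beyond it cells count as
#'   background. Default 100 um.
#' @return sorted numeric vector of distances (possibly empty).
#' @export
radialDistances <- function(cellTab, centerUm, marker, maxRadiusUm = 100) {
  if (!(maxRadiusUm > 0)) stop("maxRadiusUm must be > 0")
  sel <- cellTab$marker == marker
  d <- sqrt((cellTab$x_um[sel] - centerUm[1])^2 +
            (cellTab$y_um[sel] - centerUm[2])^2 +
            (cellTab$z_um[sel] - centerUm[3])^2)
  sort(d[d <= maxRadiusUm])
}

#' Bin radial distances into a per-marker histogram
#'
#' Half-open bins \code{[k w, (k+1) w)}; the outermost bin is closed above so
#' that every distance \code{<= maxRadiusUm} is counted (conservation). When
#' the bin width does not divide the maximum radius the last bin is shortened
#' and the histogram flagged.
#'
#' @param distances named list with numeric elements \code{iba1} and
#'   \code{gfap} (as from [radialDistances()]).
#' @param binWidthUm bin width, > 0; default 10 um.
#' @param maxRadiusUm outer limit of the histogram.
#' @return a [RadialHistogram-class].
#' @examples
#' h <- radialHistogram(list(iba1 = c(5, 15, 15), gfap = c(35)),
#'                      binWidthUm = 10, maxRadiusUm = 50)
#' h@counts
#' @export
radialHistogram <- function(distances, binWidthUm = 10, maxRadiusUm = 100) {
  if (!(binWidthUm > 0)) stop("binWidthUm must be > 0")
  edges <- seq(0, maxRadiusUm, by = binWidthUm)
  truncated <- FALSE
  if (edges[length(edges)] < maxRadiusUm) {
    edges <- c(edges, maxRadiusUm)
    truncated <- TRUE
    warning("bin width does not divide the maximum radius; last bin truncated")
  }
  nb <- length(edges) - 1L
  countOne <- function(d) {
    d <- d[d >= 0 & d <= maxRadiusUm]
    b <- findInterval(d, edges, rightmost.closed = TRUE)
    tabulate(b, nb)
  }
  counts <- cbind(iba1 = countOne(distances$iba1),
                  gfap = countOne(distances$gfap))
  new("RadialHistogram", binEdgesUm = edges, counts = counts,
      truncatedLastBin = truncated)
}

#' The interval-max-GFAP statistic
#'
#' The radial bin holding the maximum number of GFAP+ somata; ties break
#' toward the innermost bin (conservative: the smaller net). Its outer edge
#' defines the net boundary used for intra-net microglia classification.
#'
#' @param hist a [RadialHistogram-class].
#' @return numeric (lo, hi): the bin edges, micrometers.
#' @examples
#' h <- radialHistogram(list(iba1 = numeric(0), gfap = c(22, 25, 31)),
#'                      binWidthUm = 10, maxRadiusUm = 50)
#' intervalMaxGfap(h)  # c(20, 30)
#' @export
intervalMaxGfap <- function(hist) {
  stopifnot(is(hist, "RadialHistogram"))
  g <- hist@counts[, "gfap"]
  if (sum(g) == 0) stop("RGN undefined: no GFAP+ cell in the histogram")
  k <- which.max(g)  # which.max returns the first (innermost) maximum
  c(lo = hist@binEdgesUm[k], hi = hist@binEdgesUm[k + 1L])
}

#' Count microglia inside the net boundary
#'
#' @param iba1Distances radial distances of Iba1+ cells, micrometers.
#' @param boundaryUm net boundary, > 0.
#' @return integer count of distances \code{<= boundaryUm}.
#' @export
countIntraRgn <- function(iba1Distances, boundaryUm) {
  if (!(boundaryUm > 0)) stop("boundaryUm must be > 0")
  sum(iba1Distances <= boundaryUm)
}

#' Profile one plaque: radial structure, net boundary and counts
#'
#' Composes [radialDistances()], [radialHistogram()], [intervalMaxGfap()]
#' and [countIntraRgn()] into the per-plaque measurement bundle. A plaque
#' with no GFAP+ cell within the maximum radius yields a profile flagged
#' \code{gfapDefined = FALSE} (interval, boundary and intra-net count NA);
#' such profiles are excluded from cohort statistics.
#'
#' @param plaque one-row plaque data.frame.
#' @param cellTab cell data.frame (cells of this plaque's field).
#' @param binWidthUm histogram bin width; default 10 um (all reported shell
#'   positions lie on a 10 um grid).
#' @param maxRadiusUm maximum radius; default 100 um.
#' @return an [RGNProfile-class].
#' @export
profilePlaque <- function(plaque, cellTab, binWidthUm = 10,
                          maxRadiusUm = 100) {
  stopifnot(nrow(plaque) == 1)
  center <- c(plaque$cx_um, plaque$cy_um, plaque$cz_um)
  d <- list(iba1 = radialDistances(cellTab, center, "iba1", maxRadiusUm),
            gfap = radialDistances(cellTab, center, "gfap", maxRadiusUm))
  h <- radialHistogram(d, binWidthUm, maxRadiusUm)
  if (length(d$gfap) == 0) {
    return(new("RGNProfile",
               plaqueId = as.character(plaque$plaque_id),
               plaqueClass = as.character(plaque$plaque_class),
               volumeUm3 = plaque$volume_um3,
               intervalMaxGfapUm = c(NA_real_, NA_real_),
               rgnBoundaryUm = NA_real_,
               nIba1Total = length(d$iba1),
               nIba1IntraRgn = NA_integer_,
               nGfap = 0L,
               distances = d, histogram = h, gfapDefined = FALSE))
  }
  iv <- intervalMaxGfap(h)
  boundary <- unname(iv[2])
  new("RGNProfile",
      plaqueId = as.character(plaque$plaque_id),
      plaqueClass = as.character(plaque$plaque_class),
      volumeUm3 = plaque$volume_um3,
      intervalMaxGfapUm = unname(iv),
      rgnBoundaryUm = boundary,
      nIba1Total = length(d$iba1),
      nIba1IntraRgn = as.integer(countIntraRgn(d$iba1, boundary)),
      nGfap = length(d$gfap),
      distances = d, histogram = h, gfapDefined = TRUE)
}

#' Profile every plaque of a cohort
#'
#' @param cohort a [GliaCohort-class], or a list with \code{plaques} and
#'   \code{cells} data.frames.
#' @param binWidthUm,maxRadiusUm passed to [profilePlaque()].
#' @return data.frame with one row per plaque: \code{plaque_id},
#'   \code{plaque_class}, \code{volume_um3}, \code{interval_lo_um},
#'   \code{interval_hi_um}, \code{rgn_boundary_um}, \code{n_iba1_total},
#'   \code{n_iba1_intra_rgn}, \code{n_gfap}, \code{gfap_defined}. The
#'   excluded (net-undefined) plaque ids are attached as attribute
#'   \code{"excluded"}.
#' @export
profileCohort <- function(cohort, binWidthUm = 10, maxRadiusUm = 100) {
  if (is(cohort, "GliaCohort")) {
    plq <- cohort@plaques; cl <- cohort@cells
  } else {
    plq <- cohort$plaques; cl <- cohort$cells
  }
  rows <- vector("list", nrow(plq))
  cellIdx <- split(seq_len(nrow(cl)), cl$plaque_id)
  for (k in seq_len(nrow(plq))) {
    p <- plq[k, , drop = FALSE]
    sub <- cl[cellIdx[[p$plaque_id]], , drop = FALSE]
    pr <- profilePlaque(p, sub, binWidthUm, maxRadiusUm)
    rows[[k]] <- data.frame(
      plaque_id = pr@plaqueId, plaque_class = pr@plaqueClass,
      volume_um3 = pr@volumeUm3,
      interval_lo_um = pr@intervalMaxGfapUm[1],
      interval_hi_um = pr@intervalMaxGfapUm[2],
      rgn_boundary_um = pr@rgnBoundaryUm,
      n_iba1_total = pr@nIba1Total,
      n_iba1_intra_rgn = pr@nIba1IntraRgn,
      n_gfap = pr@nGfap,
      gfap_defined = pr@gfapDefined,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- out$plaque_id[!out$gfap_defined]
  out
}

#' Cohort-level recruitment correlations
#'
#' Pearson correlations of (count, plaque volume) across the valid profiles
#' of a cohort, for total Iba1+, intra-net Iba1+ and GFAP+ counts. Profiles
#' with an undefined net are excluded. A zero-variance count yields NA with
#' an \code{undefined} flag rather than 0.
#'
#' @param profiles data.frame from [profileCohort()].
#' @return list: \code{r_iba1_total}, \code{r_iba1_intra_rgn},
#'   \code{r_gfap}, \code{n_plaques}, \code{undefined} (character vector of
#'   flagged correlations).
#' @export
recruitmentCorrelations <- function(profiles) {
  ok <- profiles$gfap_defined
  p <- profiles[ok, , drop = FALSE]
  if (nrow(p) < 3)
    stop("at least 3 valid profiles are required for correlations")
  undef <- character(0)
  rOf <- function(x, label) {
    if (stats::sd(x) == 0 || stats::sd(p$volume_um3) == 0) {
      undef <<- c(undef, label)
      return(NA_real_)
    }
    stats::cor(x, p$volume_um3)
  }
  res <- list(
    r_iba1_total = rOf(p$n_iba1_total, "r_iba1_total"),
    r_iba1_intra_rgn = rOf(p$n_iba1_intra_rgn, "r_iba1_intra_rgn"),
    r_gfap = rOf(p$n_gfap, "r_gfap"),
    n_plaques = nrow(p))
  res$undefined <- undef
  res
}
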