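DEFAULT_FIELD_UM <- c(220, 220, 220)
DEFAULT_VOLUME_RANGE_UM3 <- c(500, 20000)

# Truncated-normal sampling by inversion: exact, vectorized, no rejection.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower >= upper) stop("empty truncation interval")
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Moments of the log-uniform volume law on [a, b]: V = exp(U),
# U ~ Uniform(log a, log b).
logUniformSd <- function(range) {
  a <- range[1]; b <- range[2]
  if (!(a > 0) || !(b > a)) stop("volume range must satisfy 0 < min < max")
  L <- log(b) - log(a)
  m1 <- (b - a) / L
  m2 <- (b^2 - a^2) / (2 * L)
  sqrt(m2 - m1^2)
}

#' Count-noise standard deviations implied by a preset's target correlations
#'
#' The generator draws shell counts as
#' \code{round(base + slope * V + eps)}, \code{eps ~ N(0, sd)}. For a target
#' population Pearson correlation \code{rho} between count and volume, the
#' noise sd follows in closed form from the volume variance:
#' \code{sd = slope * sd(V) * sqrt(1 / rho^2 - 1)}. The volume sd is the
#' analytic sd of the log-uniform law over \code{volumeRange}. When a slope
#' is zero (or the target is zero) the correlation is vacuously ~0 and a
#' Poisson-like \code{sqrt(base)} noise is used instead.
#'
#' @param preset an [RGNPreset-class].
#' @param volumeRangeUm3 the cohort's volume range, cubic micrometers.
#' @return named numeric: noise sd for \code{iba1} and \code{gfap}.
#' @export
countNoiseSd <- function(preset, volumeRangeUm3 = DEFAULT_VOLUME_RANGE_UM3) {
  sdV <- logUniformSd(volumeRangeUm3)
  one <- function(slope, base, rho) {
    if (slope <= 0 || abs(rho) < 1e-8) return(sqrt(max(base, 1)))
    slope * sdV * sqrt(1 / rho^2 - 1)
  }
  c(iba1 = one(preset@microgliaSlopePerUm3, preset@microgliaBaseCount,
               preset@targetR[["iba1"]]),
    gfap = one(preset@gfapSlopePerUm3, preset@gfapBaseCount,
               preset@targetR[["gfap"]]))
}

#' Create one plaque record
#'
#' Places a plaque of the given volume at the center of the field of view and
#' derives the equivalent spherical radius \code{(3V / 4 pi)^(1/3)}.
#'
#' @param preset an [RGNPreset-class]; fixes the plaque class.
#' @param volumeUm3 plaque volume (for PHF/NFT aggregates: aggregate extent),
#'   cubic micrometers, > 0.
#' @param seed integer seed (kept for interface symmetry; the record is
#'   deterministic given its arguments).
#' @param fieldUm field-of-view side lengths (x, y, z), micrometers.
#' @param plaqueId identifier.
#' @return one-row plaque data.frame (columns \code{plaque_id},
#'   \code{plaque_class}, \code{cx_um}, \code{cy_um}, \code{cz_um},
#'   \code{volume_um3}, \code{equivalent_radius_um}).
#' @examples
#' samplePlaque(makePreset("human-dense-core"), volumeUm3 = 4188.79, seed = 1)
#' @export
samplePlaque <- function(preset, volumeUm3, seed = 1L,
                         fieldUm = DEFAULT_FIELD_UM, plaqueId = "plaque_1") {
  stopifnot(is(preset, "RGNPreset"))
  if (!is.numeric(volumeUm3) || length(volumeUm3) != 1 || volumeUm3 <= 0)
    stop("volumeUm3 must be a single positive volume")
  data.frame(
    plaque_id = plaqueId,
    plaque_class = preset@plaqueClass,
    cx_um = fieldUm[1] / 2, cy_um = fieldUm[2] / 2, cz_um = fieldUm[3] / 2,
    volume_um3 = volumeUm3,
    equivalent_radius_um = (3 * volumeUm3 / (4 * pi))^(1 / 3),
    stringsAsFactors = FALSE
  )
}

#' Simulate glial somata around one plaque
#'
#' Shell somata are placed at radial distances drawn from the preset's
#' marker-specific truncated normal (truncated below at the larger of the
#' preset core radius and the plaque's equivalent radius; astrocytes also
#' truncated above at \code{astroMaxUm}), in directions uniform on the
#' sphere. Shell counts are \code{round(base + slope * V + eps)} with
#' \code{eps} calibrated via [countNoiseSd()] (negative counts clamp to 0
#' with a warning). Background somata are placed uniformly in the field at
#' the preset density. The ground-truth \code{origin} column distinguishes
#' shell from background cells.
#'
#' @param plaque one-row plaque data.frame from [samplePlaque()].
#' @param preset the matching [RGNPreset-class].
#' @param seed integer seed for this plaque's stream.
#' @param fieldUm field-of-view side lengths (x, y, z), micrometers.
#' @param noiseSd optional named numeric (\code{iba1}, \code{gfap}) count
#'   noise SDs; default derives them from the preset and the default volume
#'   range. Pass \code{c(iba1 = 0, gfap = 0)} for deterministic counts.
#' @return cell data.frame (columns \code{cell_id}, \code{marker},
#'   \code{x_um}, \code{y_um}, \code{z_um}, \code{plaque_id},
#'   \code{origin}).
#' @examples
#' pre <- makePreset("human-dense-core")
#' pl <- samplePlaque(pre, 5000, seed = 1)
#' head(sampleGlia(pl, pre, seed = 1))
#' @export
sampleGlia <- function(plaque, preset, seed, fieldUm = DEFAULT_FIELD_UM,
                       noiseSd = NULL) {
  stopifnot(is(preset, "RGNPreset"), nrow(plaque) == 1)
  if (plaque$plaque_class != preset@plaqueClass)
    stop("plaque and preset disagree on plaque class")
  if (is.null(noiseSd)) noiseSd <- countNoiseSd(preset)
  set.seed(as.integer(seed))
  center <- c(plaque$cx_um, plaque$cy_um, plaque$cz_um)
  v <- plaque$volume_um3
  lower <- max(preset@coreRadiusUm, plaque$equivalent_radius_um)

  drawCount <- function(base, slope, sd) {
    n <- round(base + slope * v + stats::rnorm(1, 0, sd))
    if (n < 0) {
      warning("computed shell count below zero; clamped to 0")
      n <- 0
    }
    as.integer(n)
  }
  nIba <- drawCount(preset@microgliaBaseCount, preset@microgliaSlopePerUm3,
                    noiseSd[["iba1"]])
  nGfap <- drawCount(preset@gfapBaseCount, preset@gfapSlopePerUm3,
                     noiseSd[["gfap"]])

  shell <- function(n, mean, sd, upper) {
    if (n == 0) return(matrix(numeric(0), 0, 3))
    r <- rtruncnorm(n, mean, sd, lower = lower, upper = upper)
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    sweep(u * r, 2, center, "+")
  }
  posIba <- shell(nIba, preset@microgliaShellMeanUm,
                  preset@microgliaShellSdUm, Inf)
  posGfap <- shell(nGfap, preset@astroShellMeanUm, preset@astroShellSdUm,
                   preset@astroMaxUm)

  fieldMm3 <- prod(fieldUm) * 1e-9
  lambda <- preset@backgroundDensityPerMm3 * fieldMm3
  bg <- function() {
    n <- stats::rpois(1, lambda)
    if (n == 0) return(matrix(numeric(0), 0, 3))
    cbind(stats::runif(n, 0, fieldUm[1]), stats::runif(n, 0, fieldUm[2]),
          stats::runif(n, 0, fieldUm[3]))
  }
  bgIba <- bg(); bgGfap <- bg()

  pos <- rbind(posIba, bgIba, posGfap, bgGfap)
  marker <- rep(c("iba1", "gfap"),
                c(nrow(posIba) + nrow(bgIba), nrow(posGfap) + nrow(bgGfap)))
  origin <- c(rep("shell", nrow(posIba)), rep("background", nrow(bgIba)),
              rep("shell", nrow(posGfap)), rep("background", nrow(bgGfap)))
  n <- nrow(pos)
  data.frame(
    cell_id = if (n) paste(plaque$plaque_id, marker, seq_len(n), sep = "_")
              else character(0),
    marker = marker,
    x_um = if (n) pos[, 1] else numeric(0),
    y_um = if (n) pos[, 2] else numeric(0),
    z_um = if (n) pos[, 3] else numeric(0),
    plaque_id = rep(plaque$plaque_id, n),
    origin = origin,
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded cohort of plaques with surrounding glia
#'
#' Plaque volumes are drawn log-uniformly over \code{volumeRangeUm3}; each
#' plaque then gets its own derived seed (drawn once from the master stream)
#' and an independent field, so cohorts are reproducible element-wise. The
#' count-noise calibration uses the analytic volume sd of the requested
#' range, so the cohort-level count--volume Pearson correlation matches the
#' preset's \code{targetR}.
#'
#' @param preset an [RGNPreset-class].
#' @param nPlaques number of plaques, >= 1.
#' @param volumeRangeUm3 interval (min, max) of plaque volumes, um^3.
#' @param seed master integer seed.
#' @param fieldUm per-plaque field-of-view side lengths, micrometers.
#' @return a [GliaCohort-class].
#' @examples
#' co <- generateCohort(makePreset("mouse-mid"), nPlaques = 5, seed = 42)
#' co
#' @export
generateCohort <- function(preset, nPlaques,
                           volumeRangeUm3 = DEFAULT_VOLUME_RANGE_UM3,
                           seed = 1L, fieldUm = DEFAULT_FIELD_UM) {
  stopifnot(is(preset, "RGNPreset"))
  if (nPlaques < 1) stop("nPlaques must be >= 1")
  if (length(volumeRangeUm3) != 2 || !(volumeRangeUm3[1] > 0) ||
      !(volumeRangeUm3[2] > volumeRangeUm3[1]))
    stop("volumeRangeUm3 must be an interval with 0 < min < max")
  seed <- as.integer(seed)
  set.seed(seed)
  volumes <- exp(stats::runif(nPlaques, log(volumeRangeUm3[1]),
                              log(volumeRangeUm3[2])))
  plaqueSeeds <- sample.int(.Machine$integer.max - 1L, nPlaques)
  noiseSd <- countNoiseSd(preset, volumeRangeUm3)

  ids <- sprintf("plaque_%03d", seq_len(nPlaques))
  plaqueList <- vector("list", nPlaques)
  cellList <- vector("list", nPlaques)
  for (k in seq_len(nPlaques)) {
    pl <- samplePlaque(preset, volumes[k], seed = plaqueSeeds[k],
                       fieldUm = fieldUm, plaqueId = ids[k])
    plaqueList[[k]] <- pl
    cellList[[k]] <- sampleGlia(pl, preset, seed = plaqueSeeds[k],
                                fieldUm = fieldUm, noiseSd = noiseSd)
  }
  new("GliaCohort",
      plaques = do.call(rbind, plaqueList),
      cells = do.call(rbind, cellList),
      preset = preset,
      fieldUm = as.numeric(fieldUm),
      seed = seed,
      groundTruth = list(
        preset_name = preset@name,
        plaque_seeds = plaqueSeeds,
        volume_range_um3 = volumeRangeUm3,
        count_noise_sd = as.list(noiseSd),
        field_um = as.numeric(fieldUm)
      ))
}

#' Describe a 2D microglial landscape
#'
#' Constructor for [LandscapeSpec-class]; see that class for the parameter
#' semantics.
#'
#' @param roiUm ROI width and height, micrometers.
#' @param mode \code{"homogeneous"} or \code{"plaque_perturbed"}.
#' @param nMicroglia number of somata (>= 3).
#' @param plaqueCenters n x 2 matrix of plaque centers (ignored in
#'   homogeneous mode).
#' @param aggregationRadiusUm,depletionOuterUm,aggregationFraction
#'   perturbation parameters: cells found in the annulus
#'   (aggregation, depletion) around a plaque are relocated into the
#'   aggregation disc with the given probability.
#' @return a [LandscapeSpec-class].
#' @export
landscapeSpec <- function(roiUm = c(1000, 1000), mode = "homogeneous",
                          nMicroglia = 100L,
                          plaqueCenters = matrix(numeric(0), 0, 2),
                          aggregationRadiusUm = 50,
                          depletionOuterUm = 150,
                          aggregationFraction = 0.7) {
  new("LandscapeSpec", roiUm = as.numeric(roiUm), mode = mode,
      nMicroglia = as.integer(nMicroglia),
      plaqueCenters = rbind(plaqueCenters),
      aggregationRadiusUm = aggregationRadiusUm,
      depletionOuterUm = depletionOuterUm,
      aggregationFraction = aggregationFraction)
}

#' Generate a 2D microglial landscape
#'
#' Homogeneous mode scatters somata uniformly in the ROI. Plaque-perturbed
#' mode starts from the same uniform draw (so a zero aggregation fraction
#' reproduces the homogeneous pattern under the same seed), then relocates
#' the stated fraction of the somata lying in the depletion annulus of a
#' plaque into the aggregation disc of a (random) plaque, producing the
#' aggregation-near-plaques / depletion-nearby signature seen in diseased
#' tissue.
#'
#' @param spec a [LandscapeSpec-class].
#' @param seed integer seed.
#' @return n x 2 matrix of soma positions (columns \code{x_um},
#'   \code{y_um}).
#' @examples
#' pts <- generateLandscape(landscapeSpec(nMicroglia = 50), seed = 1)
#' @export
generateLandscape <- function(spec, seed = 1L) {
  stopifnot(is(spec, "LandscapeSpec"))
  validObject(spec)
  set.seed(as.integer(seed))
  n <- spec@nMicroglia
  pts <- cbind(x_um = stats::runif(n, 0, spec@roiUm[1]),
               y_um = stats::runif(n, 0, spec@roiUm[2]))
  if (spec@mode == "homogeneous" || spec@aggregationFraction == 0)
    return(pts)

  centers <- spec@plaqueCenters
  d2 <- sapply(seq_len(nrow(centers)), function(j)
    (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2)
  d2 <- matrix(d2, nrow = n)
  dmin <- sqrt(apply(d2, 1, min))
  inAnnulus <- which(dmin > spec@aggregationRadiusUm &
                     dmin <= spec@depletionOuterUm)
  nMove <- round(spec@aggregationFraction * length(inAnnulus))
  if (nMove > 0) {
    move <- sample(inAnnulus, nMove)
    which.plaque <- sample.int(nrow(centers), nMove, replace = TRUE)
    r <- spec@aggregationRadiusUm * sqrt(stats::runif(nMove))
    th <- stats::runif(nMove, 0, 2 * pi)
    nx <- centers[which.plaque, 1] + r * cos(th)
    ny <- centers[which.plaque, 2] + r * sin(th)
    # keep relocated somata inside the ROI
    pts[move, 1] <- pmin(pmax(nx, 0), spec@roiUm[1])
    pts[move, 2] <- pmin(pmax(ny, 0), spec@roiUm[2])
  }
  pts
}
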