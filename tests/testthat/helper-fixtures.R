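# Shared fixtures and independent brute-force oracles.

fieldCenter <- function(fieldUm = c(220, 220, 220)) fieldUm / 2

# cells data.frame from raw positions
makeCellTable <- function(pos, marker, plaqueId = "p1", origin = "shell") {
  pos <- rbind(pos)
  n <- nrow(pos)
  data.frame(cell_id = sprintf("c%d", seq_len(n)),
             marker = rep(marker, length.out = n),
             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
             plaque_id = rep(plaqueId, n), origin = rep(origin, n),
             stringsAsFactors = FALSE)
}

# positions with a guaranteed minimum pairwise separation (rejection)
separatedPositions <- function(n, lo, hi, minSep) {
  pos <- matrix(numeric(0), 0, 3)
  while (nrow(pos) < n) {
    cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
              runif(1, lo[3], hi[3]))
    if (!nrow(pos) || min(sqrt(colSums((t(pos) - cand)^2))) > minSep)
      pos <- rbind(pos, cand)
  }
  unname(pos)
}

# --- brute-force oracles (deliberately naive, independent of the package) ---

bruteRadialDistances <- function(cellTab, center, marker, maxRadius) {
  out <- numeric(0)
  for (i in seq_len(nrow(cellTab))) {
    if (cellTab$marker[i] != marker) next
    d <- sqrt((cellTab$x_um[i] - center[1])^2 +
              (cellTab$y_um[i] - center[2])^2 +
              (cellTab$z_um[i] - center[3])^2)
    if (d <= maxRadius) out <- c(out, d)
  }
  sort(out)
}

bruteHistogram <- function(d, width, maxR) {
  nb <- ceiling(maxR / width)
  counts <- integer(nb)
  for (x in d) {
    if (x > maxR) next
    b <- floor(x / width) + 1L
    if (b > nb) b <- nb  # outermost bin closed above
    counts[b] <- counts[b] + 1L
  }
  counts
}

bruteArgmaxBin <- function(counts, width) {
  best <- 1L
  for (k in seq_along(counts)) if (counts[k] > counts[best]) best <- k
  c((best - 1L) * width, best * width)
}

bruteNN <- function(pts) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# 26-connected flood fill, naive queue version
bruteFloodLabels <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(v, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        z <- ci[1] + dz; y <- ci[2] + dy; x <- ci[3] + dx
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        idx <- z + (y - 1L) * d[1] + (x - 1L) * d[1] * d[2]
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- cur
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}
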