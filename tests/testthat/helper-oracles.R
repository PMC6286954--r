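# Independent brute-force oracles. These deliberately re-derive each
# operation from its definition (double loops, linear scans, set arithmetic)
# and never share code with the implementation under test.

# local mean threshold: double loop over windows
oracle_adaptive_threshold <- function(v, window, sensitivity) {
  k <- (window - 1) %/% 2
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(v[r, c])) next
      rs <- max(1, r - k):min(nr, r + k)
      cs <- max(1, c - k):min(nc, c + k)
      mu <- mean(v[rs, cs], na.rm = TRUE)
      out[r, c] <- v[r, c] > sensitivity * mu
    }
  }
  out
}

# BFS flood-fill labelling, raster-scan discovery order
oracle_flood_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  nbr <- if (connectivity == 8) {
    list(c(-1, 0), c(0, 1), c(1, 0), c(0, -1),
         c(-1, 1), c(1, 1), c(1, -1), c(-1, -1))
  } else {
    list(c(-1, 0), c(0, 1), c(1, 0), c(0, -1))
  }
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in nbr) {
        r2 <- p[1] + d[1]; c2 <- p[2] + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# dilation by the diamond via explicit set arithmetic
oracle_dilate_diamond <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (di in -radius:radius) {
      rem <- radius - abs(di)
      for (dj in -rem:rem) {
        r2 <- r + di; c2 <- c + dj
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) out[r2, c2] <- TRUE
      }
    }
  }
  out
}

oracle_erode_diamond <- function(mask, radius) {
  # erosion keeps a cell iff every ball cell inside the grid is foreground;
  # outside the grid counts as foreground (padding-with-1), the convention
  # that keeps closing extensive on a bounded raster
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    keep <- TRUE
    for (di in -radius:radius) {
      rem <- radius - abs(di)
      for (dj in -rem:rem) {
        r2 <- r + di; c2 <- c + dj
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!mask[r2, c2]) { keep <- FALSE; break }
      }
      if (!keep) break
    }
    out[r, c] <- keep
  }
  out
}

oracle_close_diamond <- function(mask, radius) {
  oracle_erode_diamond(oracle_dilate_diamond(mask, radius), radius)
}

# ordered flooding, linear-scan realization of the watershed contract:
# highest candidate first, FIFO among equal heights, neighbours appended in
# N, E, S, W, NE, SE, SW, NW order, seeds taken in raster-scan order
oracle_watershed <- function(height, markers, foliage) {
  nr <- nrow(height); nc <- ncol(height)
  nbr <- list(c(-1, 0), c(0, 1), c(1, 0), c(0, -1),
              c(-1, 1), c(1, 1), c(1, -1), c(-1, -1))
  out <- markers
  cand <- data.frame(r = integer(), c = integer(), lab = integer(),
                     h = numeric(), ord = integer())
  ordn <- 0L
  push <- function(cand, r, c, lab) {
    for (d in nbr) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!foliage[r2, c2] || out[r2, c2] != 0L || is.na(height[r2, c2])) next
      ordn <<- ordn + 1L
      cand[nrow(cand) + 1L, ] <- list(r2, c2, lab, height[r2, c2], ordn)
    }
    cand
  }
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (markers[r, c] > 0L) cand <- push(cand, r, c, markers[r, c])
  while (nrow(cand)) {
    i <- which(cand$h == max(cand$h))
    i <- i[which.min(cand$ord[i])]
    p <- cand[i, ]
    cand <- cand[-i, , drop = FALSE]
    if (out[p$r, p$c] != 0L) next
    out[p$r, p$c] <- p$lab
    cand <- push(cand, p$r, p$c, p$lab)
  }
  out
}

# even-odd point-in-polygon with boundary-inclusive rule (per-point loop)
oracle_point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    # on-edge?
    dx <- vx[j] - vx[i]; dy <- vy[j] - vy[i]
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) max(0, min(1, ((px - vx[i]) * dx + (py - vy[i]) * dy) / len2)) else 0
    if ((px - (vx[i] + t * dx))^2 + (py - (vy[i] + t * dy))^2 <= eps^2) return(TRUE)
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# a small random watershed scene: quantized heights (to force height ties),
# random foliage, 1-3 single-or-block markers placed inside foliage
random_watershed_scene <- function(nr, nc, n_markers) {
  height <- matrix(round(runif(nr * nc, 0, 3), 1), nr, nc)
  foliage <- matrix(runif(nr * nc) < 0.7, nr, nc)
  markers <- matrix(0L, nr, nc)
  open <- which(foliage)
  if (length(open) < n_markers) foliage[seq_len(n_markers)] <- TRUE
  open <- which(foliage)
  picks <- sample(open, n_markers)
  for (k in seq_len(n_markers)) {
    i <- picks[k]
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    markers[r, c] <- k
    # sometimes grow the marker into a small block (still inside foliage)
    if (runif(1) < 0.5 && r < nr && foliage[r + 1, c] && markers[r + 1, c] == 0L)
      markers[r + 1, c] <- k
  }
  list(height = height, markers = markers, foliage = foliage)
}
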