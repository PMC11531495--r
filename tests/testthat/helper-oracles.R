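# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately naive (scalar loops, O(n^2) scans) and share no code
# with the package internals.

# flood fill by explicit queue-based BFS, one pixel at a time
oracle_flood_fill <- function(eligible, seed_row, seed_col,
                              connectivity = 8) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  offsets <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    ll <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr != 0 || dc != 0) ll[[length(ll) + 1]] <- c(dr, dc)
    }
    ll
  }
  visited <- matrix(FALSE, nr, nc)
  stack_r <- integer(nr * nc)
  stack_c <- integer(nr * nc)
  stack_r[1] <- seed_row; stack_c[1] <- seed_col
  top <- 1L
  visited[seed_row, seed_col] <- TRUE
  while (top > 0L) {
    pr <- stack_r[top]; pc <- stack_c[top]
    top <- top - 1L
    for (off in offsets) {
      r <- pr + off[1]; c <- pc + off[2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          eligible[r, c] && !visited[r, c]) {
        visited[r, c] <- TRUE
        top <- top + 1L
        stack_r[top] <- r; stack_c[top] <- c
      }
    }
  }
  which(visited)
}

# per-pixel Euclidean distance of each foreground pixel to the nearest
# in-image background pixel
oracle_edge_ring <- function(mask, ring_width) {
  bg <- which(!mask, arr.ind = TRUE)
  edge <- matrix(FALSE, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    if (min(d2) <= ring_width^2) edge[fg[i, 1], fg[i, 2]] <- TRUE
  }
  edge
}

# exhaustive peak scan with literal topographic prominence: for each strict
# local maximum (plateaus: first index of a run strictly above both
# flanking runs), walk out to the nearest strictly higher value on each
# side and take the minimum en route; prominence is height minus the
# higher of the two minima
oracle_peaks <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    left_ok <- i > 1 && x[i - 1] < x[i]
    right_ok <- j < n && x[j + 1] < x[i]
    if (left_ok && right_ok) peaks <- c(peaks, i)
    i <- j + 1
  }
  prom <- vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    k <- p - 1
    while (k >= 1 && x[k] <= h) { lmin <- min(lmin, x[k]); k <- k - 1 }
    if (k < 1) lmin <- min(x[1:p])
    rmin <- h
    k <- p + 1
    while (k <= n && x[k] <= h) { rmin <- min(rmin, x[k]); k <- k + 1 }
    if (k > n) rmin <- min(x[p:n])
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(peak = peaks, prominence = prom)
}

# O(n^2) per-frame neighbor scan
oracle_neighbors <- function(traces, dying_id, death_frame, radius,
                             window = 10) {
  win <- (death_frame - window):(death_frame - 1)
  found <- c()
  for (f in win) {
    own <- traces[traces$cell_id == dying_id & traces$frame == f, ]
    if (!nrow(own)) next
    others <- traces[traces$cell_id != dying_id & traces$frame == f, ]
    for (k in seq_len(nrow(others))) {
      d <- sqrt((others$x_px[k] - own$x_px)^2 +
                  (others$y_px[k] - own$y_px)^2)
      if (d <= radius) found <- c(found, others$cell_id[k])
    }
  }
  sort(unique(found))
}

# closed-form Wilson score interval
oracle_wilson <- function(k, n, z = qnorm(0.975)) {
  p <- k / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n))
}

# small labeled image with one square cell, for unit tests
tiny_cell_image <- function(value = 100, side = 12, cell = 3:10) {
  intensity <- matrix(value, side, side)
  labels <- matrix(0L, side, side)
  labels[cell, cell] <- 1L
  labeled_image(intensity, labels)
}
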