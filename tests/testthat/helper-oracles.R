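# Independent oracles and fixture builders. These deliberately use naive
# algorithms (label propagation, per-box scans, distance checks) that share
# no code with the package internals they validate.

# shift a 3D array by (dk, dj, di), zero-padded
shift3 <- function(a, dk, dj, di) {
  d <- dim(a)
  out <- array(0L, d)
  if (max(1, 1 + dk) > min(d[1], d[1] + dk) ||
      max(1, 1 + dj) > min(d[2], d[2] + dj) ||
      max(1, 1 + di) > min(d[3], d[3] + di))
    return(out)
  ks <- max(1, 1 + dk):min(d[1], d[1] + dk)
  js <- max(1, 1 + dj):min(d[2], d[2] + dj)
  is <- max(1, 1 + di):min(d[3], d[3] + di)
  out[ks, js, is] <- a[ks - dk, js - dj, is - di]
  out
}

conn_offsets <- function(connectivity) {
  offs <- expand.grid(dk = -1:1, dj = -1:1, di = -1:1)
  s <- abs(offs$dk) + abs(offs$dj) + abs(offs$di)
  keep <- s > 0 & switch(as.character(connectivity),
                         "6" = s == 1, "18" = s <= 2, "26" = TRUE)
  offs[keep, , drop = FALSE]
}

# connected components by iterative minimum-label propagation
oracle_label3d <- function(vol, connectivity = 26) {
  d <- dim(vol)
  lab <- array(0L, d)
  lab[vol] <- seq_len(sum(vol))
  offs <- conn_offsets(connectivity)
  big <- sum(vol) + 1L
  repeat {
    cur <- lab
    m <- lab
    m[!vol] <- big
    best <- m
    for (t in seq_len(nrow(offs))) {
      sh <- shift3(m, offs$dk[t], offs$dj[t], offs$di[t])
      sh[sh == 0L] <- big
      best <- pmin(best, sh)
    }
    lab[vol] <- best[vol]
    if (identical(lab, cur)) break
  }
  ids <- sort(unique(lab[vol]))
  lab[vol] <- match(lab[vol], ids)
  lab
}

# occupied-box count by scanning every box explicitly
oracle_box_count <- function(x, eps) {
  d <- dim(x)
  nd <- length(d)
  starts <- lapply(d, function(n) seq(1, n, by = eps))
  n <- 0L
  if (nd == 2) {
    for (a in starts[[1]]) for (b in starts[[2]]) {
      if (any(x[a:min(a + eps - 1, d[1]), b:min(b + eps - 1, d[2])]))
        n <- n + 1L
    }
  } else {
    for (a in starts[[1]]) for (b in starts[[2]]) for (c in starts[[3]]) {
      if (any(x[a:min(a + eps - 1, d[1]), b:min(b + eps - 1, d[2]),
                c:min(c + eps - 1, d[3])]))
        n <- n + 1L
    }
  }
  n
}

# random particle with distinct voxels inside a small grid
random_particle <- function(n, side = 15, geometry = voxel_geometry()) {
  all_cells <- as.matrix(expand.grid(k = 1:side, j = 1:side, i = 1:side))
  coords <- all_cells[sample(nrow(all_cells), n), , drop = FALSE]
  particle(1L, coords, geometry = geometry)
}

# rasterized disk and circle-outline images
disk_image <- function(side, r, cy = (side + 1) / 2, cx = (side + 1) / 2) {
  yy <- matrix(seq_len(side), side, side)
  xx <- t(yy)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

ring_image <- function(side, r, width = 0.6,
                       cy = (side + 1) / 2, cx = (side + 1) / 2,
                       gap_deg = NULL) {
  yy <- matrix(seq_len(side), side, side)
  xx <- t(yy)
  dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
  out <- abs(dist - r) <= width
  if (!is.null(gap_deg)) {
    ang <- atan2(yy - cy, xx - cx) * 180 / pi
    out[out & ang >= 0 & ang <= gap_deg] <- FALSE
  }
  out
}

# place a (z,y,x) block into a larger empty scene at the given lower corner
place_block <- function(scene, block, at) {
  d <- dim(block)
  scene[at[1]:(at[1] + d[1] - 1),
        at[2]:(at[2] + d[2] - 1),
        at[3]:(at[3] + d[3] - 1)] <- scene[at[1]:(at[1] + d[1] - 1),
                                           at[2]:(at[2] + d[2] - 1),
                                           at[3]:(at[3] + d[3] - 1)] | block
  scene
}
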