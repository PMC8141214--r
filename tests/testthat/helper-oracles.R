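# Independent oracles, deliberately implemented by different routes than the
# package internals (graph components via igraph, queue-based BFS in R,
# exhaustive searches on raw data).

conn_offsets <- function(connectivity) {
  o <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  o <- o[!(o$dz == 0 & o$dy == 0 & o$dx == 0), ]
  if (connectivity == 6) o <- o[abs(o$dz) + abs(o$dy) + abs(o$dx) == 1, ]
  as.matrix(o)
}

# Connected components of a 3D logical mask via an adjacency graph and
# igraph::components. Returns an integer array (0 = background), with
# arbitrary component numbering.
cc_oracle_graph <- function(mask, connectivity) {
  dims <- dim(mask)
  V <- prod(dims)
  ids <- array(seq_len(V), dim = dims)
  off <- conn_offsets(connectivity)
  off <- off[off[, "dz"] > 0 |
             (off[, "dz"] == 0 & off[, "dy"] > 0) |
             (off[, "dz"] == 0 & off[, "dy"] == 0 & off[, "dx"] > 0), ,
             drop = FALSE]
  edges <- list()
  for (k in seq_len(nrow(off))) {
    dz <- off[k, 1]; dy <- off[k, 2]; dx <- off[k, 3]
    z1 <- max(1, 1 - dz):min(dims[1], dims[1] - dz)
    y1 <- max(1, 1 - dy):min(dims[2], dims[2] - dy)
    x1 <- max(1, 1 - dx):min(dims[3], dims[3] - dx)
    a <- mask[z1, y1, x1, drop = FALSE] &
         mask[z1 + dz, y1 + dy, x1 + dx, drop = FALSE]
    if (!any(a)) next
    ia <- ids[z1, y1, x1, drop = FALSE][a]
    ib <- ids[z1 + dz, y1 + dy, x1 + dx, drop = FALSE][a]
    edges[[length(edges) + 1L]] <- cbind(ia, ib)
  }
  fg <- which(mask)
  g <- igraph::graph_from_data_frame(
    d = if (length(edges)) as.data.frame(do.call(rbind, edges)) else
      data.frame(ia = integer(0), ib = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = fg))
  memb <- igraph::components(g)$membership
  out <- array(0L, dim = dims)
  out[fg] <- as.integer(memb[as.character(fg)])
  out
}

# Plain queue-based BFS flood fill, the slow-but-obvious reference.
cc_oracle_bfs <- function(mask, connectivity) {
  dims <- dim(mask)
  off <- conn_offsets(connectivity)
  lab <- array(0L, dim = dims)
  nxt <- 0L
  for (x in seq_len(dims[3])) for (y in seq_len(dims[2])) for (z in seq_len(dims[1])) {
    if (!mask[z, y, x] || lab[z, y, x] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(z, y, x), ncol = 3)
    lab[z, y, x] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(off, 2, cur, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      for (r in seq_len(nrow(nb))) {
        p <- nb[r, ]
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nxt
          queue <- rbind(queue, p)
        }
      }
    }
  }
  lab
}

# Canonicalize a labeling so partitions can be compared regardless of the
# numbering scheme: components renumbered by first occurrence in R's linear
# array order.
canonical_partition <- function(lab) {
  v <- as.vector(lab)
  pos <- v > 0L
  f <- match(v[pos], unique(v[pos]))
  out <- integer(length(v))
  out[pos] <- f
  out
}

# Exhaustive Otsu: evaluate the between-class variance of the raw data at
# every one of the 256 bin edges and return the argmax edge.
otsu_oracle <- function(x, n_bins = 256L) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  edges <- breaks[2:n_bins]
  score <- vapply(edges, function(e) {
    a <- x[x < e]; b <- x[x >= e]
    if (length(a) == 0L || length(b) == 0L) return(-Inf)
    w0 <- length(a) / length(x)
    w0 * (1 - w0) * (mean(a) - mean(b))^2
  }, numeric(1))
  edges[which.max(score)]
}

# Exhaustive split-seed search: for every distinct intensity in the region,
# count components of {v in region : I(v) >= t}; among thresholds with
# exactly n components return the one maximizing the smallest component size
# (ties -> lowest threshold), plus the seed partition at that threshold.
split_seed_oracle <- function(image, labels, label, n, connectivity) {
  inreg <- labels$data == label
  tvals <- sort(unique(image$data[inreg]))
  best <- NULL
  for (t in tvals) {
    cc <- cc_oracle_graph(inreg & image$data >= t, connectivity)
    k <- max(cc)
    if (k != n) next
    smallest <- min(tabulate(cc[cc > 0], nbins = k))
    if (is.null(best) || smallest > best$min_size)
      best <- list(threshold = t, min_size = smallest, cc = cc)
  }
  best
}

# Brute-force eligible set for in-plane region growing, straight from the
# definition: intensity >= t, in-plane distance to the region <= d*,
# background or same label, 8-connected to the region through the set.
grow_oracle <- function(image, labels, label, voxel) {
  z <- voxel[1]; sy <- voxel[2]; sx <- voxel[3]
  I <- image$data[z, , ]; L <- labels$data[z, , ]
  region <- which(L == label, arr.ind = TRUE)
  t_sel <- I[sy, sx]
  dist_to_region <- function(y, x)
    sqrt(min((y - region[, 1])^2 + (x - region[, 2])^2))
  d_star <- dist_to_region(sy, sx)
  elig <- matrix(FALSE, nrow(I), ncol(I))
  for (y in seq_len(nrow(I))) for (x in seq_len(ncol(I)))
    elig[y, x] <- I[y, x] >= t_sel && dist_to_region(y, x) <= d_star &&
      (L[y, x] == 0L || L[y, x] == label)
  # BFS from region voxels through eligible pixels
  added <- matrix(FALSE, nrow(I), ncol(I))
  frontier <- lapply(seq_len(nrow(region)), function(i) region[i, ])
  seen <- L == label
  while (length(frontier)) {
    p <- frontier[[1]]; frontier <- frontier[-1]
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      y <- p[1] + dy; x <- p[2] + dx
      if (y < 1 || y > nrow(I) || x < 1 || x > ncol(I)) next
      if (seen[y, x] || !elig[y, x]) next
      seen[y, x] <- TRUE
      added[y, x] <- TRUE
      frontier[[length(frontier) + 1L]] <- c(y, x)
    }
  }
  added & L == 0L
}
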