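#' Paint a brush disc into a label volume
#'
#' Sets every voxel of slice `z` whose in-plane Euclidean center distance to
#' `center` is `<= radius` to `label`, regardless of what it held before:
#' painting is authoritative, voxel-level override. The brush acts in the X-Y
#' plane only (the plane with the finest, isotropic resolution in light-sheet
#' stacks). All labels whose voxels change are recorded as modified.
#'
#' @param labels a [label_volume()].
#' @param label positive integer label to paint.
#' @param z slice index (1-based).
#' @param center length-2 vector `(y, x)`, 1-based voxel coordinates.
#' @param radius brush radius in voxel units, `>= 0` (0 paints one voxel).
#' @return The updated [label_volume()].
#' @export
paint <- function(labels, label, z, center, radius) {
  brush_op(labels, label, z, center, radius, erase = FALSE)
}

#' Erase a region under a brush disc
#'
#' As [paint()], but only voxels currently carrying `label` inside the disc
#' are reset to background; voxels of other labels are untouched.
#'
#' @inheritParams paint
#' @return The updated [label_volume()].
#' @export
erase <- function(labels, label, z, center, radius) {
  brush_op(labels, label, z, center, radius, erase = TRUE)
}

brush_op <- function(labels, label, z, center, radius, erase) {
  stopifnot(inherits(labels, "label_volume"))
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label <= 0L)
    stop("invalid label: must be a single positive integer", call. = FALSE)
  d <- dim(labels$data)
  z <- as.integer(z)
  if (z < 1L || z > d[1]) stop("slice index out of bounds", call. = FALSE)
  cy <- center[1]; cx <- center[2]
  if (cy < 1 || cy > d[2] || cx < 1 || cx > d[3])
    stop("brush center out of bounds", call. = FALSE)
  if (radius < 0) stop("`radius` must be >= 0", call. = FALSE)

  ys <- seq_len(d[2]); xs <- seq_len(d[3])
  disc <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= radius^2
  slice <- labels$data[z, , ]
  if (erase) {
    sel <- disc & slice == label
    touched <- label
    slice[sel] <- 0L
  } else {
    sel <- disc
    touched <- unique(c(label, slice[sel & slice > 0L]))
    slice[sel] <- label
  }
  labels$data[z, , ] <- slice
  note_modified(labels, touched)
}

#' Grow a region in-plane toward a selected voxel
#'
#' Constrained region growing in the X-Y plane of the selected voxel: with
#' `t` the intensity at the selected voxel and `d*` its in-plane Euclidean
#' distance (voxel units) to the nearest voxel of the region in that slice,
#' every slice voxel with intensity `>= t`, distance to the region `<= d*`,
#' that is background (voxels of other regions are never annexed) and
#' reachable from the region through the eligible set under in-plane
#' 8-connectivity, is added to the region. Selecting a brighter voxel grows a
#' subset of what a dimmer one at the same spot would.
#'
#' @param image the paired [image_volume()].
#' @param labels a [label_volume()].
#' @param label positive integer label of the region to grow.
#' @param voxel length-3 vector `(z, y, x)` of the selected voxel, 1-based;
#'   must lie outside the region, in a slice where the region is present.
#' @return The updated [label_volume()].
#' @export
grow_region <- function(image, labels, label, voxel) {
  check_pair(image, labels)
  label <- check_label_arg(labels, label)
  v <- check_voxel_arg(labels, voxel)
  z <- v[1]; sy <- v[2]; sx <- v[3]
  L <- labels$data[z, , ]
  if (L[sy, sx] == label) {
    warning("selected voxel already belongs to region ", label, "; no-op",
            call. = FALSE)
    return(labels)
  }
  region <- L == label
  if (!any(region))
    stop("region ", label, " is unreachable: absent from slice ", z,
         call. = FALSE)
  I <- image$data[z, , ]
  t_sel <- I[sy, sx]
  dist <- min_dist_to(region, dim(L))
  d_star <- dist[sy, sx]
  eligible <- I >= t_sel & dist <= d_star & (L == 0L | L == label)
  reached <- flood_from(region, eligible, dim(L))
  add <- reached & !region
  if (any(add)) {
    L[add] <- label
    labels$data[z, , ] <- L
    labels <- note_modified(labels, label)
  }
  labels
}

#' Shrink a region in-plane from a selected voxel
#'
#' Counterpart of [grow_region()]: with `t` the intensity at the selected
#' voxel (which must lie inside the region) and `d*` its in-plane depth (the
#' Euclidean distance to the nearest non-region voxel of the slice), region
#' voxels of that slice with intensity `<= t` and depth `<= d*` that are
#' reachable from the region's in-plane boundary through the eligible set
#' (8-connectivity) are removed. Dim voxels shielded by brighter ones, or
#' deeper in the region than the selection, are retained.
#'
#' @inheritParams grow_region
#' @param voxel length-3 `(z, y, x)` selected voxel; must carry `label`.
#' @return The updated [label_volume()].
#' @export
shrink_region <- function(image, labels, label, voxel) {
  check_pair(image, labels)
  label <- check_label_arg(labels, label)
  v <- check_voxel_arg(labels, voxel)
  z <- v[1]; sy <- v[2]; sx <- v[3]
  L <- labels$data[z, , ]
  if (L[sy, sx] != label)
    stop("invalid selection: voxel is not inside region ", label, call. = FALSE)
  region <- L == label
  complement <- !region
  if (!any(complement))
    stop("region fills the entire slice; nothing to shrink from", call. = FALSE)
  I <- image$data[z, , ]
  t_sel <- I[sy, sx]
  depth <- min_dist_to(complement, dim(L))
  d_star <- depth[sy, sx]
  eligible <- region & I <= t_sel & depth <= d_star
  boundary <- region & adjacent_to(complement, dim(L))
  reached <- flood_from(boundary & eligible, eligible, dim(L),
                        include_sources = TRUE)
  if (any(reached)) {
    L[reached] <- 0L
    labels$data[z, , ] <- L
    labels <- note_modified(labels, label)
  }
  labels
}

#' Merge one region into another
#'
#' Reassigns every voxel of `source` to `target`; used when one nucleus was
#' incorrectly divided into several regions. The total labeled voxel count is
#' unchanged and the region count decreases by exactly one. The target is
#' marked modified; the source's metadata entry is dropped when the sidecar
#' is next synchronized with [update_metadata()].
#'
#' @param labels a [label_volume()].
#' @param target label that absorbs the source.
#' @param source label to dissolve.
#' @return The updated [label_volume()].
#' @export
merge_regions <- function(labels, target, source) {
  stopifnot(inherits(labels, "label_volume"))
  target <- as.integer(target); source <- as.integer(source)
  if (target == source) {
    warning("target and source are the same region; no-op", call. = FALSE)
    return(labels)
  }
  present <- region_labels(labels)
  for (lab in c(target, source))
    if (!(lab %in% present))
      stop("unknown label ", lab, ": not present in the label volume",
           call. = FALSE)
  labels$data[labels$data == source] <- target
  note_modified(labels, target)
}

#' Split an incorrectly joined region into n nuclei
#'
#' Semi-automated correction for the common light-sheet segmentation error in
#' which several touching nuclei are fused into one region. The user supplies
#' the true count `n`; the algorithm exploits the fact that stained nuclei
#' are brightest toward their centers:
#'
#' 1. An increasing intensity threshold sweeps the region's distinct voxel
#'    intensities; at each threshold the voxels at or above it are split into
#'    connected components.
#' 2. Among thresholds yielding exactly `n` components, the one maximizing
#'    the volume of the *smallest* component is chosen (robust to noise
#'    specks; ties go to the lowest threshold). Those components are seeds.
#' 3. The seeds then grow back over the original region: the working
#'    intensity steps down through the region's distinct values from the seed
#'    threshold to the region minimum, each step dilating all seeds
#'    simultaneously by one voxel (under the module connectivity) into
#'    unclaimed region voxels at or above the working intensity. A voxel
#'    reached by several seeds in one step goes to the seed whose claiming
#'    neighbor is brightest (ties to the lowest seed index). At the minimum
#'    intensity, dilation repeats until nothing changes, so a connected
#'    region is claimed completely.
#'
#' The largest seed keeps the source label; the others receive fresh labels
#' above the current maximum. Voxels outside the source region are never
#' modified.
#'
#' @param image the paired [image_volume()].
#' @param labels a [label_volume()].
#' @param label region to split.
#' @param n integer `>= 2`, the number of nuclei the region actually contains.
#' @param connectivity 6 or 26 (default 26), used for both component analysis
#'   and seed growth.
#' @return A list with elements `labels` (the updated [label_volume()]) and
#'   `result` (a `split_result`: `source_label`, `n_requested`,
#'   `seed_threshold`, `seed_components` -- a list of `n` voxel index vectors
#'   (linear indices into the volume), `new_labels` -- the label assigned to
#'   each seed, and `unassigned_count`).
#' @export
split_region <- function(image, labels, label, n, connectivity = 26L) {
  check_pair(image, labels)
  label <- check_label_arg(labels, label)
  connectivity <- match_connectivity(connectivity)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)

  dfull <- dim(labels$data)
  in_region_full <- labels$data == label
  n_vox <- sum(in_region_full)
  if (n > n_vox)
    stop("invalid split: n = ", n, " exceeds the region's ", n_vox, " voxels",
         call. = FALSE)

  # work inside the region's bounding box
  idx <- which(in_region_full, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  zr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; xr <- lo[3]:hi[3]
  inreg <- in_region_full[zr, yr, xr, drop = FALSE]
  dim(inreg) <- c(length(zr), length(yr), length(xr))
  intens <- image$data[zr, yr, xr, drop = FALSE]
  dim(intens) <- dim(inreg)
  dsub <- dim(inreg)

  tvals <- sort(unique(intens[inreg]))

  # threshold sweep: find candidates giving exactly n components
  best_t <- NA_real_
  best_min <- -1L
  best_cc <- NULL
  for (t in tvals) {
    mask <- inreg & intens >= t
    cc <- .cc_label(as.vector(mask), dsub, connectivity)
    k <- attr(cc, "n")
    if (k == n) {
      smallest <- min(tabulate(cc[cc > 0L], nbins = k))
      if (smallest > best_min) {  # strict: ties keep the lowest threshold
        best_min <- smallest
        best_t <- t
        best_cc <- cc
      }
    }
  }
  if (is.na(best_t)) {
    stop("split infeasible: no intensity threshold separates region ", label,
         " into exactly ", n, " components", call. = FALSE)
  }

  # growth from the seeds down to the region minimum
  steps <- rev(tvals[tvals <= best_t])
  grown <- .grow_seeds(best_cc, as.vector(inreg), as.vector(intens),
                       dsub, connectivity, steps)
  unassigned <- sum(grown == 0L & as.vector(inreg))
  if (unassigned > 0L)
    warning("split left ", unassigned, " voxel(s) of a disconnected source ",
            "region unreachable from any seed; they become background",
            call. = FALSE)

  # the largest seed keeps the source label, others get fresh labels
  seed_sizes <- tabulate(best_cc[best_cc > 0L], nbins = n)
  keeper <- which.max(seed_sizes)
  new_labels <- integer(n)
  new_labels[keeper] <- label
  fresh <- max(region_labels(labels)) + seq_len(n - 1L)
  new_labels[-keeper] <- fresh

  # write back into the full volume
  sub <- labels$data[zr, yr, xr, drop = FALSE]
  dim(sub) <- dsub
  grown_arr <- array(grown, dim = dsub)
  sub[inreg] <- 0L
  for (s in seq_len(n)) sub[grown_arr == s] <- new_labels[s]
  labels$data[zr, yr, xr] <- sub
  labels <- note_modified(labels, new_labels)

  # seed voxel indices in full-volume linear coordinates
  full_lin <- array(seq_len(prod(dfull)), dim = dfull)[zr, yr, xr, drop = FALSE]
  dim(full_lin) <- dsub
  seed_components <- lapply(seq_len(n), function(s) full_lin[best_cc == s])

  result <- structure(list(
    source_label = label,
    n_requested = n,
    seed_threshold = best_t,
    seed_components = seed_components,
    new_labels = new_labels,
    unassigned_count = unassigned
  ), class = "split_result")
  list(labels = labels, result = result)
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "<split_result> region %d -> %d seeds at threshold %g; labels %s; %d unassigned\n",
    x$source_label, x$n_requested, x$seed_threshold,
    paste(x$new_labels, collapse = ", "), x$unassigned_count))
  invisible(x)
}

#' Build the region table
#'
#' One row per positive label: voxel count, tight bounding box (inclusive,
#' 1-based, in (z, y, x) order), and the `modified`/`done` flags merged from
#' the metadata sidecar and from edits recorded on the volume. This is the
#' bookkeeping view a user sorts by label, size, or status while working
#' through a dense field of nuclei.
#'
#' @param labels a [label_volume()].
#' @param meta a [region_metadata()] (optional).
#' @param sort_by `"label"`, `"size"` (descending), or `"status"` (done
#'   first, then modified).
#' @return A data.frame with columns `label`, `size`, `zmin`, `zmax`, `ymin`,
#'   `ymax`, `xmin`, `xmax`, `modified`, `done`.
#' @export
build_region_table <- function(labels, meta = region_metadata(),
                               sort_by = c("label", "size", "status")) {
  stopifnot(inherits(labels, "label_volume"), inherits(meta, "region_metadata"))
  sort_by <- match.arg(sort_by)
  labs <- region_labels(labels)
  if (length(labs) == 0L) {
    return(data.frame(label = integer(0), size = integer(0),
                      zmin = integer(0), zmax = integer(0),
                      ymin = integer(0), ymax = integer(0),
                      xmin = integer(0), xmax = integer(0),
                      modified = logical(0), done = logical(0)))
  }
  pos <- which(labels$data > 0L, arr.ind = TRUE)
  vals <- labels$data[labels$data > 0L]
  f <- factor(vals, levels = labs)
  size <- as.integer(table(f))
  bb <- function(col, fun) as.integer(tapply(pos[, col], f, fun))
  touched <- modified_labels(labels)
  flags <- vapply(labs, function(l) {
    e <- meta$entries[[as.character(l)]]
    c(modified = (!is.null(e) && isTRUE(e$modified)) || l %in% touched,
      done = !is.null(e) && isTRUE(e$done))
  }, logical(2))
  tab <- data.frame(
    label = labs, size = size,
    zmin = bb(1, min), zmax = bb(1, max),
    ymin = bb(2, min), ymax = bb(2, max),
    xmin = bb(3, min), xmax = bb(3, max),
    modified = flags["modified", ], done = flags["done", ],
    row.names = NULL)
  ord <- switch(sort_by,
    label = order(tab$label),
    size = order(-tab$size, tab$label),
    status = order(-tab$done, -tab$modified, tab$label))
  tab[ord, , drop = FALSE]
}

# ---- shared in-plane helpers -------------------------------------------

check_label_arg <- function(labels, label) {
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label <= 0L)
    stop("invalid label: must be a single positive integer", call. = FALSE)
  if (!(label %in% region_labels(labels)))
    stop("unknown label ", label, ": not present in the label volume",
         call. = FALSE)
  label
}

check_voxel_arg <- function(labels, voxel) {
  v <- as.integer(voxel)
  if (length(v) != 3L || any(is.na(v)))
    stop("`voxel` must be (z, y, x)", call. = FALSE)
  d <- dim(labels$data)
  if (any(v < 1L) || any(v > d))
    stop("voxel (", paste(v, collapse = ","), ") out of bounds", call. = FALSE)
  v
}

# Exact in-plane Euclidean distance (voxel units) from every pixel of a slice
# to the nearest TRUE pixel of `target`. Chunked to bound memory.
min_dist_to <- function(target, d) {
  ty <- row(target)[target]; tx <- col(target)[target]
  ys <- rep(seq_len(d[1]), times = d[2])
  xs <- rep(seq_len(d[2]), each = d[1])
  out <- numeric(length(ys))
  chunk <- max(1L, floor(4e6 / length(ty)))
  for (start in seq(1L, length(ys), by = chunk)) {
    i <- start:min(start + chunk - 1L, length(ys))
    d2 <- outer(ys[i], ty, `-`)^2 + outer(xs[i], tx, `-`)^2
    out[i] <- sqrt(.rowMins(d2))
  }
  matrix(out, d[1], d[2])
}

.rowMins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, as.data.frame(m))
}

# TRUE for pixels 8-adjacent to a TRUE pixel of `mask` (not counting itself).
adjacent_to <- function(mask, d) {
  out <- matrix(FALSE, d[1], d[2])
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- seq_len(d[1]) + dy; xs <- seq_len(d[2]) + dx
    oky <- ys >= 1 & ys <= d[1]; okx <- xs >= 1 & xs <= d[2]
    out[oky, okx] <- out[oky, okx] | mask[ys[oky], xs[okx], drop = FALSE]
  }
  out
}

# In-plane 8-connected flood fill from `sources` through `eligible`.
# Returns the reached non-source set (or reached sources too if requested).
flood_from <- function(sources, eligible, d, include_sources = FALSE) {
  reached <- matrix(FALSE, d[1], d[2])
  frontier <- sources
  visited <- sources
  repeat {
    nxt <- adjacent_to(frontier, d) & eligible & !visited
    if (!any(nxt)) break
    visited <- visited | nxt
    reached <- reached | nxt
    frontier <- nxt
  }
  if (include_sources) reached | (sources & eligible) else reached
}
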