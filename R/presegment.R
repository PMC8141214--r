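#' Otsu threshold of an image volume
#'
#' Computes the global intensity threshold that maximizes the between-class
#' variance over a 256-bin histogram of the whole volume, the standard
#' automatic starting point for separating stained nuclei from background
#' before manual refinement. The returned threshold is the lower edge of the
#' first foreground bin, so the foreground rule `intensity >= threshold`
#' keeps the selected class boundary inside the foreground. Ties are broken
#' toward the lowest qualifying bin edge.
#'
#' @param image an [image_volume()] with at least two distinct intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return A list of class `threshold_result` with elements `threshold`
#'   (numeric scalar in `[min, max]` of the intensities) and `method`
#'   (`"otsu"`).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  stopifnot(inherits(image, "image_volume"))
  x <- as.vector(image$data)
  lo <- min(x); hi <- max(x)
  if (lo == hi)
    stop("degenerate input: constant volume has no Otsu threshold",
         call. = FALSE)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  n <- length(x)
  w0 <- cumsum(counts) / n                       # background weight up to bin k
  mu0 <- cumsum(counts * mids) / pmax(cumsum(counts), 1)
  mu <- sum(counts * mids) / n
  w1 <- 1 - w0
  mu1 <- (mu - w0 * mu0) / ifelse(w1 > 0, w1, 1)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2             # split after bin k
  sigma_b <- sigma_b[-n_bins]                    # a split must leave both classes nonempty
  k <- which.max(sigma_b)
  structure(list(threshold = breaks[k + 1L], method = "otsu"),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> threshold = %g (%s)\n", x$threshold, x$method))
  invisible(x)
}

#' Threshold-based pre-segmentation
#'
#' Binarizes the volume with the rule `intensity >= threshold` and partitions
#' the foreground into connected components under 6- (face) or 26- (full 3D
#' neighborhood) connectivity on the voxel grid, ignoring physical
#' anisotropy. Components are labeled 1..K in order of their first voxel in
#' (z, y, x) raster order. The result is the initial instance segmentation
#' that manual editing then refines; no minimum-size filtering is applied.
#'
#' @param image an [image_volume()].
#' @param threshold finite intensity threshold (e.g. from [otsu_threshold()]).
#' @param connectivity 6 or 26 (default 26: nuclei are blob-like, and face-only
#'   connectivity over-fragments diagonal contacts).
#' @return A [label_volume()] on the same grid.
#' @export
threshold_segment <- function(image, threshold, connectivity = 26L) {
  stopifnot(inherits(image, "image_volume"))
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  connectivity <- match_connectivity(connectivity)
  mask <- image$data >= threshold
  lab <- .cc_label(as.vector(mask), dim(image$data), connectivity)
  label_volume(array(lab, dim = dim(image$data)), image$spacing)
}

match_connectivity <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!(connectivity %in% c(6L, 26L)))
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  connectivity
}

#' Connected components of an arbitrary voxel mask
#'
#' Lower-level entry point used by [threshold_segment()] and the split
#' algorithm: labels the `TRUE` voxels of a logical mask 1..K in raster
#' order under the given connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return Integer array of the same shape; 0 outside the mask.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  connectivity <- match_connectivity(connectivity)
  lab <- .cc_label(as.vector(mask), dim(mask), connectivity)
  array(lab, dim = dim(mask))
}
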