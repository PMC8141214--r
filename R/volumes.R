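#' @useDynLib segvol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif sd qt
#' @importFrom utils modifyList
NULL

# Default voxel spacing (dz, dy, dx) in micrometres for light-sheet volumes
# whose container format carries no spacing information.
DEFAULT_SPACING <- c(2.50, 0.75, 0.75)

#' Construct a 3D image volume
#'
#' An `image_volume` wraps a 3D array of non-negative scalar intensities with
#' an anisotropic voxel spacing. The array is indexed `data[z, y, x]`: the
#' first axis is the slice (Z) axis and the last two axes form the in-plane
#' X-Y grid, matching slice-stack acquisition order. Spacing is given as
#' `(dz, dy, dx)` in micrometres; the default `(2.50, 0.75, 0.75)` matches a
#' typical light-sheet acquisition in which the in-plane resolution is finer
#' than the slice thickness.
#'
#' @param data numeric 3D array of finite, non-negative intensities,
#'   dimension `(nz, ny, nx)`.
#' @param spacing numeric length-3 vector `(dz, dy, dx)` in micrometres,
#'   all positive.
#' @return An object of class `image_volume`: a list with elements `data`
#'   and `spacing`.
#' @examples
#' v <- image_volume(array(0, dim = c(2, 4, 4)))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = DEFAULT_SPACING) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (any(!is.finite(data))) stop("intensities must be finite", call. = FALSE)
  if (any(data < 0)) stop("intensities must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (dz, dy, dx)", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' Construct a 3D label volume
#'
#' A `label_volume` holds a 3D grid of non-negative integers with the same
#' axis convention and spacing semantics as [image_volume()]. Label 0 is
#' background; every positive label present defines one region (one nucleus
#' instance). Editing operations record which labels they touched in the
#' `modified_labels` attribute, which [update_metadata()] merges into the
#' JSON status sidecar.
#'
#' @param data integer-valued 3D array, dimension `(nz, ny, nx)`, all values
#'   `>= 0`.
#' @inheritParams image_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = DEFAULT_SPACING) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (any(!is.finite(data))) stop("labels must be finite", call. = FALSE)
  if (any(data < 0)) stop("labels must be non-negative", call. = FALSE)
  if (any(data != round(data)))
    stop("label volume contains non-integer voxel values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (dz, dy, dx)", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing), class = "label_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  labs <- region_labels(x)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  %d region(s), %d labeled voxel(s)\n",
              length(labs), sum(x$data > 0L)))
  invisible(x)
}

#' Positive labels present in a label volume
#'
#' @param labels a [label_volume()].
#' @return Sorted integer vector of the distinct positive labels.
#' @export
region_labels <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  u <- sort(unique(as.vector(labels$data)))
  u[u > 0L]
}

#' Check that an image and a label volume are a valid pair
#'
#' Editing operations act on a grayscale volume together with its label
#' volume; both must share the same grid. Called before any edit runs.
#'
#' @param image an [image_volume()].
#' @param labels a [label_volume()].
#' @return Invisibly `TRUE`; stops on mismatch.
#' @export
check_pair <- function(image, labels) {
  stopifnot(inherits(image, "image_volume"), inherits(labels, "label_volume"))
  if (!identical(dim(image$data), dim(labels$data)))
    stop(sprintf(
      "image (%s) and labels (%s) have different shapes",
      paste(dim(image$data), collapse = "x"),
      paste(dim(labels$data), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

# Record labels touched by an editing operation on the volume itself, so that
# a chain of edits can be flushed to the sidecar in one update_metadata() call.
note_modified <- function(labels, touched) {
  touched <- as.integer(touched)
  prev <- attr(labels, "modified_labels")
  attr(labels, "modified_labels") <- sort(unique(c(prev, touched)))
  labels
}

#' Labels modified by editing operations since load
#'
#' @param labels a [label_volume()].
#' @return Integer vector of labels an editing operation has touched.
#' @export
modified_labels <- function(labels) {
  out <- attr(labels, "modified_labels")
  if (is.null(out)) integer(0) else out
}
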