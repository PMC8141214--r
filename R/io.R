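#' Read a 3D volume from TIFF or NIfTI
#'
#' Reads a grayscale volume from a single multi-page TIFF file, a directory of
#' per-slice TIFF files, or a NIfTI-1 file (`.nii` / `.nii.gz`). Slices of a
#' multi-file stack are ordered by lexicographic (byte-order) filename sort.
#' NIfTI voxel spacing is taken from the header; TIFF carries no reliable
#' spacing convention, so `spacing` (default 2.50 x 0.75 x 0.75 um) is used.
#'
#' @param path file or directory path.
#' @param format `"tiff"`, `"nifti"`, or `NULL` to infer from the extension
#'   (directories are TIFF stacks).
#' @param spacing spacing `(dz, dy, dx)` in micrometres applied to formats
#'   that carry none (TIFF). Ignored for NIfTI unless the header spacing is
#'   degenerate.
#' @return An [image_volume()].
#' @export
read_image <- function(path, format = NULL, spacing = DEFAULT_SPACING) {
  format <- infer_format(path, format)
  switch(format,
    tiff = read_tiff_volume(path, spacing),
    nifti = read_nifti_volume(path, spacing)
  )
}

#' Write a 3D volume to TIFF or NIfTI
#'
#' Integer-valued data round-trips bit-exactly in both formats. TIFF storage
#' uses the smallest of 8- or 16-bit unsigned samples that holds the maximum
#' value; floating-point data is stored as 32-bit float TIFF and must lie in
#' `[0, 1]` (the format's defined float range here) -- use NIfTI for arbitrary
#' floating-point volumes.
#'
#' @param volume an [image_volume()] or [label_volume()].
#' @param path output path (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @param format `"tiff"`, `"nifti"`, or `NULL` to infer from the extension.
#' @return Invisibly, `path`.
#' @export
write_image <- function(volume, path, format = NULL) {
  stopifnot(inherits(volume, "image_volume") || inherits(volume, "label_volume"))
  format <- infer_format(path, format, for_write = TRUE)
  switch(format,
    tiff = write_tiff_volume(volume$data, path),
    nifti = write_nifti_volume(volume$data, volume$spacing, path)
  )
  invisible(path)
}

#' Read a label volume
#'
#' As [read_image()], but the result must be integer-valued: any fractional
#' voxel value is a validation error, since labels identify object instances.
#'
#' @inheritParams read_image
#' @return A [label_volume()].
#' @export
read_labels <- function(path, format = NULL, spacing = DEFAULT_SPACING) {
  v <- read_image(path, format, spacing)
  if (any(v$data != round(v$data)))
    stop("label file contains non-integer voxel values: ", path, call. = FALSE)
  label_volume(v$data, v$spacing)
}

#' Write a label volume
#'
#' Labels are written with the smallest unsigned integer sample width that
#' holds the maximum label (TIFF: 8 or 16 bit; larger labels require NIfTI).
#'
#' @param labels a [label_volume()].
#' @inheritParams write_image
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path, format = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  write_image(labels, path, format)
}

infer_format <- function(path, format, for_write = FALSE) {
  if (!is.null(format)) {
    format <- match.arg(tolower(format), c("tiff", "nifti", "tif", "nii"))
    return(switch(format, tif = "tiff", nii = "nifti", format))
  }
  if (!for_write && dir.exists(path)) return("tiff")
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.tiff?$", low)) return("tiff")
  stop("cannot infer format from '", path,
       "'; pass format = \"tiff\" or \"nifti\"", call. = FALSE)
}

read_tiff_volume <- function(path, spacing) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE)
    if (length(files) == 0L)
      stop("no TIFF files found in directory: ", path, call. = FALSE)
    files <- files[order(files, method = "radix")]
    pages <- lapply(file.path(path, files), read_tiff_pages)
    n_per <- vapply(pages, length, 1L)
    if (any(n_per != 1L))
      stop("per-slice TIFF stack contains multi-page files", call. = FALSE)
    pages <- lapply(pages, `[[`, 1L)
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    pages <- read_tiff_pages(path)
  }
  shapes <- vapply(pages, function(p) dim(p), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice shapes in TIFF stack", call. = FALSE)
  arr <- array(0, dim = c(length(pages), shapes[1, 1], shapes[2, 1]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  image_volume(arr, spacing)
}

read_tiff_pages <- function(path) {
  info <- tryCatch(tiff::readTIFF(path, all = TRUE, payload = FALSE),
                   error = function(e)
                     stop("unreadable TIFF file '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  # 8/16-bit samples are unsigned integers (read as stored values); 32-bit
  # samples written by this package are IEEE float
  is_float <- any(info$bits.per.sample >= 32L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of RGB(A) input
    p
  })
}

write_tiff_volume <- function(data, path) {
  integral <- all(data == round(data))
  mx <- max(data)
  if (integral) {
    if (mx > 65535)
      stop("values above 65535 cannot be stored in unsigned 16-bit TIFF; ",
           "use NIfTI", call. = FALSE)
    bits <- if (mx > 255) 16L else 8L
    denom <- 2^bits - 1
    pages <- lapply(seq_len(dim(data)[1]), function(z) data[z, , ] / denom)
  } else {
    if (mx > 1)
      stop("floating-point TIFF storage is defined on [0, 1]; ",
           "use NIfTI for arbitrary float volumes", call. = FALSE)
    bits <- 32L
    pages <- lapply(seq_len(dim(data)[1]), function(z) data[z, , ])
  }
  dir_ok(dirname(path))
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

read_nifti_volume <- function(path, spacing) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("unreadable NIfTI file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), "D", call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]  # (dx, dy, dz)
  sp <- if (all(is.finite(pd)) && all(pd > 0)) rev(pd) else spacing
  image_volume(aperm(arr, c(3, 2, 1)), sp)
}

write_nifti_volume <- function(data, spacing, path) {
  arr <- aperm(data, c(3, 2, 1))  # store as (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(spacing)  # (dx, dy, dz)
  dir_ok(dirname(path))
  RNifti::writeNifti(img, path)
  invisible(path)
}

dir_ok <- function(d) {
  if (!dir.exists(d))
    stop("directory does not exist: ", d, call. = FALSE)
  invisible(TRUE)
}
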