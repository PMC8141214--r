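#' Region status metadata (JSON sidecar)
#'
#' Per-region `modified` and `done` flags live outside the label volume, in a
#' small JSON sidecar written next to the segmentation:
#'
#' ```
#' {"version": 1, "regions": {"<label>": {"modified": false, "done": true}}}
#' ```
#'
#' Unknown keys, at the top level or inside a region entry, are preserved on
#' round-trip. This schema is this package's own dialect.
#'
#' @param entries named list keyed by label (coercible to positive integer);
#'   each element a list with logical `modified` and `done` (missing flags
#'   default to `FALSE`).
#' @param version schema version, currently 1.
#' @param extra named list of unknown top-level keys to preserve.
#' @return An object of class `region_metadata`.
#' @export
region_metadata <- function(entries = list(), version = 1L, extra = list()) {
  if (length(entries)) {
    keys <- suppressWarnings(as.integer(names(entries)))
    if (any(is.na(keys)) || any(keys <= 0L))
      stop("metadata keys must be positive integer labels", call. = FALSE)
    entries <- lapply(entries, function(e) {
      e$modified <- isTRUE(e$modified)
      e$done <- isTRUE(e$done)
      e
    })
    entries <- entries[order(keys)]
  }
  if (length(extra) == 0L) extra <- list()
  structure(list(version = as.integer(version), entries = entries,
                 extra = extra),
            class = "region_metadata")
}

#' @export
print.region_metadata <- function(x, ...) {
  done <- sum(vapply(x$entries, function(e) isTRUE(e$done), logical(1)))
  mod <- sum(vapply(x$entries, function(e) isTRUE(e$modified), logical(1)))
  cat(sprintf("<region_metadata> %d entr%s (%d done, %d modified)\n",
              length(x$entries), if (length(x$entries) == 1) "y" else "ies",
              done, mod))
  invisible(x)
}

#' Read the region status sidecar
#'
#' A missing file yields empty metadata (all flags false), so a fresh
#' segmentation needs no sidecar. When `labels` is supplied, entries whose
#' label is absent from the volume are kept but flagged `stale = TRUE`, with
#' a warning -- they typically come from a sidecar saved against an older
#' version of the segmentation.
#'
#' @param path path to the JSON sidecar.
#' @param labels optional [label_volume()] used to flag stale entries.
#' @return A [region_metadata()].
#' @export
read_metadata <- function(path, labels = NULL) {
  if (!file.exists(path)) return(region_metadata())
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e)
      stop("malformed JSON sidecar '", path, "': ", conditionMessage(e),
           call. = FALSE))
  if (!is.list(raw)) stop("malformed JSON sidecar: expected an object",
                          call. = FALSE)
  regions <- raw$regions
  if (is.null(regions)) regions <- list()
  extra <- raw[setdiff(names(raw), c("version", "regions"))]
  version <- if (is.null(raw$version)) 1L else as.integer(raw$version)
  meta <- region_metadata(regions, version = version, extra = extra)
  if (!is.null(labels)) {
    present <- region_labels(labels)
    keys <- as.integer(names(meta$entries))
    stale <- !(keys %in% present)
    if (any(stale)) {
      warning("sidecar has ", sum(stale), " stale entr",
              if (sum(stale) == 1) "y" else "ies",
              " for label(s) absent from the volume: ",
              paste(keys[stale], collapse = ", "), call. = FALSE)
      meta$entries[stale] <- lapply(meta$entries[stale], function(e) {
        e$stale <- TRUE
        e
      })
    }
  }
  meta
}

#' Write the region status sidecar
#'
#' @param meta a [region_metadata()].
#' @param path output path for the JSON file.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "region_metadata"))
  out <- c(list(version = meta$version), meta$extra,
           list(regions = meta$entries))
  if (length(out$regions) == 0L) out$regions <- structure(list(), names = character(0))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Set a region's done flag
#'
#' @param meta a [region_metadata()].
#' @param label positive integer region label.
#' @param done logical flag.
#' @param labels optional [label_volume()]; when supplied, `label` must be
#'   present in the volume.
#' @return The updated [region_metadata()].
#' @export
mark_done <- function(meta, label, done = TRUE, labels = NULL) {
  stopifnot(inherits(meta, "region_metadata"))
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label <= 0L)
    stop("`label` must be a single positive integer", call. = FALSE)
  if (!is.null(labels) && !(label %in% region_labels(labels)))
    stop("unknown label ", label, ": not present in the label volume",
         call. = FALSE)
  key <- as.character(label)
  entry <- meta$entries[[key]]
  if (is.null(entry)) entry <- list(modified = FALSE, done = FALSE)
  entry$done <- isTRUE(done)
  meta$entries[[key]] <- entry
  meta$entries <- meta$entries[order(as.integer(names(meta$entries)))]
  meta
}

#' Synchronize metadata with a label volume after editing
#'
#' Merges the `modified_labels` recorded on the volume by editing operations
#' into the metadata, and drops entries whose label no longer exists (e.g.
#' after merge or erase). The CLI calls this before writing the sidecar next
#' to an output volume.
#'
#' @param meta a [region_metadata()].
#' @param labels a [label_volume()].
#' @return The updated [region_metadata()].
#' @export
update_metadata <- function(meta, labels) {
  stopifnot(inherits(meta, "region_metadata"), inherits(labels, "label_volume"))
  present <- region_labels(labels)
  keep <- as.integer(names(meta$entries)) %in% present
  meta$entries <- meta$entries[keep]
  for (lab in intersect(modified_labels(labels), present)) {
    key <- as.character(lab)
    entry <- meta$entries[[key]]
    if (is.null(entry)) entry <- list(modified = FALSE, done = FALSE)
    entry$modified <- TRUE
    meta$entries[[key]] <- entry
  }
  if (length(meta$entries))
    meta$entries <- meta$entries[order(as.integer(names(meta$entries)))]
  meta
}
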