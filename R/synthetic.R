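#' Specify one synthetic nucleus
#'
#' A nucleus is modeled as an axis-aligned anisotropic Gaussian intensity
#' profile: stained nuclei in cleared-tissue light-sheet images are brightest
#' toward their centers, which is the property the split algorithm relies on.
#' The profile at voxel position `p` (micrometres) is
#' `exp(-0.5 * sum(((p - center) / (falloff * radii))^2))`, scaled by
#' `peak_intensity`.
#'
#' @param center length-3 `(z, y, x)` position in micrometres.
#' @param radii length-3 `(rz, ry, rx)` nominal radii in micrometres, all
#'   positive. Defaults are typical of mouse cortical nuclei at this
#'   resolution (axial extent of roughly five 2.5-um slices).
#' @param peak_intensity profile amplitude at the center (arbitrary counts).
#' @param falloff Gaussian sigma as a fraction of each radius (default 0.5:
#'   intensity at the nominal radius is `exp(-2)` of the peak).
#' @return A `nucleus_spec` list.
#' @export
nucleus_spec <- function(center, radii = c(5, 4.5, 4.5),
                         peak_intensity = 200, falloff = 0.5) {
  center <- as.numeric(center); radii <- as.numeric(radii)
  stopifnot(length(center) == 3L, length(radii) == 3L)
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  if (peak_intensity <= 0) stop("peak_intensity must be positive", call. = FALSE)
  if (falloff <= 0) stop("falloff must be positive", call. = FALSE)
  structure(list(center = center, radii = radii,
                 peak_intensity = peak_intensity, falloff = falloff),
            class = "nucleus_spec")
}

#' Specify a synthetic light-sheet scene
#'
#' Bundles the volume geometry, the nuclei, and the background model. The
#' extent divided by the spacing must give an integer voxel shape. All
#' randomness (the additive background noise) is fixed by `rng_seed`.
#'
#' @param volume_extent length-3 `(z, y, x)` physical extent in micrometres.
#' @param nuclei list of [nucleus_spec()] objects.
#' @param spacing `(dz, dy, dx)` in micrometres; default `(2.50, 0.75, 0.75)`.
#' @param background_mean mean background intensity (counts).
#' @param background_noise_sd standard deviation of the additive Gaussian
#'   background noise (counts).
#' @param rng_seed integer seed fixing the rendered noise.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(volume_extent, nuclei = list(),
                       spacing = DEFAULT_SPACING,
                       background_mean = 10, background_noise_sd = 5,
                       rng_seed = 1L) {
  volume_extent <- as.numeric(volume_extent)
  spacing <- as.numeric(spacing)
  stopifnot(length(volume_extent) == 3L, length(spacing) == 3L)
  shape <- volume_extent / spacing
  if (any(abs(shape - round(shape)) > 1e-8))
    stop("volume_extent must be an integer multiple of spacing on each axis",
         call. = FALSE)
  if (any(round(shape) < 1)) stop("extent too small for one voxel", call. = FALSE)
  if (background_mean < 0 || background_noise_sd < 0)
    stop("background parameters must be non-negative", call. = FALSE)
  for (nuc in nuclei)
    if (!inherits(nuc, "nucleus_spec"))
      stop("`nuclei` must be a list of nucleus_spec objects", call. = FALSE)
  if (length(nuclei) >= 2L) {
    centers <- t(vapply(nuclei, `[[`, numeric(3), "center"))
    if (anyDuplicated(round(centers, 9)))
      stop("two nuclei share an identical center", call. = FALSE)
  }
  structure(list(volume_extent = volume_extent, spacing = spacing,
                 nuclei = nuclei, background_mean = background_mean,
                 background_noise_sd = background_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# run code with a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic scene to an image and ground-truth labels
#'
#' Intensity at each voxel is `background_mean` plus the sum of the nuclear
#' Gaussian profiles plus i.i.d. Gaussian noise, clipped at zero and rounded
#' to integer counts (camera-like). The ground-truth label of a voxel is the
#' index of the nucleus whose normalized profile is largest there, provided
#' that profile exceeds the membership cutoff `0.5 * exp(-0.5 / falloff^2)`
#' (half the normalized profile value at the nominal radius); otherwise 0.
#' Deterministic given `rng_seed`. A warning is emitted if a nucleus is
#' clipped so hard by the volume edge that it contributes no voxel.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `image` (an [image_volume()]) and `labels`
#'   (the ground-truth [label_volume()]).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  shape <- as.integer(round(spec$volume_extent / spec$spacing))
  # voxel center coordinates in micrometres
  coords <- lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * spec$spacing[a])

  intensity <- array(spec$background_mean, dim = shape)
  best_profile <- array(0, dim = shape)
  best_label <- array(0L, dim = shape)

  for (j in seq_along(spec$nuclei)) {
    nuc <- spec$nuclei[[j]]
    sig <- nuc$falloff * nuc$radii
    gz <- exp(-0.5 * ((coords[[1]] - nuc$center[1]) / sig[1])^2)
    gy <- exp(-0.5 * ((coords[[2]] - nuc$center[2]) / sig[2])^2)
    gx <- exp(-0.5 * ((coords[[3]] - nuc$center[3]) / sig[3])^2)
    profile <- outer(outer(gz, gy), gx)  # separable axis-aligned Gaussian
    intensity <- intensity + nuc$peak_intensity * profile
    cutoff <- 0.5 * exp(-0.5 / nuc$falloff^2)
    member <- profile >= cutoff & profile > best_profile
    if (!any(profile >= cutoff))
      warning("nucleus ", j, " is clipped by the volume edge and contributes ",
              "no ground-truth voxel", call. = FALSE)
    best_label[member] <- j
    best_profile[member] <- profile[member]
  }

  noise <- with_seed(spec$rng_seed,
                     rnorm(prod(shape), 0, spec$background_noise_sd))
  intensity <- round(pmax(intensity + noise, 0))
  dim(intensity) <- shape

  list(image = image_volume(intensity, spec$spacing),
       labels = label_volume(best_label, spec$spacing))
}

#' Scene of k deliberately touching nuclei
#'
#' Builds the canonical "incorrectly joined region" fixture: `k` nuclei whose
#' pairwise center distance is `(1 - overlap)` times the sum of their
#' in-plane radii along the connecting line, so that an intensity bridge
#' joins them and a global threshold fuses them into a single connected
#' component while the ground truth keeps them distinct. Two nuclei are
#' placed along X; three form a triangle in the X-Y plane. The cluster is
#' rotated in-plane and the radii and peaks jittered (around 10%) under
#' `rng_seed`.
#'
#' @param k 2 or 3 nuclei.
#' @param overlap fraction in (0, 1); larger values push the centers closer.
#' @param rng_seed integer seed controlling jitter and rendered noise.
#' @param radii base nominal radii `(rz, ry, rx)` in micrometres.
#' @param peak_intensity base peak intensity.
#' @return A [scene_spec()]; render it with [render_scene()].
#' @export
make_touching_cluster <- function(k, overlap = 0.3, rng_seed = 1L,
                                  radii = c(5, 4.5, 4.5),
                                  peak_intensity = 200) {
  k <- as.integer(k)
  if (!(k %in% c(2L, 3L))) stop("`k` must be 2 or 3", call. = FALSE)
  if (overlap <= 0 || overlap >= 1)
    stop("infeasible geometry: `overlap` must be in (0, 1)", call. = FALSE)

  par <- with_seed(rng_seed, list(
    rscale = runif(k, 0.9, 1.1),
    pscale = runif(k, 0.9, 1.1),
    theta = runif(1, 0, 2 * pi)
  ))
  rad <- lapply(seq_len(k), function(j) radii * par$rscale[j])
  rxy <- vapply(rad, function(r) mean(r[2:3]), numeric(1))

  # in-plane (y, x) layout before rotation
  if (k == 2L) {
    d12 <- (1 - overlap) * (rxy[1] + rxy[2])
    pts <- rbind(c(0, 0), c(0, d12))
  } else {
    d12 <- (1 - overlap) * (rxy[1] + rxy[2])
    d13 <- (1 - overlap) * (rxy[1] + rxy[3])
    d23 <- (1 - overlap) * (rxy[2] + rxy[3])
    if (d12 + d13 <= d23 || d12 + d23 <= d13 || d13 + d23 <= d12)
      stop("infeasible geometry for the requested radii", call. = FALSE)
    x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
    y3 <- sqrt(max(d13^2 - x3^2, 0))
    pts <- rbind(c(0, 0), c(0, d12), c(y3, x3))
  }
  rot <- cbind(c(cos(par$theta), sin(par$theta)),
               c(-sin(par$theta), cos(par$theta)))
  pts <- pts %*% rot

  # fit the volume around the cluster with a ~1.5-radius margin
  margin_xy <- 1.5 * max(rxy)
  margin_z <- 1.5 * max(vapply(rad, `[[`, numeric(1), 1))
  sp <- DEFAULT_SPACING
  span_y <- diff(range(pts[, 1])); span_x <- diff(range(pts[, 2]))
  extent <- c(2 * margin_z,
              span_y + 2 * margin_xy,
              span_x + 2 * margin_xy)
  shape <- ceiling(extent / sp)
  extent <- shape * sp
  cz <- extent[1] / 2
  offs_y <- (extent[2] - span_y) / 2 - min(pts[, 1])
  offs_x <- (extent[3] - span_x) / 2 - min(pts[, 2])

  nuclei <- lapply(seq_len(k), function(j)
    nucleus_spec(center = c(cz, pts[j, 1] + offs_y, pts[j, 2] + offs_x),
                 radii = rad[[j]],
                 peak_intensity = peak_intensity * par$pscale[j]))
  scene_spec(volume_extent = extent, nuclei = nuclei, spacing = sp,
             rng_seed = rng_seed)
}

#' Scene emulating a block of cortex at a given nuclear density
#'
#' Places nuclei with uniformly random, pairwise-distinct centers in a block
#' of the given extent; the count is Poisson with mean `density_target *
#' volume`. The default density matches roughly 460 nuclei in a 96 x 96 x
#' 160 um block of adult mouse cortex; the default extent is a scaled-down
#' block (one eighth the volume) so that tests render quickly. If the
#' requested density cannot be realized without nuclei overlapping, a warning
#' is emitted and overlapping nuclei are placed anyway (dense tissue is the
#' realistic regime).
#'
#' @param density_target nuclei per cubic micrometre; default
#'   `460 / (96 * 96 * 160)`.
#' @param rng_seed integer seed.
#' @param volume_extent `(z, y, x)` block extent in micrometres; default
#'   `(80, 48, 48)`.
#' @param radii base nominal radii, jittered ~10% per nucleus.
#' @param peak_intensity base peak intensity, jittered ~10%.
#' @return A [scene_spec()].
#' @export
make_cortex_block <- function(density_target = 460 / (96 * 96 * 160),
                              rng_seed = 1L,
                              volume_extent = c(80, 48, 48),
                              radii = c(5, 4.5, 4.5),
                              peak_intensity = 200) {
  if (density_target <= 0) stop("density_target must be > 0", call. = FALSE)
  volume_extent <- as.numeric(volume_extent)
  sp <- DEFAULT_SPACING
  shape <- ceiling(volume_extent / sp - 1e-9)
  volume_extent <- shape * sp
  vol <- prod(volume_extent)

  draws <- with_seed(rng_seed, {
    n <- rpois(1, density_target * vol)
    list(n = n,
         centers = cbind(runif(n, 0, volume_extent[1]),
                         runif(n, 0, volume_extent[2]),
                         runif(n, 0, volume_extent[3])),
         rscale = runif(n, 0.9, 1.1),
         pscale = runif(n, 0.9, 1.1))
  })
  n <- draws$n
  mean_nucleus_vol <- 4 / 3 * pi * prod(radii)
  if (n * mean_nucleus_vol > 0.35 * vol)
    warning("requested density is too high for non-overlapping nuclei; ",
            "placing overlapping nuclei", call. = FALSE)
  nuclei <- lapply(seq_len(n), function(j)
    nucleus_spec(center = draws$centers[j, ],
                 radii = radii * draws$rscale[j],
                 peak_intensity = peak_intensity * draws$pscale[j]))
  scene_spec(volume_extent = volume_extent, nuclei = nuclei, spacing = sp,
             rng_seed = rng_seed)
}
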