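# Small deterministic fixtures shared across test files.

vol3 <- function(values, dims, spacing = c(2.5, 0.75, 0.75)) {
  image_volume(array(values, dim = dims), spacing)
}

labs3 <- function(values, dims, spacing = c(2.5, 0.75, 0.75)) {
  label_volume(array(as.integer(values), dim = dims), spacing)
}

# One Z-slice (1 x ny x nx) image/label pair from matrices given in [y, x].
slice_pair <- function(intensity, labels) {
  ny <- nrow(intensity); nx <- ncol(intensity)
  img <- array(0, dim = c(1, ny, nx)); img[1, , ] <- intensity
  lab <- array(0L, dim = c(1, ny, nx)); lab[1, , ] <- as.integer(labels)
  list(image = image_volume(img), labels = label_volume(lab))
}

# Intensity ramp row 100, 90, 80, 70 at y = 3 of a 5 x 5 slice, region = the
# 100-voxel; the canonical grow/shrink fixture.
ramp_fixture <- function(values = c(100, 90, 80, 70)) {
  I <- matrix(0, 5, 5)
  I[3, seq_along(values)] <- values
  L <- matrix(0L, 5, 5)
  L[3, 1] <- 1L
  slice_pair(I, L)
}

# Dumbbell: two 5x5x3 bright cores joined by a single-voxel bridge of
# intensity 80; one region at threshold 50. Returns the pair plus the
# ground-truth core halves (x <= 5 vs x >= 7).
dumbbell_fixture <- function() {
  nz <- 3; ny <- 5; nx <- 11
  img <- array(0, dim = c(nz, ny, nx))
  core <- function(xs) {
    for (z in 1:3) for (y in 1:5) for (x in xs) {
      cheb <- max(abs(z - 2), abs(y - 3), abs(x - mean(range(xs))))
      img[z, y, x] <<- 200 - 25 * cheb
    }
  }
  core(1:5); core(7:11)
  img[2, 3, 6] <- 80
  lab <- array(0L, dim = c(nz, ny, nx))
  lab[img >= 50] <- 1L
  half_a <- array(FALSE, dim = c(nz, ny, nx)); half_a[, , 1:5] <- lab[, , 1:5] > 0
  half_b <- array(FALSE, dim = c(nz, ny, nx)); half_b[, , 7:11] <- lab[, , 7:11] > 0
  list(image = image_volume(img), labels = label_volume(lab),
       half_a = half_a, half_b = half_b)
}

# Random binary mask of a given shape and foreground probability.
random_mask <- function(dims, p, seed) {
  set.seed(seed)
  array(runif(prod(dims)) < p, dim = dims)
}

# Random blobby intensity landscape with small-integer values: a few Gaussian
# bumps plus noise, quantized; the largest connected component above a floor
# becomes the test region for the split-seed oracle.
random_region_fixture <- function(dims, seed, n_bumps = 2) {
  set.seed(seed)
  zc <- runif(n_bumps, 1, dims[1]); yc <- runif(n_bumps, 1, dims[2])
  xc <- runif(n_bumps, 1, dims[3])
  amp <- runif(n_bumps, 8, 14)
  sig <- runif(n_bumps, 1, 2.5)
  img <- array(0, dim = dims)
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2])) for (x in seq_len(dims[3])) {
    v <- 0
    for (b in seq_len(n_bumps))
      v <- v + amp[b] * exp(-0.5 * ((z - zc[b])^2 + (y - yc[b])^2 +
                                      (x - xc[b])^2) / sig[b]^2)
    img[z, y, x] <- v
  }
  img <- round(img + runif(prod(dims), 0, 1))
  cc <- label_components(img >= 3, connectivity = 26L)
  if (max(cc) == 0) return(NULL)
  sizes <- tabulate(cc[cc > 0])
  lab <- array(0L, dim = dims)
  lab[cc == which.max(sizes)] <- 1L
  list(image = image_volume(img), labels = label_volume(lab))
}
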