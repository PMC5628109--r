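# Test helpers: small volume builders and independent brute-force oracles.

make_volume <- function(dims = c(5, 6, 6), spacing = c(3, 1.35, 1.35),
                        fill = 0, origin = c(0, 0, 0)) {
  ct_volume(array(fill, dims), spacing = spacing, origin = origin)
}

# Brute-force flood fill over a logical 3D array; independent of the
# package's labeling path. Returns a list of voxel-index matrices.
flood_fill_components <- function(fg, connectivity) {
  d <- dim(fg)
  offsets <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    s <- abs(dz) + abs(dy) + abs(dx)
    if (s == 0) next
    if (connectivity == 6 && s > 1) next
    if (connectivity == 18 && s > 2) next
    offsets[[length(offsets) + 1L]] <- c(dz, dy, dx)
  }
  seen <- array(FALSE, d)
  comps <- list()
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!fg[z, y, x] || seen[z, y, x]) next
    queue <- list(c(z, y, x))
    seen[z, y, x] <- TRUE
    members <- list()
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      members[[length(members) + 1L]] <- v
      for (off in offsets) {
        w <- v + off
        if (any(w < 1) || any(w > d)) next
        if (fg[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
    comps[[length(comps) + 1L]] <- do.call(rbind, members)
  }
  comps
}

# canonical string form of a voxel set, for set comparison
voxel_set_key <- function(idx) {
  paste(sort(paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")), collapse = ";")
}

# Dense direct 3D Gaussian convolution on a small grid (physical sigma),
# replicate padding; independent oracle for the separable implementation.
dense_gaussian_oracle <- function(vol, sigma_mm) {
  d <- dim(vol$data)
  sig_vox <- sigma_mm / vol$spacing
  r <- pmax(1, ceiling(3 * sig_vox))
  w1 <- lapply(1:3, function(a) {
    w <- dnorm(seq(-r[a], r[a]), sd = sig_vox[a])
    w / sum(w)
  })
  out <- array(0, d)
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (iz in seq_along(w1[[1]])) for (iy in seq_along(w1[[2]]))
      for (ix in seq_along(w1[[3]])) {
        zz <- clamp(z + iz - r[1] - 1, d[1])
        yy <- clamp(y + iy - r[2] - 1, d[2])
        xx <- clamp(x + ix - r[3] - 1, d[3])
        acc <- acc + w1[[1]][iz] * w1[[2]][iy] * w1[[3]][ix] *
          vol$data[zz, yy, xx]
      }
    out[z, y, x] <- acc
  }
  out
}

# toy feature matrix with a schema attribute, for classifier tests
toy_features <- function(n_per_class, seed, shift = 8) {
  set.seed(seed)
  p <- 4
  a <- matrix(rnorm(n_per_class * p), ncol = p)
  b <- matrix(rnorm(n_per_class * p, mean = shift), ncol = p)
  m <- rbind(a, b)
  colnames(m) <- paste0("f", seq_len(p))
  attr(m, "schema") <- "toy/1"
  list(features = m,
       labels = rep(c("background", "CAC"), each = n_per_class))
}
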