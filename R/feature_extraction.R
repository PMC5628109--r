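#' Separable Gaussian smoothing of a CT volume
#'
#' Smooths with a physical-scale Gaussian: the standard deviation `sigma_mm`
#' is converted per axis into voxel units, so anisotropic grids are handled
#' correctly. Replicate padding at the borders; axes where the kernel is
#' narrower than a hundredth of a voxel are left untouched.
#'
#' @param volume a [ct_volume].
#' @param sigma_mm Gaussian standard deviation in mm (> 0).
#' @return A [ct_volume] with smoothed data on the same grid.
#' @export
gaussian_smooth <- function(volume, sigma_mm) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm <= 0)
    stop("`sigma_mm` must be a single positive scale")
  a <- volume$data
  for (axis in 1:3) {
    sig <- sigma_mm / volume$spacing[axis]
    if (sig < 0.01) next
    r <- max(1L, ceiling(3 * sig))
    w <- dnorm(-r:r, sd = sig)
    w <- w / sum(w)
    a <- convolve_axis(a, w, axis)
  }
  out <- volume
  out$data <- a
  out
}

convolve_axis <- function(a, w, axis) {
  n <- dim(a)[axis]
  r <- (length(w) - 1L) / 2L
  res <- array(0, dim(a))
  for (k in seq_along(w)) {
    off <- k - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    res <- res + w[k] * switch(axis,
                               a[idx, , , drop = FALSE],
                               a[, idx, , drop = FALSE],
                               a[, , idx, drop = FALSE])
  }
  res
}

#' Shape features of a lesion candidate
#'
#' Ratios of the eigenvalues of the covariance of the candidate's voxel
#' positions in physical (mm) coordinates, so that thick slices do not
#' distort shape. Eigenvalues are sorted descending (`l1 >= l2 >= l3`); the
#' ratios `r21 = l2/l1`, `r31 = l3/l1`, `r32 = l3/l2` lie in `[0, 1]`
#' (1 = isotropic blob, 0 = degenerate axis). A zero denominator yields 0.
#'
#' @param candidate a `lesion_candidate` with at least 2 voxels.
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @return Named numeric vector `(r21, r31, r32)`.
#' @export
shape_features <- function(candidate, spacing) {
  idx <- candidate$voxel_indices
  if (nrow(idx) < 2L) stop("shape features need >= 2 voxels")
  xyz <- sweep(idx - 1, 2, spacing, "*")
  ev <- sort(eigen(cov(xyz), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  tol <- max(ev[1], .Machine$double.eps) * 1e-9
  ratio <- function(num, den) if (den > tol) num / den else 0
  c(r21 = ratio(ev[2], ev[1]), r31 = ratio(ev[3], ev[1]),
    r32 = ratio(ev[3], ev[2]))
}

#' Intensity features of a lesion candidate
#'
#' Statistics of the candidate's member voxels in the raw volume (max, mean,
#' sd) plus max and mean sampled over the member voxels of Gaussian-smoothed
#' copies of the volume at each requested physical scale. The multi-scale
#' block captures how conspicuous the lesion remains under increasing blur,
#' which separates compact calcium from streaky noise.
#'
#' @param candidate a `lesion_candidate`.
#' @param volume the parent [ct_volume].
#' @param scales positive Gaussian scales in mm (default 1, 2, 4).
#' @param smoothed optional pre-computed list of smoothed volumes (one per
#'   scale), to share work across candidates.
#' @return Named numeric vector: `hu_max`, `hu_mean`, `hu_sd`, then
#'   `hu_s<scale>_max`, `hu_s<scale>_mean` per scale.
#' @export
intensity_features <- function(candidate, volume, scales = c(1, 2, 4),
                               smoothed = NULL) {
  if (length(scales) == 0L || any(scales <= 0))
    stop("`scales` must be a nonempty vector of positive mm values")
  hu <- volume$data[candidate$voxel_indices]
  out <- c(hu_max = max(hu), hu_mean = mean(hu), hu_sd = sd(hu))
  if (is.null(smoothed))
    smoothed <- lapply(scales, function(s) gaussian_smooth(volume, s))
  for (i in seq_along(scales)) {
    sv <- smoothed[[i]]$data[candidate$voxel_indices]
    nm <- paste0("hu_s", format(scales[i]), "_")
    out[paste0(nm, c("max", "mean"))] <- c(max(sv), mean(sv))
  }
  out
}

#' Coronary tree template
#'
#' Bundles a reference volume, its heart mask and three labeled centerlines
#' (RCA, LAD, LCX) in the template's physical coordinates. Used by
#' [estimate_coronary_tree] to carry the coronary geometry into a subject
#' scan. The phantom generator ships its true geometry as a template; for
#' real data, supply your own.
#'
#' @param volume template [ct_volume].
#' @param heart_mask [voxel_mask] of the heart region on the template grid.
#' @param centerlines named list (`RCA`, `LAD`, `LCX`) of `m x 3` matrices of
#'   `(z, y, x)` vertices in mm, each with at least 2 vertices.
#' @return Object of class `coronary_template`.
#' @export
coronary_template <- function(volume, heart_mask, centerlines) {
  stopifnot(inherits(volume, "ct_volume"), inherits(heart_mask, "voxel_mask"))
  if (!all(c("RCA", "LAD", "LCX") %in% names(centerlines)))
    stop("centerlines must be named RCA, LAD, LCX")
  for (cl in centerlines)
    if (!is.matrix(cl) || ncol(cl) != 3L || nrow(cl) < 2L)
      stop("each centerline needs >= 2 (z, y, x) vertices")
  structure(list(volume = volume, heart_mask = heart_mask,
                 centerlines = centerlines),
            class = "coronary_template")
}

#' Estimate the coronary tree location in a subject scan
#'
#' Maps a template's labeled coronary centerlines into the subject volume by
#' an affine transform that aligns heart-region intensity moments: the
#' centroid and per-axis spread of the soft-tissue/blood band (default 35-90
#' HU, between fat and calcium) of subject and template are matched by a
#' per-axis scaling plus translation. Rotation is not estimated: axial CT is
#' acquired in a fixed supine convention, and the template is defined in it.
#'
#' @param volume subject [ct_volume].
#' @param template a [coronary_template].
#' @param hu_band length-2 HU interval defining the heart-like region.
#' @return Object of class `coronary_tree`: transformed `centerlines` (mm),
#'   `heart_centroid_mm`, `heart_halfext_mm`, the `transform`
#'   (`scale`, `shift` per axis), and the subject grid geometry.
#' @export
estimate_coronary_tree <- function(volume, template, hu_band = c(35, 90)) {
  stopifnot(inherits(volume, "ct_volume"), inherits(template, "coronary_template"))
  subj <- mask_moments(volume$data >= hu_band[1] & volume$data <= hu_band[2],
                       volume)
  if (subj$n < 10L)
    stop("no heart-like region in the subject volume; cannot estimate the coronary tree")
  # same region definition on both sides, so matched anatomy maps exactly
  temp <- mask_moments(template$volume$data >= hu_band[1] &
                         template$volume$data <= hu_band[2],
                       template$volume)
  scale <- subj$sd / pmax(temp$sd, .Machine$double.eps)
  shift <- subj$centroid - scale * temp$centroid
  map <- function(p) sweep(sweep(p, 2, scale, "*"), 2, shift, "+")
  centerlines <- lapply(template$centerlines, map)
  heart <- mask_moments(template$heart_mask$data, template$volume)
  heart_centroid <- as.vector(scale * heart$centroid + shift)
  heart_halfext <- as.vector(scale * heart$halfext)
  structure(list(centerlines = centerlines,
                 heart_centroid_mm = heart_centroid,
                 heart_halfext_mm = heart_halfext,
                 transform = list(scale = scale, shift = shift),
                 grid = list(dim = dim(volume$data), spacing = volume$spacing,
                             origin = volume$origin)),
            class = "coronary_tree")
}

mask_moments <- function(mask, volume) {
  lin <- which(mask)
  d <- dim(volume$data)
  z <- ((lin - 1L) %% d[1]) + 1L
  y <- (((lin - 1L) %/% d[1]) %% d[2]) + 1L
  x <- ((lin - 1L) %/% (d[1] * d[2])) + 1L
  pts <- sweep(sweep(cbind(z, y, x) - 1, 2, volume$spacing, "*"), 2,
               volume$origin, "+")
  if (length(lin) == 0L)
    return(list(n = 0L, centroid = c(0, 0, 0), sd = c(1, 1, 1),
                halfext = c(1, 1, 1)))
  ctr <- colMeans(pts)
  list(n = length(lin), centroid = ctr,
       sd = apply(pts, 2, sd),
       halfext = (apply(pts, 2, max) - apply(pts, 2, min)) / 2)
}

#' Exact distance map to the estimated coronary tree
#'
#' Euclidean distance (mm) from every voxel centre of a grid to the nearest
#' point of a labeled centerline, or of the union of all three.
#'
#' @param tree a `coronary_tree` from [estimate_coronary_tree].
#' @param volume the subject [ct_volume] supplying the grid.
#' @param label `"RCA"`, `"LAD"`, `"LCX"` or `"union"`.
#' @return Numeric 3D array of distances in mm.
#' @export
distance_map <- function(tree, volume, label = "union") {
  stopifnot(inherits(tree, "coronary_tree"))
  d <- dim(volume$data)
  zz <- volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1]
  yy <- volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2]
  xx <- volume$origin[3] + (seq_len(d[3]) - 1) * volume$spacing[3]
  pts <- cbind(rep(zz, times = d[2] * d[3]),
               rep(rep(yy, each = d[1]), times = d[3]),
               rep(xx, each = d[1] * d[2]))
  dist <- dist_points_to_tree(pts, tree, label)
  array(dist, d)
}

dist_points_to_tree <- function(pts, tree, label) {
  if (label == "union") {
    dmat <- vapply(tree$centerlines,
                   function(cl) dist_points_to_polyline(pts, cl),
                   numeric(nrow(pts)))
    if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1)
    apply(dmat, 1, min)
  } else {
    dist_points_to_polyline(pts, tree$centerlines[[label]])
  }
}

# Minimum Euclidean distance from each point (rows of `pts`) to a polyline
# given by consecutive vertices (rows of `verts`), all in mm.
dist_points_to_polyline <- function(pts, verts) {
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(verts) - 1L)) {
    a <- verts[i, ]; b <- verts[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    pa <- sweep(pts, 2, a)
    t <- if (len2 > 0) pmin(pmax(pa %*% ab / len2, 0), 1) else rep(0, nrow(pts))
    diff <- pa - outer(as.vector(t), ab)
    best <- pmin(best, sqrt(rowSums(diff^2)))
  }
  best
}

#' Location features of a lesion candidate
#'
#' Distances (mm) from the candidate centroid to the nearest point of each
#' labeled coronary centerline and of their union, computed exactly against
#' the polylines, plus the centroid position in heart-centered normalized
#' coordinates (`(centroid - heart centroid) / heart half-extent` per axis).
#'
#' @param candidate a `lesion_candidate`.
#' @param tree a `coronary_tree` from [estimate_coronary_tree].
#' @return Named numeric vector: `dist_rca_mm`, `dist_lad_mm`, `dist_lcx_mm`,
#'   `dist_tree_mm`, `pos_z`, `pos_y`, `pos_x`.
#' @export
location_features <- function(candidate, tree) {
  stopifnot(inherits(tree, "coronary_tree"))
  p <- matrix(candidate$centroid_mm, nrow = 1)
  lo <- tree$grid$origin - tree$grid$spacing / 2
  hi <- tree$grid$origin + (tree$grid$dim - 0.5) * tree$grid$spacing
  if (any(p < lo) || any(p > hi))
    stop("candidate centroid lies outside the subject volume")
  d <- vapply(c("RCA", "LAD", "LCX"),
              function(l) dist_points_to_polyline(p, tree$centerlines[[l]]),
              numeric(1))
  pos <- (candidate$centroid_mm - tree$heart_centroid_mm) /
    pmax(tree$heart_halfext_mm, .Machine$double.eps)
  c(dist_rca_mm = d[["RCA"]], dist_lad_mm = d[["LAD"]],
    dist_lcx_mm = d[["LCX"]], dist_tree_mm = min(d),
    pos_z = pos[1], pos_y = pos[2], pos_x = pos[3])
}

#' Feature-computation configuration
#'
#' @param scales Gaussian scales in mm for the intensity block.
#' @return List with `scales` and the feature `schema` version string.
#' @export
feature_config <- function(scales = c(1, 2, 4)) {
  if (length(scales) == 0L || any(scales <= 0)) stop("scales must be positive")
  list(scales = scales,
       schema = paste0("cac-features/1-s", paste(format(scales), collapse = ",")))
}

#' Compute the full feature matrix for a set of candidates
#'
#' Assembles the volume, shape, intensity and location blocks into one row
#' per candidate, in candidate order, with stable column names recorded in
#' the `schema` attribute.
#'
#' @param candidates list of `lesion_candidate`.
#' @param volume parent [ct_volume].
#' @param tree `coronary_tree` for the same grid.
#' @param config from [feature_config].
#' @return Numeric matrix (candidates x features) with attribute `schema`.
#' @export
featurize <- function(candidates, volume, tree, config = feature_config()) {
  smoothed <- lapply(config$scales, function(s) gaussian_smooth(volume, s))
  rows <- lapply(candidates, function(cc) {
    c(n_voxels = cc$n_voxels, volume_mm3 = cc$volume_mm3,
      shape = shape_features(cc, volume$spacing),
      intensity_features(cc, volume, config$scales, smoothed = smoothed),
      location_features(cc, tree))
  })
  if (length(rows) == 0L) {
    probe <- feature_names(config)
    m <- matrix(numeric(0), nrow = 0, ncol = length(probe),
                dimnames = list(NULL, probe))
  } else {
    m <- do.call(rbind, rows)
    rownames(m) <- NULL
  }
  if (any(!is.finite(m))) stop("non-finite feature value")
  attr(m, "schema") <- config$schema
  m
}

feature_names <- function(config = feature_config()) {
  c("n_voxels", "volume_mm3", "shape.r21", "shape.r31", "shape.r32",
    "hu_max", "hu_mean", "hu_sd",
    as.vector(t(outer(paste0("hu_s", format(config$scales), "_"),
                      c("max", "mean"), paste0))),
    "dist_rca_mm", "dist_lad_mm", "dist_lcx_mm", "dist_tree_mm",
    "pos_z", "pos_y", "pos_x")
}

#' Write / read centerlines as JSON polylines
#'
#' Format: a JSON array of objects `{"label": "RCA", "points_mm": [[z,y,x],
#' ...]}`.
#'
#' @param centerlines named list of `m x 3` vertex matrices in mm.
#' @param path JSON file path.
#' @export
write_centerlines <- function(centerlines, path) {
  obj <- lapply(names(centerlines), function(nm)
    list(label = nm, points_mm = unname(apply(centerlines[[nm]], 1,
                                              as.numeric, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centerlines
#' @export
read_centerlines <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (el in obj) {
    pts <- do.call(rbind, lapply(el$points_mm, function(p) as.numeric(unlist(p))))
    out[[el$label]] <- pts
  }
  out
}
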