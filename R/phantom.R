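#' Specification of a synthetic thorax phantom
#'
#' Describes one synthetic patient: a parametric thorax (soft tissue, lungs,
#' heart, descending aorta, vertebra) with three coronary centerlines on the
#' heart surface, coronary calcifications placed along them, distractor
#' calcifications in the aortic wall, and the acquisition characteristics of
#' a paired gated calcium-scoring scan (CSCT: fine in-plane grid, low noise,
#' no motion) and a non-gated attenuation-correction scan (CTAC: coarse
#' in-plane grid, high noise, motion blur). The CSCT in-plane spacing is
#' exactly 1/4 of the CTAC spacing, so the fine rendering doubles as the 4x
#' supersampled source for area-weighted CTAC downsampling; both scans use
#' 3 mm slices.
#'
#' The anatomy is deliberately geometric, not anatomically realistic: its
#' purpose is exercising threshold topology, shape statistics, tree
#' distances and classifier separability with a known ground truth.
#'
#' @param lesions data frame with one coronary lesion per row: `artery`
#'   (`"RCA"`, `"LAD"`, `"LCX"`), `t` (position along the centerline in
#'   `[0, 1]`), `radius_mm` (> 0) and `peak_hu` (>= 130).
#' @param aorta_calcs data frame of aortic-wall distractor calcifications:
#'   `z_mm`, `angle_deg` (position on the wall, 0 = away from the heart),
#'   `radius_mm`, `peak_hu`.
#' @param noise_sd_csct,noise_sd_ctac Gaussian HU noise per scan type.
#' @param motion_blur_mm standard deviation (mm) of the anisotropic Gaussian
#'   blur emulating cardiac motion in the non-gated scan, applied before
#'   downsampling: full along z (through-plane) and y, half along x. Cardiac
#'   displacement during a free-breathing non-gated acquisition is several
#'   mm; the default effective sigma of 1.5 mm is conservative.
#' @param heart_center,heart_axes centre and semi-axes (mm, `(z, y, x)`) of
#'   the heart ellipsoid.
#' @param seed integer; fixes the noise. Identical specs render
#'   byte-identical volumes.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(lesions = empty_lesion_table(),
                         aorta_calcs = empty_aorta_table(),
                         noise_sd_csct = 10, noise_sd_ctac = 25,
                         motion_blur_mm = 1.5,
                         heart_center = c(24, 30, 32),
                         heart_axes = c(20, 19, 17),
                         seed = 1) {
  lesions <- as.data.frame(lesions)
  aorta_calcs <- as.data.frame(aorta_calcs)
  need <- c("artery", "t", "radius_mm", "peak_hu")
  if (nrow(lesions) > 0) {
    if (!all(need %in% names(lesions))) stop("lesions need columns ", paste(need, collapse = ", "))
    if (any(!lesions$artery %in% c("RCA", "LAD", "LCX"))) stop("unknown artery label")
    if (any(lesions$t < 0 | lesions$t > 1)) stop("lesion position t must be in [0, 1]")
    if (any(lesions$radius_mm <= 0)) stop("lesion radii must be > 0")
    if (any(lesions$peak_hu < 130)) stop("lesion peak HU must be >= 130")
  }
  spec <- list(
    fov_mm = c(48, 64.8, 64.8),
    slice_mm = 3, csct_inplane_mm = 1.35 / 4, ctac_inplane_mm = 1.35,
    hu = list(soft = 20, lung = -800, heart = 50, vertebra = 700),
    heart_center = heart_center, heart_axes = heart_axes,
    lungs = list(centers = list(c(24, 26, 10), c(24, 26, 54.8)),
                 axes = c(24, 14, 8.5)),
    aorta = list(center_yx = c(52, 54), radius = 4.5),
    vertebra = list(center_yx = c(57, 28), radius = 7),
    lesions = lesions, aorta_calcs = aorta_calcs,
    noise_sd_csct = noise_sd_csct, noise_sd_ctac = noise_sd_ctac,
    motion_blur_mm = motion_blur_mm, seed = seed
  )
  class(spec) <- "phantom_spec"
  spec
}

empty_lesion_table <- function() {
  data.frame(artery = character(), t = numeric(), radius_mm = numeric(),
             peak_hu = numeric())
}
empty_aorta_table <- function() {
  data.frame(z_mm = numeric(), angle_deg = numeric(), radius_mm = numeric(),
             peak_hu = numeric())
}

# Parametric coronary centerlines on the (slightly shrunken) heart surface.
phantom_centerlines <- function(spec, n_vertices = 25) {
  C <- spec$heart_center
  A <- spec$heart_axes * 0.98
  surf <- function(theta, phi)
    cbind(C[1] + A[1] * cos(theta),
          C[2] + A[2] * sin(theta) * sin(phi),
          C[3] + A[3] * sin(theta) * cos(phi))
  tt <- seq(0, 1, length.out = n_vertices)
  deg <- pi / 180
  list(
    RCA = surf(theta = (20 + 140 * tt) * deg, phi = rep(45 * deg, n_vertices)),
    LAD = surf(theta = (15 + 150 * tt) * deg, phi = rep(-35 * deg, n_vertices)),
    LCX = surf(theta = (35 + 55 * tt) * deg, phi = (-60 - 100 * tt) * deg)
  )
}

# Linear interpolation of a point at parameter t in [0,1] along a polyline.
polyline_point <- function(verts, t) {
  seg <- sqrt(rowSums(diff(verts)^2))
  s <- c(0, cumsum(seg))
  target <- t * s[length(s)]
  i <- max(1L, findInterval(target, s, rightmost.closed = TRUE))
  i <- min(i, nrow(verts) - 1L)
  frac <- if (seg[i] > 0) (target - s[i]) / seg[i] else 0
  verts[i, ] + frac * (verts[i + 1L, ] - verts[i, ])
}

phantom_grid <- function(spec, type = c("csct", "ctac")) {
  type <- match.arg(type)
  inplane <- if (type == "csct") spec$csct_inplane_mm else spec$ctac_inplane_mm
  spacing <- c(spec$slice_mm, inplane, inplane)
  dims <- round(spec$fov_mm / spacing)
  list(dim = as.integer(dims), spacing = spacing, origin = spacing / 2)
}

# Render the noise-free, blur-free anatomy on the fine (CSCT) grid.
# Returns the HU array plus the per-lesion calcium fields needed for truth.
render_fine <- function(spec) {
  g <- phantom_grid(spec, "csct")
  nz <- g$dim[1]; ny <- g$dim[2]; nx <- g$dim[3]
  zc <- g$origin[1] + (seq_len(nz) - 1) * g$spacing[1]
  yc <- g$origin[2] + (seq_len(ny) - 1) * g$spacing[2]
  xc <- g$origin[3] + (seq_len(nx) - 1) * g$spacing[3]
  Z <- array(rep(zc, times = ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(yc, each = nz), times = nx), c(nz, ny, nx))
  X <- array(rep(xc, each = nz * ny), c(nz, ny, nx))

  a <- array(spec$hu$soft, c(nz, ny, nx))
  for (lc in spec$lungs$centers) {
    ax <- spec$lungs$axes
    inside <- ((Z - lc[1]) / ax[1])^2 + ((Y - lc[2]) / ax[2])^2 +
      ((X - lc[3]) / ax[3])^2 <= 1
    a[inside] <- spec$hu$lung
  }
  hc <- spec$heart_center; ha <- spec$heart_axes
  heart <- ((Z - hc[1]) / ha[1])^2 + ((Y - hc[2]) / ha[2])^2 +
    ((X - hc[3]) / ha[3])^2 <= 1
  a[heart] <- spec$hu$heart
  ao <- spec$aorta
  in_aorta <- (Y - ao$center_yx[1])^2 + (X - ao$center_yx[2])^2 <= ao$radius^2
  a[in_aorta] <- spec$hu$heart
  vb <- spec$vertebra
  in_vert <- (Y - vb$center_yx[1])^2 + (X - vb$center_yx[2])^2 <= vb$radius^2
  a[in_vert] <- spec$hu$vertebra

  # distractor calcifications on the aortic wall
  away <- (ao$center_yx - spec$heart_center[2:3])
  away <- away / sqrt(sum(away^2))
  base_ang <- atan2(away[2], away[1])
  if (nrow(spec$aorta_calcs) > 0) {
    for (i in seq_len(nrow(spec$aorta_calcs))) {
      cal <- spec$aorta_calcs[i, ]
      ang <- base_ang + cal$angle_deg * pi / 180
      ctr <- c(cal$z_mm,
               ao$center_yx[1] + ao$radius * cos(ang),
               ao$center_yx[2] + ao$radius * sin(ang))
      fld <- calcium_field(Z, Y, X, ctr, cal$radius_mm, cal$peak_hu)
      a <- pmax(a, fld)
    }
  }

  centerlines <- phantom_centerlines(spec)
  lesion_fields <- list()
  if (nrow(spec$lesions) > 0) {
    for (i in seq_len(nrow(spec$lesions))) {
      les <- spec$lesions[i, ]
      ctr <- polyline_point(centerlines[[les$artery]], les$t)
      if (any(ctr - les$radius_mm < 0) || any(ctr + les$radius_mm > spec$fov_mm))
        stop("lesion ", i, " extends outside the volume")
      fld <- calcium_field(Z, Y, X, ctr, les$radius_mm, les$peak_hu)
      lesion_fields[[i]] <- list(center = ctr, radius = les$radius_mm,
                                 field_max = max(fld))
      a <- pmax(a, fld)
    }
  }
  dim(a) <- c(nz, ny, nx)
  list(data = a, grid = g, centerlines = centerlines,
       lesion_centers = lapply(lesion_fields, `[[`, "center"),
       heart_mask = heart)
}

# Parabolic attenuation profile: peak at the centre, background at radius r.
calcium_field <- function(Z, Y, X, center, radius, peak) {
  d2 <- (Z - center[1])^2 + (Y - center[2])^2 + (X - center[3])^2
  f <- peak * (1 - d2 / radius^2)
  f[f < 0] <- 0
  f
}

# Area-weighted in-plane downsampling by an integer factor.
downsample_inplane <- function(a, f) {
  d <- dim(a)
  stopifnot(d[2] %% f == 0, d[3] %% f == 0)
  nyc <- d[2] %/% f; nxc <- d[3] %/% f
  dim(a) <- c(d[1], f, nyc, f, nxc)
  a1 <- colSums(aperm(a, c(2, 1, 3, 4, 5)))   # over y sub-index
  a2 <- colSums(aperm(a1, c(3, 1, 2, 4)))     # over x sub-index
  a2 / (f * f)
}

#' Generate a paired CSCT-like and CTAC-like scan with ground truth
#'
#' Renders the phantom anatomy once on the fine grid, then derives
#' * the CSCT scan: fine grid plus low Gaussian noise;
#' * the CTAC scan: anisotropic motion blur, 4x area-weighted in-plane
#'   downsampling to the coarse grid, plus high Gaussian noise;
#' * ground truth: per-lesion masks on both grids (supra-130 HU voxels of
#'   the noise-free rendering belonging to each lesion), true Agatston and
#'   volume scores per scan type computed from the noise-free volumes, and
#'   the true coronary centerlines.
#'
#' @param spec a [phantom_spec].
#' @return List: `csct`, `ctac` ([ct_volume]s), `truth` (list with
#'   `lesions_csct`, `lesions_ctac` as `lesion_candidate` lists,
#'   `agatston_csct`, `agatston_ctac`, `volume_csct`, `volume_ctac`,
#'   `centerlines`, `heart_mask`), and `clean` (the noise-free volumes).
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  fine <- render_fine(spec)
  g_csct <- fine$grid
  csct_clean <- ct_volume(fine$data, g_csct$spacing, g_csct$origin)

  f <- round(spec$ctac_inplane_mm / spec$csct_inplane_mm)
  g_ctac <- phantom_grid(spec, "ctac")
  blur_src <- csct_clean
  if (spec$motion_blur_mm > 0) {
    blur_src$data <- blur_motion(csct_clean$data, spec$motion_blur_mm,
                                 g_csct$spacing)
  }
  ctac_clean <- ct_volume(downsample_inplane(fine$data, f),
                          g_ctac$spacing, g_ctac$origin)
  ctac_blurred <- ct_volume(downsample_inplane(blur_src$data, f),
                            g_ctac$spacing, g_ctac$origin)

  # truth on the CTAC side is what a perfect scorer would measure on the
  # noise-free acquisition, which includes the deterministic motion blur
  truth <- phantom_truth(spec, fine, csct_clean, ctac_blurred)

  noisy <- withr_seed(spec$seed, {
    csct <- csct_clean
    if (spec$noise_sd_csct > 0)
      csct$data <- clip_hu(csct$data +
                             array(rnorm(length(csct$data), 0, spec$noise_sd_csct),
                                   dim(csct$data)))
    ctac <- ctac_blurred
    if (spec$noise_sd_ctac > 0)
      ctac$data <- clip_hu(ctac$data +
                             array(rnorm(length(ctac$data), 0, spec$noise_sd_ctac),
                                   dim(ctac$data)))
    list(csct = csct, ctac = ctac)
  })

  list(csct = noisy$csct, ctac = noisy$ctac, truth = truth,
       clean = list(csct = csct_clean, ctac = ctac_blurred))
}

# Anisotropic Gaussian blur emulating cardiac motion during a non-gated
# acquisition: full sigma along z (through-plane) and y, half along x.
blur_motion <- function(a, sigma_mm, spacing) {
  for (axis in 1:3) {
    sig <- (if (axis == 3) sigma_mm / 2 else sigma_mm) / spacing[axis]
    if (sig < 0.01) next
    r <- max(1L, ceiling(3 * sig))
    w <- dnorm(-r:r, sd = sig); w <- w / sum(w)
    a <- convolve_axis(a, w, axis)
  }
  a
}

phantom_truth <- function(spec, fine, csct_clean, ctac_basis) {
  mk_lesions <- function(vol, centers, radii, margin_z, margin_xy) {
    # gated voxel sets may overlap where two lesions are close; each voxel
    # belongs to the nearest lesion centre so that masks partition the voxels
    gated <- lapply(seq_along(centers), function(i)
      supra_voxels_near(vol, centers[[i]], radii[i], margin_z, margin_xy))
    if (length(gated) > 1L) {
      d <- dim(vol$data)
      lin <- lapply(gated, function(idx)
        idx[, 1] + d[1] * ((idx[, 2] - 1) + d[2] * (idx[, 3] - 1)))
      dist2 <- lapply(seq_along(gated), function(i) {
        pos <- sweep(sweep(gated[[i]] - 1, 2, vol$spacing, "*"), 2,
                     vol$origin, "+")
        rowSums(sweep(pos, 2, centers[[i]])^2)
      })
      best <- new.env()
      for (i in seq_along(gated)) for (j in seq_along(lin[[i]])) {
        k <- as.character(lin[[i]][j])
        if (is.null(best[[k]]) || dist2[[i]][j] < best[[k]][2])
          best[[k]] <- c(i, dist2[[i]][j])
      }
      gated <- lapply(seq_along(gated), function(i) {
        keep <- vapply(seq_along(lin[[i]]), function(j)
          best[[as.character(lin[[i]][j])]][1] == i, logical(1))
        gated[[i]][keep, , drop = FALSE]
      })
    }
    out <- list()
    for (i in seq_along(gated)) {
      idx <- drop_singleton_satellites(gated[[i]])
      if (nrow(idx) == 0L) next
      hu <- vol$data[idx]
      out[[length(out) + 1L]] <- new_lesion_candidate(length(out) + 1L, idx,
                                                      hu, vol)
    }
    out
  }
  radii <- if (nrow(spec$lesions) > 0) spec$lesions$radius_mm else numeric()
  lesions_csct <- mk_lesions(csct_clean, fine$lesion_centers, radii, 0.75, 0.75)
  # the anisotropic motion blur pushes the 130 HU contour outward by at most
  # one slice in z and ~2 sigma in-plane; the gate covers that and no more,
  # so neighbouring structures can never leak into a lesion's truth mask
  lesions_ctac <- mk_lesions(ctac_basis, fine$lesion_centers, radii,
                             spec$slice_mm + 0.75,
                             2 * spec$motion_blur_mm + 0.25)
  list(
    lesions_csct = lesions_csct,
    lesions_ctac = lesions_ctac,
    agatston_csct = agatston_score(lesions_csct, csct_clean),
    agatston_ctac = agatston_score(lesions_ctac, ctac_basis),
    volume_csct = volume_score(lesions_csct, csct_clean),
    volume_ctac = volume_score(lesions_ctac, ctac_basis),
    centerlines = fine$centerlines,
    heart_mask = fine$heart_mask
  )
}

# Truth follows the standard scoring convention: a lone supra-threshold
# voxel is not a scoreable lesion fragment. Drop 1-voxel 26-connected
# satellites from a gated voxel set.
drop_singleton_satellites <- function(idx) {
  if (nrow(idx) < 2L) return(idx[integer(), , drop = FALSE])
  lo <- apply(idx, 2, min)
  dims <- apply(idx, 2, max) - lo + 1L
  rel <- sweep(idx, 2, lo - 1L)
  fg <- array(FALSE, dims)
  fg[rel] <- TRUE
  labels <- .cc_label3d(as.vector(fg), as.integer(dims), 26L)
  lab_at <- array(labels, dims)[rel]
  sizes <- tabulate(lab_at)
  idx[sizes[lab_at] >= 2L, , drop = FALSE]
}

# (z,y,x) indices of supra-130 voxels inside an anisotropic gate around a
# lesion centre: |dz| <= r + margin_z, in-plane distance <= r + margin_xy.
supra_voxels_near <- function(vol, center, r, margin_z, margin_xy) {
  d <- dim(vol$data)
  rad <- c(r + margin_z, r + margin_xy, r + margin_xy)
  rng <- function(axis) {
    lo <- max(1L, floor((center[axis] - rad[axis] - vol$origin[axis]) /
                          vol$spacing[axis]) + 1L)
    hi <- min(d[axis], ceiling((center[axis] + rad[axis] - vol$origin[axis]) /
                                 vol$spacing[axis]) + 1L)
    if (lo > hi) integer() else lo:hi
  }
  zi <- rng(1); yi <- rng(2); xi <- rng(3)
  if (!length(zi) || !length(yi) || !length(xi))
    return(matrix(integer(), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  idx <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
  pos <- sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  dz <- abs(pos[, 1] - center[1])
  dxy <- sqrt((pos[, 2] - center[2])^2 + (pos[, 3] - center[3])^2)
  keep <- dz <= rad[1] & dxy <= rad[2] & vol$data[idx] >= 130
  idx[keep, , drop = FALSE]
}

#' Template carrying the phantom's true coronary geometry
#'
#' Builds a [coronary_template] from a lesion-free, noise-free rendering of
#' the canonical phantom anatomy: the template volume, the analytic heart
#' mask and the true centerlines.
#'
#' @param spec optional [phantom_spec]; defaults to the canonical anatomy.
#' @return A [coronary_template].
#' @export
phantom_template <- function(spec = phantom_spec(noise_sd_csct = 0,
                                                 noise_sd_ctac = 0)) {
  spec$lesions <- empty_lesion_table()
  spec$aorta_calcs <- empty_aorta_table()
  fine <- render_fine(spec)
  vol <- ct_volume(fine$data, fine$grid$spacing, fine$grid$origin)
  coronary_template(vol, voxel_mask(fine$heart_mask, vol), fine$centerlines)
}

#' Generate a cohort of synthetic patients
#'
#' Draws per-patient phantom specs from fixed parameter ranges with a
#' per-patient seed derived from `seed`, producing paired scans, ground
#' truth, and a per-patient/scan-type score table. A configurable fraction
#' of patients has no coronary calcium at all. Lesion centres are kept at
#' least 6 mm apart (surface to surface) so that distinct lesions never
#' merge under thresholding.
#'
#' @param n_patients cohort size (>= 1).
#' @param seed master seed; fixes everything.
#' @param zero_cac_fraction fraction of patients with zero coronary calcium
#'   (default 0.1).
#' @param lesion_count_range integer range of lesion counts for CAC-positive
#'   patients (default 1 to 6).
#' @param radius_range_mm,peak_range_hu uniform sampling ranges for lesion
#'   size and peak attenuation. Defaults 2.2-3.5 mm and 400-800 HU: lesions
#'   large and dense enough to remain conspicuous on a 3 mm / 1.35 mm
#'   non-gated grid.
#' @param ... further arguments passed to [phantom_spec] (noise, blur).
#' @return List of class `phantom_cohort`: `patients` (each with
#'   `patient_id`, `spec`, `csct`, `ctac`, `truth`), `template`, and
#'   `scores` (data frame: `patient_id`, `scan_type`, `agatston`,
#'   `volume_mm3`, `n_lesions`, `category`).
#' @export
generate_phantom_cohort <- function(n_patients, seed = 1,
                                    zero_cac_fraction = 0.1,
                                    lesion_count_range = c(1, 6),
                                    radius_range_mm = c(2.2, 3.5),
                                    peak_range_hu = c(400, 800), ...) {
  if (n_patients < 1) stop("need at least one patient")
  draws <- withr_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      list(seed = sample.int(2^31 - 2, 1),
           zero = runif(1) < zero_cac_fraction,
           heart_jitter = c(runif(1, -2, 2), runif(1, -3, 3), runif(1, -3, 3)),
           heart_scale = runif(1, 0.94, 1.06),
           n_lesions = sample(lesion_count_range[1]:lesion_count_range[2], 1),
           n_aorta = sample(0:3, 1),
           u = runif(64))
    })
  })
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    dr <- draws[[i]]
    lesions <- empty_lesion_table()
    if (!dr$zero) {
      lesions <- draw_lesions(dr$n_lesions, dr$u, radius_range_mm,
                              peak_range_hu)
    }
    aorta_calcs <- empty_aorta_table()
    if (dr$n_aorta > 0) {
      u2 <- dr$u[33:64]
      aorta_calcs <- data.frame(
        z_mm = 6 + 36 * u2[seq_len(dr$n_aorta)],
        angle_deg = -45 + 90 * u2[4 + seq_len(dr$n_aorta)],
        radius_mm = 1.5 + 1.5 * u2[8 + seq_len(dr$n_aorta)],
        peak_hu = 300 + 400 * u2[12 + seq_len(dr$n_aorta)]
      )
    }
    spec <- phantom_spec(
      lesions = lesions, aorta_calcs = aorta_calcs,
      heart_center = c(24, 30, 32) + dr$heart_jitter,
      heart_axes = c(20, 19, 17) * dr$heart_scale,
      seed = dr$seed, ...
    )
    pair <- generate_phantom_pair(spec)
    patients[[i]] <- list(patient_id = sprintf("P%03d", i), spec = spec,
                          csct = pair$csct, ctac = pair$ctac,
                          truth = pair$truth, clean = pair$clean)
  }
  scores <- do.call(rbind, lapply(patients, function(p) {
    data.frame(
      patient_id = p$patient_id,
      scan_type = c("CSCT", "CTAC"),
      agatston = c(p$truth$agatston_csct, p$truth$agatston_ctac),
      volume_mm3 = c(p$truth$volume_csct, p$truth$volume_ctac),
      n_lesions = c(length(p$truth$lesions_csct), length(p$truth$lesions_ctac)),
      category = risk_category(c(p$truth$agatston_csct, p$truth$agatston_ctac)),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(patients = patients, template = phantom_template(),
                 scores = scores, seed = seed),
            class = "phantom_cohort")
}

# Rejection-sample lesion placements with pairwise centre separation
# >= r_i + r_j + 6 mm, using the pre-drawn uniform deviates in `u`.
draw_lesions <- function(n, u, radius_range, peak_range) {
  arteries <- c("RCA", "LAD", "LCX")
  spec0 <- phantom_spec()
  cls <- phantom_centerlines(spec0)
  out <- empty_lesion_table()
  centers <- list()
  ui <- 1
  nxt <- function() {
    v <- u[((ui - 1) %% length(u)) + 1]
    ui <<- ui + 1
    v
  }
  attempts <- 0
  while (nrow(out) < n && attempts < 60) {
    attempts <- attempts + 1
    artery <- arteries[1 + floor(nxt() * 3) %% 3]
    t <- 0.1 + 0.8 * nxt()
    r <- radius_range[1] + diff(radius_range) * nxt()
    peak <- peak_range[1] + diff(peak_range) * nxt()
    ctr <- polyline_point(cls[[artery]], t)
    ok <- TRUE
    for (j in seq_along(centers)) {
      if (sqrt(sum((ctr - centers[[j]]$ctr)^2)) <
          r + centers[[j]]$r + 6) { ok <- FALSE; break }
    }
    if (!ok) next
    centers[[length(centers) + 1L]] <- list(ctr = ctr, r = r)
    out <- rbind(out, data.frame(artery = artery, t = t, radius_mm = r,
                                 peak_hu = peak))
  }
  out
}

#' Write a phantom cohort to disk
#'
#' Writes, per patient, the CSCT and CTAC scans (NIfTI), the union
#' ground-truth lesion mask on the CTAC grid (NIfTI, uint8), plus the
#' template centerlines (JSON) and the truth score table
#' (`truth_scores.csv`).
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    save_volume(p$ctac, file.path(dir, paste0(p$patient_id, "_ctac.nii.gz")))
    save_volume(p$csct, file.path(dir, paste0(p$patient_id, "_csct.nii.gz")))
    save_volume(candidates_to_mask(p$truth$lesions_ctac, p$ctac),
                file.path(dir, paste0(p$patient_id, "_truth_ctac.nii.gz")))
  }
  write_centerlines(cohort$template$centerlines,
                    file.path(dir, "template_centerlines.json"))
  save_volume(cohort$template$volume, file.path(dir, "template_volume.nii.gz"))
  save_volume(cohort$template$heart_mask,
              file.path(dir, "template_heart_mask.nii.gz"))
  write.csv(cohort$scores, file.path(dir, "truth_scores.csv"),
            row.names = FALSE)
  invisible(dir)
}
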