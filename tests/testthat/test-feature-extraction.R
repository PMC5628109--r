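make_candidate <- function(v, threshold = 130) {
  cand <- extract_candidates(v, threshold)
  expect_length(cand, 1)
  cand[[1]]
}

test_that("shape eigenratios recover line, cube and plane geometry", {
  v <- make_volume(c(9, 9, 9), spacing = c(1, 1, 1))
  v$data[5, 5, 3:7] <- 200                   # 5 collinear voxels
  expect_equal(shape_features(make_candidate(v), v$spacing),
               c(r21 = 0, r31 = 0, r32 = 0))

  v2 <- make_volume(c(9, 9, 9), spacing = c(1, 1, 1))
  v2$data[4:6, 4:6, 4:6] <- 200              # symmetric cube
  expect_equal(shape_features(make_candidate(v2), v2$spacing),
               c(r21 = 1, r31 = 1, r32 = 1))

  v3 <- make_volume(c(9, 9, 9), spacing = c(1, 1, 1))
  v3$data[5, 4:6, 4:6] <- 200                # 3x3x1 plane
  expect_equal(shape_features(make_candidate(v3), v3$spacing),
               c(r21 = 1, r31 = 0, r32 = 0))
})

test_that("shape ratios are invariant to 90-degree rotation and uniform scaling", {
  v <- make_volume(c(9, 9, 9), spacing = c(1, 1, 1))
  v$data[4:5, 3:6, 4] <- 200                 # 2x4x1 slab
  f1 <- shape_features(make_candidate(v), v$spacing)
  vr <- make_volume(c(9, 9, 9), spacing = c(1, 1, 1))
  vr$data[4:5, 4, 3:6] <- 200                # rotated 90 degrees about z. . . y<->x
  expect_equal(shape_features(make_candidate(vr), vr$spacing), f1)
  expect_equal(shape_features(make_candidate(v), v$spacing * 2.5), f1)
})

test_that("intensity statistics are exact on constant lesions", {
  # constant 200 HU everywhere: statistics and smoothing are both exact
  v <- make_volume(c(5, 7, 7), spacing = c(1, 1, 1), fill = 200)
  cand <- extract_candidates(v)[[1]]
  f <- intensity_features(cand, v, scales = c(1, 2))
  expect_equal(unname(f["hu_max"]), 200)
  expect_equal(unname(f["hu_mean"]), 200)
  expect_equal(unname(f["hu_sd"]), 0)
  # smoothing preserves a constant field exactly (replicate padding)
  expect_equal(unname(f["hu_s1_max"]), 200)
  expect_equal(unname(f["hu_s2_mean"]), 200)
  expect_error(intensity_features(cand, v, scales = c(-1)), "positive|scale")
})

test_that("smoothed spike features match a dense convolution oracle", {
  v <- make_volume(c(7, 7, 7), spacing = c(1.5, 1, 1), fill = -50)
  v$data[4, 4, 4] <- 500
  sm <- gaussian_smooth(v, 2)
  oracle <- dense_gaussian_oracle(v, 2)
  expect_equal(sm$data, oracle, tolerance = 1e-10)
  expect_lt(max(sm$data), 500)
  expect_gt(max(sm$data), -50)
})

test_that("self-registration returns the identity transform", {
  templ <- phantom_template()
  tree <- estimate_coronary_tree(templ$volume, templ)
  expect_equal(tree$transform$scale, c(z = 1, y = 1, x = 1), tolerance = 1e-12)
  expect_equal(unname(tree$transform$shift), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(tree$centerlines$LAD, templ$centerlines$LAD, tolerance = 1e-9)
})

test_that("a translated subject moves the centerlines by the same vector", {
  templ <- phantom_template()
  shift <- c(0, 10, 0)
  subj <- ct_volume(templ$volume$data, templ$volume$spacing,
                    templ$volume$origin + shift)
  tree <- estimate_coronary_tree(subj, templ)
  moved <- templ$centerlines$RCA + matrix(shift, nrow(templ$centerlines$RCA),
                                          3, byrow = TRUE)
  # recovery within one coarse (CTAC) voxel
  expect_lt(max(abs(tree$centerlines$RCA - moved)), 1.35)
})

test_that("uniform subjects cannot be registered", {
  templ <- phantom_template()
  flat <- make_volume(c(8, 16, 16), fill = -200)
  expect_error(estimate_coronary_tree(flat, templ), "heart-like")
})

test_that("distance maps vanish on centerline vertices and match analytic distances", {
  templ <- phantom_template()
  spec <- phantom_spec(noise_sd_csct = 0, noise_sd_ctac = 0)
  pair <- generate_phantom_pair(spec)
  tree <- estimate_coronary_tree(pair$ctac, templ)
  dm <- distance_map(tree, pair$ctac, "RCA")
  vox <- round((tree$centerlines$RCA[5, ] - pair$ctac$origin) /
                 pair$ctac$spacing) + 1
  # the voxel containing a vertex is within half a voxel diagonal of it
  expect_lt(dm[vox[1], vox[2], vox[3]], sqrt(sum((pair$ctac$spacing / 2)^2)))
  expect_true(all(dm >= 0))
})

test_that("location features give exact point-to-segment distances", {
  # straight synthetic centerline along x at y = 10, z = 6; centroid 5 mm away
  v <- make_volume(c(5, 20, 20), spacing = c(3, 1.35, 1.35))
  grid <- list(dim = dim(v$data), spacing = v$spacing, origin = v$origin)
  cl <- list(RCA = cbind(6, 10, c(0, 27)),
             LAD = cbind(6, 24, c(0, 27)),
             LCX = cbind(12, 24, c(0, 27)))
  tree <- structure(list(centerlines = cl, heart_centroid_mm = c(6, 12, 13),
                         heart_halfext_mm = c(6, 12, 13),
                         transform = list(scale = c(1, 1, 1),
                                          shift = c(0, 0, 0)),
                         grid = grid),
                    class = "coronary_tree")
  cand <- list(centroid_mm = c(6, 15, 13), voxel_indices = cbind(2, 10, 10),
               n_voxels = 1L)
  f <- location_features(cand, tree)
  expect_equal(unname(f["dist_rca_mm"]), 5)
  expect_equal(unname(f["dist_tree_mm"]), 5)
  expect_gt(f[["dist_lad_mm"]], f[["dist_rca_mm"]])
  # heart-centred coordinates of the heart centroid itself are (0,0,0)
  ctr <- list(centroid_mm = c(6, 12, 13))
  expect_equal(unname(location_features(ctr, tree)[c("pos_z", "pos_y", "pos_x")]),
               c(0, 0, 0))
  out <- list(centroid_mm = c(60, 15, 13))
  expect_error(location_features(out, tree), "outside")
})

test_that("featurize is deterministic, order-equivariant and schema-stable", {
  spec <- phantom_spec(lesions = data.frame(artery = c("LAD", "RCA"),
                                            t = c(0.3, 0.6),
                                            radius_mm = c(2.5, 3),
                                            peak_hu = c(500, 700)),
                       noise_sd_csct = 0, noise_sd_ctac = 0, seed = 5)
  pair <- generate_phantom_pair(spec)
  templ <- phantom_template()
  tree <- estimate_coronary_tree(pair$ctac, templ)
  cand <- extract_candidates(pair$ctac)
  cfg <- feature_config()
  f1 <- featurize(cand, pair$ctac, tree, cfg)
  f2 <- featurize(cand, pair$ctac, tree, cfg)
  expect_identical(f1, f2)
  expect_identical(colnames(f1), cacscore:::feature_names(cfg))
  expect_true(all(is.finite(f1)))
  expect_true(all(f1[, c("shape.r21", "shape.r31", "shape.r32")] >= 0 &
                    f1[, c("shape.r21", "shape.r31", "shape.r32")] <= 1))
  perm <- rev(seq_along(cand))
  f3 <- featurize(cand[perm], pair$ctac, tree, cfg)
  expect_equal(f3, f1[perm, , drop = FALSE], ignore_attr = TRUE)
  # empty candidate list -> 0-row matrix with the full schema
  f0 <- featurize(list(), pair$ctac, tree, cfg)
  expect_identical(nrow(f0), 0L)
  expect_identical(colnames(f0), colnames(f1))
})
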