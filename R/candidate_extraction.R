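#' Extract calcification candidates by thresholding and 3D component labeling
#'
#' Identifies potential coronary-calcium lesions as maximal 3D connected
#' components of voxels at or above an attenuation threshold (inclusive,
#' default the conventional 130 HU). Components of exactly one voxel are
#' discarded: at CTAC noise levels a single supra-threshold voxel cannot be
#' told apart from noise.
#'
#' Candidates are ordered by decreasing volume; ties are broken by the
#' lexicographically smallest `(z, y, x)` member voxel. Ids are `1..n` in that
#' order.
#'
#' @param volume a [ct_volume].
#' @param threshold HU threshold (inclusive), `>= -1024`. Default 130.
#' @param connectivity 3D neighborhood order: 6 (faces), 18 (faces+edges) or
#'   26 (full). Default 26, which merges motion-smeared fragments.
#' @return A list of `lesion_candidate` objects. Each has `id`,
#'   `voxel_indices` (n x 3 integer matrix of 1-based `(z, y, x)` indices),
#'   `n_voxels`, `volume_mm3`, `max_hu`, `centroid_mm` (physical `(z, y, x)`),
#'   and `per_slice` (data frame `z`, `n_voxels`, `max_hu`).
#' @examples
#' v <- ct_volume(array(0, c(3, 4, 4)), c(3, 1.35, 1.35))
#' v$data[2, 2, 2:3] <- 140
#' cand <- extract_candidates(v)
#' cand[[1]]$volume_mm3  # 2 * 3 * 1.35 * 1.35
#' @export
extract_candidates <- function(volume, threshold = 130, connectivity = 26) {
  stopifnot(inherits(volume, "ct_volume"))
  if (length(volume$data) == 0L) stop("empty volume")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < -1024)
    stop("`threshold` must be a single HU value >= -1024")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be one of 6, 18, 26")

  dims <- dim(volume$data)
  fg <- volume$data >= threshold
  labels <- .cc_label3d(as.vector(fg), as.integer(dims), as.integer(connectivity))
  keep <- labels != 0L
  if (!any(keep)) return(list())

  lin <- which(keep)
  lab <- labels[keep]
  sizes <- tabulate(lab)
  multi <- which(sizes >= 2L)          # single-voxel components dropped
  if (length(multi) == 0L) return(list())

  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  z <- ((lin - 1L) %% nz) + 1L
  y <- (((lin - 1L) %/% nz) %% ny) + 1L
  x <- ((lin - 1L) %/% (nz * ny)) + 1L
  hu <- volume$data[lin]
  # scan-order key: lexicographic on (z, y, x)
  key <- ((z - 1) * ny + (y - 1)) * nx + (x - 1)

  comps <- lapply(multi, function(l) {
    sel <- lab == l
    idx <- cbind(z = z[sel], y = y[sel], x = x[sel])
    ord <- order(key[sel])
    list(idx = idx[ord, , drop = FALSE], hu = hu[sel][ord],
         first_key = min(key[sel]))
  })
  n_vox <- vapply(comps, function(cc) nrow(cc$idx), integer(1))
  first <- vapply(comps, function(cc) cc$first_key, numeric(1))
  ord <- order(-n_vox, first)

  voxel_mm3 <- prod(volume$spacing)
  out <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    cc <- comps[[ord[i]]]
    out[[i]] <- new_lesion_candidate(i, cc$idx, cc$hu, volume)
  }
  out
}

new_lesion_candidate <- function(id, idx, hu, volume) {
  sp <- volume$spacing
  centroid_mm <- volume$origin + (colMeans(idx) - 1) * sp
  zs <- sort(unique(idx[, 1]))
  per_slice <- data.frame(
    z = zs,
    n_voxels = vapply(zs, function(s) sum(idx[, 1] == s), integer(1)),
    max_hu = vapply(zs, function(s) max(hu[idx[, 1] == s]), numeric(1))
  )
  structure(list(
    id = id,
    voxel_indices = idx,
    n_voxels = nrow(idx),
    volume_mm3 = nrow(idx) * prod(sp),
    max_hu = max(hu),
    centroid_mm = unname(centroid_mm),
    per_slice = per_slice
  ), class = "lesion_candidate")
}

#' @export
print.lesion_candidate <- function(x, ...) {
  cat(sprintf("<lesion_candidate #%d> %d voxels, %.3f mm3, max %d HU, %d slice(s)\n",
              x$id, x$n_voxels, x$volume_mm3, round(x$max_hu),
              nrow(x$per_slice)))
  invisible(x)
}

#' Tabulate candidates for export
#'
#' @param candidates list of `lesion_candidate` from [extract_candidates].
#' @return A data frame with columns `id`, `n_voxels`, `volume_mm3`, `max_hu`,
#'   `centroid_z_mm`, `centroid_y_mm`, `centroid_x_mm`, suitable for
#'   `write.csv`.
#' @export
candidate_table <- function(candidates) {
  if (length(candidates) == 0L)
    return(data.frame(id = integer(), n_voxels = integer(),
                      volume_mm3 = numeric(), max_hu = numeric(),
                      centroid_z_mm = numeric(), centroid_y_mm = numeric(),
                      centroid_x_mm = numeric()))
  do.call(rbind, lapply(candidates, function(cc) {
    data.frame(id = cc$id, n_voxels = cc$n_voxels, volume_mm3 = cc$volume_mm3,
               max_hu = cc$max_hu, centroid_z_mm = cc$centroid_mm[1],
               centroid_y_mm = cc$centroid_mm[2],
               centroid_x_mm = cc$centroid_mm[3])
  }))
}

#' Union mask of a set of candidates
#'
#' @param candidates list of `lesion_candidate`.
#' @param volume the parent [ct_volume].
#' @return A [voxel_mask] marking every member voxel.
#' @export
candidates_to_mask <- function(candidates, volume) {
  m <- array(FALSE, dim(volume$data))
  for (cc in candidates) m[cc$voxel_indices] <- TRUE
  voxel_mask(m, volume)
}
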