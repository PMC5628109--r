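#' Agatston score of a set of lesions
#'
#' Classical per-lesion, per-axial-slice score: for each lesion and each slice
#' it occupies, the calcified area (voxel count x in-plane pixel area, mm^2)
#' is multiplied by a weight determined by the slice's peak attenuation
#' (1 for 130-199 HU, 2 for 200-299, 3 for 300-399, 4 for >= 400) and summed.
#' No rounding is applied, so sub-mm^2 pixels yield fractional scores.
#'
#' @param lesions list of `lesion_candidate` (see [extract_candidates]),
#'   extracted from `volume` at the 130 HU threshold.
#' @param volume the [ct_volume] the lesions were extracted from.
#' @return Non-negative numeric score (dimensionless).
#' @examples
#' v <- ct_volume(array(0, c(2, 4, 4)), c(3, 1.35, 1.35))
#' v$data[1, 2, 2:3] <- c(250, 240)
#' agatston_score(extract_candidates(v), v)  # 2 * 1.8225 * 2
#' @export
agatston_score <- function(lesions, volume) {
  stopifnot(inherits(volume, "ct_volume"))
  pixel_area <- volume$spacing[2] * volume$spacing[3]
  total <- 0
  for (les in lesions) {
    check_lesion_in_volume(les, volume)
    hu <- volume$data[les$voxel_indices]
    zs <- les$voxel_indices[, 1]
    for (s in unique(zs)) {
      in_slice <- zs == s
      w <- agatston_weight(max(hu[in_slice]))
      total <- total + sum(in_slice) * pixel_area * w
    }
  }
  total
}

agatston_weight <- function(max_hu) {
  if (max_hu >= 400) 4
  else if (max_hu >= 300) 3
  else if (max_hu >= 200) 2
  else if (max_hu >= 130) 1
  else 0
}

check_lesion_in_volume <- function(lesion, volume) {
  idx <- lesion$voxel_indices
  d <- dim(volume$data)
  if (any(idx < 1L) || any(idx[, 1] > d[1]) || any(idx[, 2] > d[2]) ||
      any(idx[, 3] > d[3]))
    stop("lesion voxel outside volume")
  invisible(TRUE)
}

#' Calcium volume score
#'
#' Total physical volume (mm^3) of all member voxels over all lesions.
#'
#' @inheritParams agatston_score
#' @return Volume in mm^3.
#' @export
volume_score <- function(lesions, volume) {
  stopifnot(inherits(volume, "ct_volume"))
  for (les in lesions) check_lesion_in_volume(les, volume)
  vox <- prod(volume$spacing)
  sum(vapply(lesions, function(l) nrow(l$voxel_indices), integer(1))) * vox
}

#' Cardiovascular risk category from an Agatston score
#'
#' The five standard ordinal categories on the Agatston scale: level 1 for a
#' score of exactly 0, then the half-open intervals (0, 10], (10, 100],
#' (100, 400] and (400, Inf) for levels 2-5. Fractional scores are allowed;
#' the zero/positive distinction is preserved exactly.
#'
#' @param agatston numeric vector of non-negative scores.
#' @return Integer vector of levels 1-5.
#' @examples
#' risk_category(c(0, 5, 10.5, 400, 400.01))
#' @export
risk_category <- function(agatston) {
  if (any(!is.finite(agatston)) || any(agatston < 0))
    stop("Agatston scores must be finite and >= 0")
  findInterval(agatston, c(0, 10, 100, 400), left.open = TRUE) + 1L
}

#' Risk-category boundaries
#'
#' @return Data frame of levels, labels and score intervals.
#' @export
risk_category_table <- function() {
  data.frame(level = 1:5,
             label = c("very low", "low", "intermediate", "high", "very high"),
             lower = c(0, 0, 10, 100, 400),
             upper = c(0, 10, 100, 400, Inf))
}

#' Rank-based risk-category assignment across scan types
#'
#' When two scan types systematically disagree in absolute score (e.g.
#' partial-volume losses on a coarse non-gated grid), patient ranking is more
#' stable than the score itself. This assignment gives the test cohort the
#' same category counts as the reference categorization: test patients are
#' sorted by ascending score and fill the reference quotas from the lowest
#' category upward, with two rules:
#' * patients with score exactly 0 always receive level 1, even if this
#'   overflows the level-1 quota;
#' * a group of tied (equal, nonzero) scores all receive the single category
#'   holding the majority of the group's quota slots, the lower category on a
#'   split majority.
#'
#' @param reference_categories integer vector of levels 1-5, one per patient,
#'   defining the quotas.
#' @param test_scores numeric vector of scores in the same patient order.
#' @return Integer vector of assigned levels, one per patient.
#' @examples
#' rank_assign(c(1, 1, 2, 3), c(0, 0, 7, 320))
#' @export
rank_assign <- function(reference_categories, test_scores) {
  if (length(reference_categories) != length(test_scores))
    stop("reference and test cohorts must have the same length")
  n <- length(test_scores)
  if (n == 0L) return(integer())
  if (any(!reference_categories %in% 1:5))
    stop("reference categories must be levels 1-5")
  if (any(!is.finite(test_scores)) || any(test_scores < 0))
    stop("test scores must be finite and >= 0")
  quotas <- tabulate(reference_categories, nbins = 5L)
  slots <- rep.int(1:5, quotas)        # category of each ascending rank slot

  ord <- order(test_scores)            # stable
  assigned <- integer(n)
  pos <- 1L
  while (pos <= n) {
    sc <- test_scores[ord[pos]]
    grp_end <- pos
    while (grp_end < n && test_scores[ord[grp_end + 1L]] == sc)
      grp_end <- grp_end + 1L
    members <- ord[pos:grp_end]
    if (sc == 0) {
      assigned[members] <- 1L
    } else {
      grp_slots <- slots[pos:grp_end]
      tab <- tabulate(grp_slots, nbins = 5L)
      assigned[members] <- which.max(tab)  # lower category on split majority
    }
    pos <- grp_end + 1L
  }
  assigned
}
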