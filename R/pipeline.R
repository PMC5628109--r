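#' Pipeline run configuration
#'
#' Collects every tunable constant of the scoring pipeline in one place.
#' Defaults follow standard clinical calcium-scoring practice: 130 HU
#' threshold, full 26-neighborhood, an ensemble of 250 extremely randomized
#' trees with a 0.5 decision threshold, and tenfold patient-level
#' cross-validation.
#'
#' @param threshold_hu candidate extraction threshold (HU).
#' @param connectivity 6, 18 or 26.
#' @param scales Gaussian scales (mm) for intensity features.
#' @param n_trees ensemble size.
#' @param decision_threshold CAC probability cutoff.
#' @param n_folds cross-validation folds.
#' @param seed master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(threshold_hu = 130, connectivity = 26,
                       scales = c(1, 2, 4), n_trees = 250,
                       decision_threshold = 0.5, n_folds = 10, seed = 1) {
  cfg <- list(threshold_hu = threshold_hu, connectivity = connectivity,
              scales = scales, n_trees = n_trees,
              decision_threshold = decision_threshold, n_folds = n_folds,
              seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Run the full scoring experiment on a phantom cohort
#'
#' Executes the whole pipeline on the CTAC scans of a cohort: candidate
#' extraction, coronary-tree estimation from the template, feature
#' computation, reference labeling by overlap with the ground-truth masks,
#' patient-level cross-validated classification, Agatston/volume scoring of
#' the predicted calcium, risk categorization, and all evaluation
#' statistics (confusion matrix and weighted kappa / accuracy of automatic
#' vs reference CTAC categories, ICC of the scores, per-scan detection
#' metrics, and rank-based agreement of automatic CTAC scores with the
#' reference CSCT categorization).
#'
#' @param cohort a `phantom_cohort` from [generate_phantom_cohort], or a
#'   directory written by [write_phantom_cohort].
#' @param config a [run_config].
#' @return List of class `cac_experiment`: `scores` (per-patient data
#'   frame), `candidates` (per-candidate out-of-fold results), `agreement`
#'   (kappa + accuracy vs the CTAC reference), `rank_agreement` (vs the
#'   CSCT reference after rank assignment), `icc`, `detection`, `config`.
#' @export
run_experiment <- function(cohort, config = run_config()) {
  if (is.character(cohort)) cohort <- load_phantom_cohort(cohort)
  stopifnot(inherits(cohort, "phantom_cohort"))
  fcfg <- feature_config(config$scales)

  per_patient <- lapply(cohort$patients, function(p) {
    cand <- extract_candidates(p$ctac, config$threshold_hu,
                               config$connectivity)
    tree <- estimate_coronary_tree(p$ctac, cohort$template)
    feats <- featurize(cand, p$ctac, tree, fcfg)
    truth_lin <- unlist(lapply(p$truth$lesions_ctac, function(l)
      lin_index(l$voxel_indices, dim(p$ctac$data))), use.names = FALSE)
    labels <- vapply(cand, function(cc) {
      if (any(lin_index(cc$voxel_indices, dim(p$ctac$data)) %in% truth_lin))
        "CAC" else "background"
    }, character(1))
    list(patient_id = p$patient_id, candidates = cand, features = feats,
         labels = labels)
  })

  feats <- do.call(rbind, lapply(per_patient, `[[`, "features"))
  attr(feats, "schema") <- fcfg$schema
  labels <- unlist(lapply(per_patient, `[[`, "labels"), use.names = FALSE)
  pid <- unlist(lapply(per_patient, function(p)
    rep(p$patient_id, length(p$labels))), use.names = FALSE)

  if (length(unique(labels)) < 2L) {
    # degenerate cohort (e.g. no calcium anywhere): no classifier can be
    # trained; every candidate keeps the only observed label
    cv <- data.frame(patient_id = pid, label = labels, fold = NA_integer_,
                     proba = as.numeric(labels == "CAC"),
                     stringsAsFactors = FALSE)
  } else {
    cv <- cross_validate_cac(feats, labels, pid, n_folds = config$n_folds,
                             n_trees = config$n_trees, seed = config$seed)
  }
  cv$predicted <- cv$proba >= config$decision_threshold

  rows <- list(); detected <- list(); reference <- list(); vols <- list()
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    sel <- cv$patient_id == p$patient_id
    keep <- which(sel)[cv$predicted[sel]]
    det <- per_patient[[i]]$candidates[cv$predicted[sel]]
    auto_ag <- agatston_score(det, p$ctac)
    auto_vol <- volume_score(det, p$ctac)
    rows[[i]] <- data.frame(
      patient_id = p$patient_id,
      auto_agatston = auto_ag, auto_volume_mm3 = auto_vol,
      auto_n_lesions = length(det),
      auto_category = risk_category(auto_ag),
      ref_agatston = p$truth$agatston_ctac,
      ref_category = risk_category(p$truth$agatston_ctac),
      csct_agatston = p$truth$agatston_csct,
      csct_category = risk_category(p$truth$agatston_csct),
      stringsAsFactors = FALSE
    )
    detected[[i]] <- det
    reference[[i]] <- p$truth$lesions_ctac
    vols[[i]] <- p$ctac
  }
  scores <- do.call(rbind, rows)

  cm <- confusion_matrix(scores$ref_category, scores$auto_category)
  agreement <- list(
    confusion = cm,
    kappa = maybe(weighted_kappa(cm)),
    accuracy = maybe(category_accuracy(cm))
  )
  ranked <- rank_assign(scores$csct_category, scores$auto_agatston)
  cm_rank <- confusion_matrix(scores$csct_category, ranked)
  rank_agreement <- list(
    confusion = cm_rank,
    kappa = maybe(weighted_kappa(cm_rank)),
    accuracy = maybe(category_accuracy(cm_rank)),
    assigned = ranked
  )
  icc <- if (nrow(scores) >= 3)
    maybe(icc_absolute(cbind(scores$ref_agatston, scores$auto_agatston)))
  else NULL

  structure(list(scores = scores, candidates = cv, agreement = agreement,
                 rank_agreement = rank_agreement, icc = icc,
                 detection = detection_metrics(reference, detected, vols),
                 config = config),
            class = "cac_experiment")
}

# capture "undefined statistic" error flags instead of aborting the report
maybe <- function(expr) {
  tryCatch(expr, error = function(e) structure(list(error = conditionMessage(e)),
                                               class = "undefined_statistic"))
}

#' @export
print.cac_experiment <- function(x, ...) {
  cat("<cac_experiment>", nrow(x$scores), "patients\n")
  if (inherits(x$agreement$kappa, "agreement_result"))
    cat(sprintf("  auto vs reference CTAC: kappa %.2f, accuracy %.2f\n",
                x$agreement$kappa$kappa, x$agreement$accuracy$accuracy))
  if (inherits(x$rank_agreement$kappa, "agreement_result"))
    cat(sprintf("  rank-assigned vs CSCT:  kappa %.2f, accuracy %.2f\n",
                x$rank_agreement$kappa$kappa, x$rank_agreement$accuracy$accuracy))
  d <- x$detection
  cat(sprintf("  detection: lesion sens %.3f, volume sens %.3f, FP/scan %.2f (%.1f mm3)\n",
              d$lesion_sensitivity, d$volume_sensitivity,
              d$fp_lesions_per_scan, d$fp_volume_per_scan))
  invisible(x)
}

#' Reload a phantom cohort written by [write_phantom_cohort]
#'
#' Rebuilds the in-memory cohort structure from disk: scans, ground-truth
#' CTAC lesion masks (re-split into connected lesions), template and truth
#' scores.
#'
#' @param dir cohort directory.
#' @return A `phantom_cohort`.
#' @export
load_phantom_cohort <- function(dir) {
  score_path <- file.path(dir, "truth_scores.csv")
  if (!file.exists(score_path)) stop("not a cohort directory: ", dir)
  scores <- read.csv(score_path, stringsAsFactors = FALSE)
  ids <- unique(scores$patient_id)
  template_vol <- load_volume(file.path(dir, "template_volume.nii.gz"))
  template_mask <- load_volume(file.path(dir, "template_heart_mask.nii.gz"))
  template <- coronary_template(
    template_vol, voxel_mask(template_mask$data > 0, template_vol),
    read_centerlines(file.path(dir, "template_centerlines.json")))
  patients <- lapply(ids, function(id) {
    ctac <- load_volume(file.path(dir, paste0(id, "_ctac.nii.gz")))
    csct <- load_volume(file.path(dir, paste0(id, "_csct.nii.gz")))
    mask <- load_volume(file.path(dir, paste0(id, "_truth_ctac.nii.gz")))
    lesions <- mask_components(mask$data > 0, ctac)
    sc <- scores[scores$patient_id == id, ]
    list(patient_id = id, csct = csct, ctac = ctac,
         truth = list(
           lesions_ctac = lesions,
           agatston_ctac = sc$agatston[sc$scan_type == "CTAC"],
           agatston_csct = sc$agatston[sc$scan_type == "CSCT"],
           volume_ctac = sc$volume_mm3[sc$scan_type == "CTAC"],
           volume_csct = sc$volume_mm3[sc$scan_type == "CSCT"]))
  })
  structure(list(patients = patients, template = template, scores = scores,
                 seed = NA_integer_),
            class = "phantom_cohort")
}

# connected components of a stored truth mask (single voxels kept),
# with HU taken from the accompanying scan
mask_components <- function(fg, scan) {
  labels <- .cc_label3d(as.vector(fg), as.integer(dim(scan$data)), 26L)
  lin <- which(labels != 0L)
  if (!length(lin)) return(list())
  lab <- labels[lin]
  d <- dim(scan$data)
  z <- ((lin - 1L) %% d[1]) + 1L
  y <- (((lin - 1L) %/% d[1]) %% d[2]) + 1L
  x <- ((lin - 1L) %/% (d[1] * d[2])) + 1L
  out <- list()
  for (l in unique(lab)) {
    sel <- lab == l
    idx <- cbind(z = z[sel], y = y[sel], x = x[sel])
    out[[length(out) + 1L]] <- new_lesion_candidate(length(out) + 1L, idx,
                                                    scan$data[idx], scan)
  }
  out
}
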