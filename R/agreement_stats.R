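#' Build a k x k confusion matrix of ordinal categories
#'
#' Rows are reference categories, columns test categories.
#'
#' @param reference,test integer vectors of levels `1..k`.
#' @param k number of ordinal categories (default 5, the CVD risk scale).
#' @return Integer `k x k` matrix of counts.
#' @export
confusion_matrix <- function(reference, test, k = 5L) {
  if (length(reference) != length(test)) stop("length mismatch")
  if (any(!reference %in% seq_len(k)) || any(!test %in% seq_len(k)))
    stop("categories must be integers in 1..k")
  m <- table(factor(reference, levels = seq_len(k)),
             factor(test, levels = seq_len(k)))
  matrix(as.integer(m), k, k, dimnames = dimnames(m))
}

check_confusion <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || nrow(m) < 2L) stop("need a square k x k matrix, k >= 2")
  if (any(m < 0) || any(m != round(m))) stop("cells must be non-negative counts")
  if (sum(m) <= 0) stop("empty confusion matrix")
  m
}

#' Weighted Cohen's kappa for ordinal agreement
#'
#' Chance-corrected agreement with disagreement penalties proportional to
#' category distance. With linear weights `w_ij = 1 - |i - j| / (k - 1)`,
#' `kappa = (Po_w - Pe_w) / (1 - Pe_w)` where `Po_w` is the weighted observed
#' proportion of agreement and `Pe_w` the weighted chance agreement from the
#' marginal products. The standard error uses the large-sample variance of
#' weighted kappa (Fleiss, Cohen & Everitt), from which a Wald 95% CI is
#' formed; the CI method is reported in the result.
#'
#' @param m confusion matrix (rows reference, columns test).
#' @param weighting `"linear"` (default) or `"quadratic"`.
#' @return List of class `agreement_result`: `kappa`, `kappa_se`,
#'   `kappa_ci95`, `n`, `weighting`, `ci_method`.
#' @examples
#' weighted_kappa(diag(10, 5))$kappa  # 1
#' @export
weighted_kappa <- function(m, weighting = c("linear", "quadratic")) {
  m <- check_confusion(m)
  weighting <- match.arg(weighting)
  k <- nrow(m)
  n <- sum(m)
  p <- m / n
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (weighting == "linear") 1 - d else 1 - d^2
  r <- rowSums(p)
  s <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, s))
  if (1 - pe < .Machine$double.eps^0.5)
    stop("weighted chance agreement is 1; kappa undefined")
  kappa <- (po - pe) / (1 - pe)
  # large-sample variance of the weighted kappa estimate
  wi <- as.vector(w %*% s)       # row-wise expected weight, \bar w_i.
  wj <- as.vector(t(w) %*% r)    # column-wise expected weight, \bar w_.j
  wbar <- outer(wi, wj, "+")
  term <- sum(p * (w - wbar * (1 - kappa))^2)
  var_k <- (term - (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  ci <- kappa + c(-1, 1) * qnorm(0.975) * se
  structure(list(kappa = kappa, kappa_se = se,
                 kappa_ci95 = pmin(pmax(ci, -1), 1), n = n,
                 weighting = weighting,
                 ci_method = "Wald, Fleiss-Cohen-Everitt large-sample SE"),
            class = "agreement_result")
}

#' Categorization accuracy with Wilson 95% interval
#'
#' Proportion of subjects on the confusion-matrix diagonal: the fraction of
#' scans on which the two methods assign the same category.
#'
#' @param m confusion matrix (rows reference, columns test).
#' @return List of class `agreement_result`: `accuracy`, `accuracy_se`,
#'   `accuracy_ci95` (Wilson score interval), `n_agree`, `n`.
#' @export
category_accuracy <- function(m) {
  m <- check_confusion(m)
  n <- sum(m)
  x <- sum(diag(m))
  acc <- x / n
  se <- sqrt(acc * (1 - acc) / n)
  z <- qnorm(0.975)
  centre <- (acc + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(acc * (1 - acc) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  structure(list(accuracy = acc, accuracy_se = se,
                 accuracy_ci95 = c(centre - half, centre + half),
                 n_agree = x, n = n, ci_method = "Wilson score"),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (!is.null(x$kappa))
    cat(sprintf("weighted kappa %.2f (95%% CI %.2f-%.2f), n = %d\n",
                x$kappa, x$kappa_ci95[1], x$kappa_ci95[2], x$n))
  if (!is.null(x$accuracy))
    cat(sprintf("accuracy %.2f (%d/%d, 95%% CI %.2f-%.2f)\n",
                x$accuracy, x$n_agree, x$n,
                x$accuracy_ci95[1], x$accuracy_ci95[2]))
  invisible(x)
}

#' Two-way mixed, absolute-agreement, single-measure ICC
#'
#' ICC(A,1) from the two-way ANOVA decomposition of an `n x k` table of
#' subjects by raters: `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with the F-based 95% confidence interval of McGraw & Wong. Penalizes
#' systematic offsets between raters, unlike consistency forms.
#'
#' @param scores numeric matrix or data frame, `n >= 3` subjects (rows) by
#'   `k >= 2` raters (columns), no missing cells.
#' @return List: `icc`, `ci95`, `n`, `k`, plus the mean squares.
#' @examples
#' icc_absolute(cbind(c(1, 3, 5), c(2, 4, 6)))$icc  # 8/9
#' @export
icc_absolute <- function(scores) {
  x <- as.matrix(scores)
  if (any(!is.finite(x))) stop("missing or non-finite cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < .Machine$double.eps)
    stop("zero variance everywhere; ICC undefined")
  icc <- (msr - mse) / denom
  ci <- icc_a1_ci(msr, msc, mse, n, k, icc)
  list(icc = icc, ci95 = ci, n = n, k = k, msr = msr, msc = msc, mse = mse)
}

# F-based interval for ICC(A,1), McGraw & Wong (1996).
icc_a1_ci <- function(msr, msc, mse, n, k, icc, alpha = 0.05) {
  if (mse <= 0) return(c(NA_real_, NA_real_))  # degenerate: no residual noise
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  c(lower, upper)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test for a systematic difference between paired scores. Zero
#' differences are dropped; tied absolute differences receive average ranks.
#' The exact null distribution is used for up to 25 informative pairs
#' without ties, and the normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y equal-length numeric vectors of paired scores.
#' @return List: `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_effective` (pairs after dropping zeros), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) stop("all paired differences are zero; test undefined")
  n <- length(d)
  rk <- rank(abs(d))                    # tied ranks averaged
  v <- sum(rk[d > 0])
  if (n <= 25L) {
    p <- exact_signed_rank_p(rk, v)
    method <- "exact"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                              correct = TRUE))
    p <- ht$p.value
    method <- "normal approximation with continuity correction"
  }
  list(statistic = v, p_value = p, n_effective = n, method = method)
}

# Exact two-sided p-value of the signed-rank statistic under random sign
# flips, by dynamic programming over achievable rank sums (average ranks are
# half-integers, so doubling gives an integer lattice). Valid with ties.
exact_signed_rank_p <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)        # counts[s + 1] = #subsets with sum s
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(ranks)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(probs[seq_len(v2 + 1L)])
  p_ge <- sum(probs[(v2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' z-comparison of two agreement estimates
#'
#' Compares two kappas (or two accuracies) by a z-score on their difference,
#' treating the samples as independent:
#' `z = (e1 - e2) / sqrt(se1^2 + se2^2)`.
#'
#' @param r1,r2 `agreement_result` objects from [weighted_kappa] or
#'   [category_accuracy].
#' @return List: `z`, `p_value` (two-sided), `difference`.
#' @export
compare_agreement <- function(r1, r2) {
  g <- function(r) {
    if (!is.null(r$kappa)) c(r$kappa, r$kappa_se)
    else if (!is.null(r$accuracy)) c(r$accuracy, r$accuracy_se)
    else stop("not an agreement_result")
  }
  a <- g(r1); b <- g(r2)
  if (!is.finite(a[2]) || !is.finite(b[2])) stop("missing standard error")
  se <- sqrt(a[2]^2 + b[2]^2)
  if (se == 0) {
    z <- 0
  } else {
    z <- (a[1] - b[1]) / se
  }
  list(z = z, p_value = 2 * pnorm(-abs(z)), difference = a[1] - b[1])
}

#' @rdname compare_agreement
#' @export
compare_kappas <- compare_agreement

#' Per-scan lesion detection metrics
#'
#' Compares detected lesions against reference lesions scan by scan. A
#' detected lesion is a true positive when it shares at least one voxel with
#' any reference lesion; a reference lesion counts as found when some
#' detected lesion overlaps it. Lesion and volume sensitivity are averaged
#' over scans with at least one reference lesion; false-positive counts and
#' volume are averaged over all scans.
#'
#' @param reference,detected lists (one element per scan) of lists of
#'   `lesion_candidate` objects on identical grids.
#' @param volumes list of the parent [ct_volume]s, one per scan (grid info
#'   for volumes in mm^3).
#' @return List: `lesion_sensitivity`, `volume_sensitivity`,
#'   `fp_lesions_per_scan`, `fp_volume_per_scan`, `n_scans`,
#'   `n_scans_with_cac`.
#' @export
detection_metrics <- function(reference, detected, volumes) {
  if (length(reference) != length(detected) ||
      length(reference) != length(volumes))
    stop("reference, detected and volumes must have one element per scan")
  sens_l <- c(); sens_v <- c(); fp_n <- c(); fp_v <- c()
  for (i in seq_along(reference)) {
    vol <- volumes[[i]]
    dims <- dim(vol$data)
    vox_mm3 <- prod(vol$spacing)
    ref_lin <- lapply(reference[[i]], function(l) lin_index(l$voxel_indices, dims))
    det_lin <- lapply(detected[[i]], function(l) lin_index(l$voxel_indices, dims))
    check_grid_fit(reference[[i]], detected[[i]], dims)
    ref_all <- unlist(ref_lin, use.names = FALSE)
    tp_det <- vapply(det_lin, function(v) any(v %in% ref_all), logical(1))
    if (length(ref_lin) > 0L) {
      det_all <- unlist(det_lin, use.names = FALSE)
      found <- vapply(ref_lin, function(v) any(v %in% det_all), logical(1))
      sens_l <- c(sens_l, mean(found))
      sens_v <- c(sens_v, length(intersect(ref_all, det_all)) / length(ref_all))
    }
    fp_lin <- unlist(det_lin[!tp_det], use.names = FALSE)
    fp_n <- c(fp_n, sum(!tp_det))
    fp_v <- c(fp_v, length(fp_lin) * vox_mm3)
  }
  list(lesion_sensitivity = if (length(sens_l)) mean(sens_l) else NA_real_,
       volume_sensitivity = if (length(sens_v)) mean(sens_v) else NA_real_,
       fp_lesions_per_scan = mean(fp_n),
       fp_volume_per_scan = mean(fp_v),
       n_scans = length(reference),
       n_scans_with_cac = length(sens_l))
}

lin_index <- function(idx, dims) {
  as.integer(idx[, 1] + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1)))
}

check_grid_fit <- function(ref, det, dims) {
  for (l in c(ref, det)) {
    if (any(l$voxel_indices < 1L) || any(l$voxel_indices[, 1] > dims[1]) ||
        any(l$voxel_indices[, 2] > dims[2]) || any(l$voxel_indices[, 3] > dims[3]))
      stop("lesion voxel indices do not fit the scan grid")
  }
  invisible(TRUE)
}

#' Worked-example risk-categorization tables
#'
#' Six published 5 x 5 confusion matrices of CVD risk categories from a
#' 128-patient myocardial-perfusion PET/CT cohort, comparing manual and
#' automatic calcium scoring on attenuation-correction CT (rest and stress)
#' and dedicated calcium-scoring CT. Bundled as worked examples for the
#' agreement statistics.
#'
#' @return Named list of six integer matrices:
#'   `ctac_rest_manual_vs_auto`, `ctac_stress_manual_vs_auto`,
#'   `csct_vs_ctac_rest_manual`, `csct_vs_ctac_rest_auto`,
#'   `csct_vs_ctac_stress_manual`, `csct_vs_ctac_stress_auto`.
#'   Rows are the reference categorization, columns the test.
#' @export
cac_example_tables <- function() {
  path <- system.file("extdata", "risk_agreement_tables.csv",
                      package = "cacscore", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$table), function(d) {
    d <- d[order(d$row), ]
    m <- as.matrix(d[, paste0("c", 1:5)])
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  })
  out[unique(df$table)]
}

#' Read / write a labeled confusion matrix as CSV
#'
#' @param m confusion matrix with optional dimnames.
#' @param path CSV path.
#' @return `read_confusion` returns an integer matrix.
#' @export
write_confusion <- function(m, path) {
  m <- check_confusion(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  check_confusion(m)
}
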