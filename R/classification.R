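#' Train the calcification classifier
#'
#' Fits an ensemble of extremely randomized trees (Extra-Trees: no bootstrap,
#' one random split threshold per candidate feature) separating true coronary
#' calcium from negative candidates (aortic calcifications, bone, noise).
#' Training is deterministic given the example order, tree count and seed.
#'
#' @param features numeric matrix (candidates x features) from [featurize],
#'   carrying its `schema` attribute.
#' @param labels factor or character vector with values `"CAC"` and
#'   `"background"`, one per row; both classes must be present.
#' @param n_trees ensemble size (default 250).
#' @param seed integer seed for the tree randomization.
#' @return Object of class `cac_classifier` wrapping the fitted ensemble,
#'   the feature schema and the training seed.
#' @export
train_cac_classifier <- function(features, labels, n_trees = 250, seed = 1) {
  schema <- attr(features, "schema")
  if (is.null(schema)) stop("feature matrix carries no schema attribute")
  labels <- as.character(labels)
  if (!all(labels %in% c("CAC", "background")))
    stop('labels must be "CAC" or "background"')
  if (nrow(features) != length(labels)) stop("one label per feature row")
  for (cls in c("CAC", "background"))
    if (!any(labels == cls))
      stop("training set has no examples of class ", cls)
  df <- as.data.frame(features)
  df$.label <- factor(labels, levels = c("background", "CAC"))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees, probability = TRUE,
    splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1, min.node.size = 1,
    respect.unordered.factors = "ignore",
    seed = seed, num.threads = 1
  )
  structure(list(forest = fit, schema = schema, n_trees = n_trees,
                 seed = seed, feature_names = colnames(features)),
            class = "cac_classifier")
}

#' Probability that each candidate is coronary calcium
#'
#' Scores candidates with a trained ensemble; the probability is the fraction
#' of trees voting CAC. A candidate is labeled CAC when the probability
#' reaches the decision threshold (0.5 by default; see
#' [classify_candidates]). Scoring refuses feature matrices produced under a
#' different schema than the model was trained on.
#'
#' @param model a `cac_classifier`.
#' @param features numeric matrix from [featurize] with matching schema.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_cac_proba <- function(model, features) {
  stopifnot(inherits(model, "cac_classifier"))
  schema <- attr(features, "schema")
  if (is.null(schema) || !identical(schema, model$schema))
    stop("feature schema mismatch: model trained on '", model$schema,
         "', got '", schema %||% "<none>", "'")
  if (nrow(features) == 0L) return(numeric())
  pred <- stats::predict(model$forest, data = as.data.frame(features),
                         num.threads = 1)
  as.vector(pred$predictions[, "CAC"])
}

#' @rdname predict_cac_proba
#' @param threshold decision threshold on the CAC probability (default 0.5).
#' @return `classify_candidates` returns a logical vector (TRUE = CAC).
#' @export
classify_candidates <- function(model, features, threshold = 0.5) {
  predict_cac_proba(model, features) >= threshold
}

#' Patient-level k-fold cross-validation
#'
#' Splits *patients* (never candidates) into `n_folds` folds of as equal
#' size as possible, trains on the complement of each fold and scores the
#' fold's candidates, so that no candidate is ever scored by a model that
#' saw its patient.
#'
#' @param features feature matrix (candidates x features) with schema.
#' @param labels `"CAC"`/`"background"` per candidate.
#' @param patient_ids patient identifier per candidate.
#' @param n_folds number of folds (default 10); must not exceed the number
#'   of distinct patients.
#' @param n_trees,seed passed to [train_cac_classifier]; the seed also fixes
#'   the patient shuffle.
#' @return Data frame with one row per candidate: `patient_id`, `label`,
#'   `fold`, `proba` (out-of-fold CAC probability).
#' @export
cross_validate_cac <- function(features, labels, patient_ids, n_folds = 10,
                               n_trees = 250, seed = 1) {
  if (nrow(features) != length(labels) ||
      nrow(features) != length(patient_ids))
    stop("features, labels and patient_ids must align")
  patients <- unique(patient_ids)
  if (length(patients) < n_folds)
    stop("need at least as many distinct patients (", length(patients),
         ") as folds (", n_folds, ")")
  shuffled <- withr_seed(seed, sample(patients))
  fold_of_patient <- setNames(rep_len(seq_len(n_folds), length(patients)),
                              shuffled)
  fold <- unname(fold_of_patient[as.character(patient_ids)])
  proba <- rep(NA_real_, nrow(features))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    if (!any(test)) next
    train_feat <- features[!test, , drop = FALSE]
    attr(train_feat, "schema") <- attr(features, "schema")
    model <- train_cac_classifier(train_feat, labels[!test],
                                  n_trees = n_trees, seed = seed + f)
    test_feat <- features[test, , drop = FALSE]
    attr(test_feat, "schema") <- attr(features, "schema")
    proba[test] <- predict_cac_proba(model, test_feat)
  }
  data.frame(patient_id = patient_ids, label = as.character(labels),
             fold = fold, proba = proba, stringsAsFactors = FALSE)
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
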