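# SVM classification of brain-metastasized vs non-brain-metastasized
# primary tumors: Gaussian-kernel SVM with balanced class weights, SVM-RFE
# feature ranking, stratified k-fold cross-validation, ROC/AUC.

#' Classifier settings
#'
#' @param cost Soft-margin regularization parameter C (default 1).
#' @param gamma Gaussian-kernel width, either the string `"scale"` (the
#'   auto-scale rule `1 / (n_features * var)` computed on the standardized
#'   training matrix) or a positive number.
#' @param class_weight `"balanced"` (weights inversely proportional to class
#'   frequencies, `n / (2 * n_c)`) or `"none"`.
#' @param seed Integer seed controlling fold assignment and any sampling.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(cost = 1, gamma = "scale",
                            class_weight = c("balanced", "none"),
                            seed = 1L) {
  class_weight <- match.arg(class_weight)
  stopifnot(cost > 0, identical(gamma, "scale") || (is.numeric(gamma) && gamma > 0))
  structure(list(cost = cost, gamma = gamma, class_weight = class_weight,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds preserving class proportions: within
#' each class, samples are shuffled and dealt round-robin, so per-fold class
#' counts differ by at most one from the balanced split.
#'
#' @param labels Class label per sample.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < k)) {
    stop("every class needs at least k = ", k, " members")
  }
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney probability that a random
#' positive-class score exceeds a random negative-class score, with half
#' credit for ties; the returned ROC points (one per distinct score
#' threshold, plus the endpoints) integrate to the same value by the
#' trapezoidal rule.
#'
#' @param scores Numeric classifier scores (larger = more positive-class).
#' @param labels Class labels; `positive_class` identifies the cases.
#' @param positive_class Label of the positive class (default: second
#'   factor level).
#' @return List with `roc` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive_class = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("both classes must be present")
  if (is.null(positive_class)) positive_class <- levels(labels)[2L]
  pos <- labels == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- c(diff(s) != 0, TRUE)            # last index of each tied block
  tpr <- cumsum(p)[keep] / n_pos
  fpr <- cumsum(!p)[keep] / n_neg
  list(roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)), auc = auc)
}

# Standardize columns using training-set statistics; constant columns are
# centred and left unscaled.
.col_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(apply = function(m) sweep(sweep(m, 2, mu, "-"), 2, sd, "/"))
}

.class_weights <- function(y, spec) {
  if (spec$class_weight == "none") return(NULL)
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

.resolve_gamma <- function(x, spec) {
  if (identical(spec$gamma, "scale")) {
    v <- mean(apply(x, 2, stats::var))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(x) * v)
  } else {
    spec$gamma
  }
}

# Fit an SVM on pre-scaled data and return a positive-class decision-value
# scorer. e1071 orients decision values toward the first label of the
# "A/B" column name; flip when that label is not the positive class.
.fit_svm <- function(x, y, spec, kernel, positive_class) {
  fit <- e1071::svm(x = x, y = y, kernel = kernel, cost = spec$cost,
                    gamma = if (kernel == "radial") .resolve_gamma(x, spec) else 1 / ncol(x),
                    class.weights = .class_weights(y, spec),
                    scale = FALSE)
  score <- function(newx) {
    pr <- stats::predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1]][1]
    if (first == positive_class) as.numeric(dv) else -as.numeric(dv)
  }
  list(fit = fit, score = score)
}

#' Rank features by SVM recursive feature elimination
#'
#' Fits a linear-kernel SVM with balanced class weights, scores each feature
#' by the squared component of the primal weight vector, eliminates the
#' lowest-scoring feature, and repeats on the survivors until one remains
#' (one feature per iteration). Rank 1 is the most contributing feature.
#' Constant features carry no weight; they are eliminated first and flagged.
#' Exact criterion ties (e.g. duplicated columns) are broken by column
#' order, the earlier column being eliminated first.
#'
#' @param x Samples-by-features numeric matrix (e.g. the transpose of an
#'   enzyme expression submatrix) with column names.
#' @param labels Class label per sample (two classes).
#' @param spec A [classifier_spec()].
#' @return Data.frame `feature`, `rank`, `constant`, ordered by rank.
#' @export
svm_rfe_rank <- function(x, labels, spec = classifier_spec()) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 features to rank")
  if (is.null(colnames(x))) stop("feature matrix needs column names")
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  positive_class <- levels(y)[2L]
  sc <- .col_scaler(x)
  xs <- sc$apply(x)
  is_const <- apply(x, 2, function(v) stats::var(v) == 0)

  eliminated <- character(0)
  surviving <- colnames(x)
  # constant features carry zero discriminative weight: drop them first
  eliminated <- c(eliminated, surviving[surviving %in% colnames(x)[is_const]])
  surviving <- setdiff(surviving, eliminated)
  if (length(surviving) == 0L) {
    surviving <- eliminated[length(eliminated)]
    eliminated <- eliminated[-length(eliminated)]
  }
  while (length(surviving) > 1L) {
    m <- .fit_svm(xs[, surviving, drop = FALSE], y, spec,
                  kernel = "linear", positive_class = positive_class)$fit
    w <- crossprod(m$coefs, m$SV)           # 1 x n_features
    crit <- as.numeric(w)^2
    worst <- surviving[which.min(crit)]
    eliminated <- c(eliminated, worst)
    surviving <- setdiff(surviving, worst)
  }
  ordered <- c(surviving, rev(eliminated))  # best first
  data.frame(feature = ordered, rank = seq_along(ordered),
             constant = is_const[ordered], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select the top-k ranked features
#'
#' @param ranking Data.frame from [svm_rfe_rank()].
#' @param k Number of features to keep (default 20).
#' @return Character vector of the `k` best-ranked feature names.
#' @export
select_top_k <- function(ranking, k = 20L) {
  if (k <= 0L || k > nrow(ranking)) {
    stop("k must be in 1..", nrow(ranking))
  }
  ranking$feature[order(ranking$rank)][seq_len(k)]
}

#' Cross-validated SVM classification
#'
#' Runs a Gaussian-kernel SVM with balanced class weights under stratified
#' k-fold cross-validation and pools the out-of-fold decision values into a
#' single ROC curve. When `select_k` is given, SVM-RFE feature selection is
#' performed over the `select_from` columns; by default the ranking is
#' recomputed inside each training fold (no information from the test fold
#' leaks into selection). Columns outside `select_from` are always kept, so
#' a combined model can mix fixed features with a selected subset.
#'
#' @param features Samples-by-features data.frame or matrix (row order
#'   matches `labels`).
#' @param labels Class label per sample (two classes).
#' @param spec A [classifier_spec()].
#' @param k_folds Number of CV folds (default 5).
#' @param positive_class Label of the positive class (default second level).
#' @param select_k Optional: number of features to keep by SVM-RFE.
#' @param select_from Columns eligible for elimination (default: all).
#' @param rfe_inside_cv If `FALSE`, rank once on the full data before CV
#'   (global pre-selection) instead of per training fold.
#' @return List of class `cv_result`: `scores` (out-of-fold, per sample),
#'   `folds`, `labels`, `roc`, `auc`, `selected` (per-fold selected feature
#'   list when selection is on).
#' @export
run_classifier <- function(features, labels, spec = classifier_spec(),
                           k_folds = 5L, positive_class = NULL,
                           select_k = NULL, select_from = NULL,
                           rfe_inside_cv = TRUE) {
  x <- as.matrix(features)
  if (anyNA(x)) stop("missing feature values")
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  if (is.null(positive_class)) positive_class <- levels(y)[2L]
  if (is.null(select_from)) select_from <- colnames(x)

  folds <- stratified_kfold(y, k = k_folds, seed = spec$seed)
  scores <- numeric(length(y))
  selected <- vector("list", k_folds)

  global_keep <- NULL
  if (!is.null(select_k) && !rfe_inside_cv) {
    rk <- svm_rfe_rank(x[, select_from, drop = FALSE], y, spec)
    global_keep <- select_top_k(rk, select_k)
  }
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    cols <- colnames(x)
    if (!is.null(select_k)) {
      keep <- if (rfe_inside_cv) {
        rk <- svm_rfe_rank(x[tr, select_from, drop = FALSE], y[tr], spec)
        select_top_k(rk, select_k)
      } else {
        global_keep
      }
      cols <- c(setdiff(colnames(x), select_from), keep)
      selected[[f]] <- keep
    }
    sc <- .col_scaler(x[tr, cols, drop = FALSE])
    m <- .fit_svm(sc$apply(x[tr, cols, drop = FALSE]), y[tr], spec,
                  kernel = "radial", positive_class = positive_class)
    scores[!tr] <- m$score(sc$apply(x[!tr, cols, drop = FALSE]))
  }
  ra <- roc_auc(scores, y, positive_class = positive_class)
  structure(list(scores = scores, folds = folds, labels = y,
                 roc = ra$roc, auc = ra$auc,
                 selected = if (is.null(select_k)) NULL else selected),
            class = "cv_result")
}
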