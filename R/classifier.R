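# Random-forest discrimination of disease vs control from CAG-summed
# abundances, with stratified 70/30 split, 10-fold cross-validation, Gini
# importance, confusion metrics, rank-based ROC/AUC, and a from-scratch
# Monte-Carlo permutation Shapley attributor.

#' Stratified train/test split
#'
#' Per class, `floor(train_fraction * n_class)` samples go to the training
#' set (so class balance is preserved within one sample) and the remainder to
#' the test set. Deterministic under `seed`.
#'
#' @param labels class labels (two classes, each with at least 2 samples).
#' @param train_fraction fraction in (0, 1), default 0.7.
#' @param seed optional integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_stratified <- function(labels, train_fraction = 0.7, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("exactly two classes required")
  if (any(table(labels) < 2)) stop("each class needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  train <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_tr <- floor(train_fraction * length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Stratified fold ids for cross-validation.
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit and evaluate a random-forest classifier
#'
#' Fits a 500-tree (by default) random forest on a stratified 70/30 split,
#' scores the held-out test set, and reports: accuracy, sensitivity and
#' specificity from the confusion matrix at probability threshold 0.5; the
#' empirical ROC curve and its rank-based AUC ([rank_auc()], computed on
#' test-set probability scores only); per-feature mean-decrease-Gini
#' importance; and stratified k-fold cross-validated accuracy (mean and sd)
#' on the training set. Remaining forest hyperparameters stay at the
#' randomForest package defaults and are echoed in `protocol`.
#'
#' @param features samples x features numeric matrix (>= 2 features).
#' @param labels two-class labels, one per row.
#' @param n_trees number of trees (default 500).
#' @param train_fraction training fraction for the stratified split.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param positive_class label treated as "disease"; default `"case"` when
#'   present, otherwise the first factor level.
#' @param prob_threshold classification threshold on the positive-class
#'   probability (default 0.5).
#' @param seed optional integer seed controlling split, forest and folds.
#' @return object of class `cag_rf`: list with `model`, `metrics` (accuracy,
#'   sensitivity, specificity, auc, cv_accuracy_mean, cv_accuracy_sd),
#'   `confusion`, `roc` (data.frame fpr/tpr), `importance` (named
#'   mean-decrease-Gini vector), `scores` (test-set positive-class
#'   probabilities), `split`, `labels`, `positive_class`, `protocol`.
#' @export
rf_fit_evaluate <- function(features, labels, n_trees = 500,
                            train_fraction = 0.7, cv_folds = 10,
                            positive_class = NULL, prob_threshold = 0.5,
                            seed = NULL) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("need at least 2 features")
  labels <- as.factor(labels)
  stopifnot(nrow(features) == length(labels))
  if (is.null(positive_class)) {
    positive_class <- if ("case" %in% levels(labels)) "case" else levels(labels)[1L]
  }
  if (!is.null(seed)) set.seed(seed)
  sp <- split_stratified(labels, train_fraction)
  x_tr <- features[sp$train, , drop = FALSE]
  y_tr <- droplevels(labels[sp$train])
  x_te <- features[sp$test, , drop = FALSE]
  y_te <- droplevels(labels[sp$test])
  if (nlevels(y_tr) < 2) stop("training set lost a class")
  rf <- randomForest::randomForest(x = x_tr, y = y_tr, ntree = n_trees)
  scores <- stats::predict(rf, x_te, type = "prob")[, positive_class]
  pred_pos <- scores >= prob_threshold
  actual_pos <- y_te == positive_class
  tp <- sum(pred_pos & actual_pos); tn <- sum(!pred_pos & !actual_pos)
  fp <- sum(pred_pos & !actual_pos); fn <- sum(!pred_pos & actual_pos)
  confusion <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                      dimnames = list(predicted = c("positive", "negative"),
                                      actual = c("positive", "negative")))
  auc <- rank_auc(scores[actual_pos], scores[!actual_pos])
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thresholds,
    tpr = vapply(thresholds, function(th) mean(scores[actual_pos] >= th), 1),
    fpr = vapply(thresholds, function(th) mean(scores[!actual_pos] >= th), 1)
  )
  fold <- stratified_folds(y_tr, cv_folds)
  cv_acc <- vapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    if (nlevels(droplevels(y_tr[tr])) < 2) {
      stop("cross-validation fold lost a class; reduce cv_folds")
    }
    m <- randomForest::randomForest(x = x_tr[tr, , drop = FALSE],
                                    y = droplevels(y_tr[tr]),
                                    ntree = n_trees)
    mean(stats::predict(m, x_tr[!tr, , drop = FALSE]) == y_tr[!tr])
  }, 1)
  imp <- rf$importance[, "MeanDecreaseGini"]
  structure(
    list(model = rf,
         metrics = list(accuracy = (tp + tn) / length(y_te),
                        sensitivity = tp / (tp + fn),
                        specificity = tn / (tn + fp),
                        auc = auc,
                        cv_accuracy_mean = mean(cv_acc),
                        cv_accuracy_sd = stats::sd(cv_acc)),
         confusion = confusion, roc = roc,
         importance = imp, scores = scores,
         split = sp, labels = labels, positive_class = positive_class,
         protocol = list(n_trees = n_trees, train_fraction = train_fraction,
                         cv_folds = cv_folds, prob_threshold = prob_threshold,
                         mtry = rf$mtry, nodesize = 1, seed = seed)),
    class = "cag_rf"
  )
}

#' @export
print.cag_rf <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<cag_rf> %d trees; accuracy %.3f, sensitivity %.3f, ",
                     "specificity %.3f, AUC %.3f, CV accuracy %.3f +/- %.3f\n"),
              x$protocol$n_trees, m$accuracy, m$sensitivity, m$specificity,
              m$auc, m$cv_accuracy_mean, m$cv_accuracy_sd))
  invisible(x)
}

# Resolve a prediction function returning a numeric score per row.
as_predict_fun <- function(model, positive_class = NULL) {
  if (is.function(model)) return(model)
  if (inherits(model, "cag_rf")) {
    pc <- model$positive_class
    rf <- model$model
    return(function(newdata) stats::predict(rf, newdata, type = "prob")[, pc])
  }
  if (inherits(model, "randomForest")) {
    pc <- if (is.null(positive_class)) colnames(model$votes)[1L] else positive_class
    return(function(newdata) stats::predict(model, newdata, type = "prob")[, pc])
  }
  stop("model must be a function, a cag_rf, or a randomForest object")
}

#' Monte-Carlo permutation Shapley attribution
#'
#' Estimates per-instance, per-feature Shapley values of a prediction
#' function by permutation sampling against a background (training marginal)
#' distribution. For each of `mc_samples` draws, a random feature permutation
#' and a random background row are combined into a chain of hybrid
#' instances; the marginal contribution of feature j is the prediction
#' difference between the hybrids with and without j. Per-permutation totals
#' telescope to `f(x) - f(z)`, so the efficiency identity
#' `sum(phi) = f(x) - baseline` holds up to Monte-Carlo error, which is
#' reported per feature and per instance.
#'
#' @param model a `cag_rf`, a randomForest object, or a prediction function
#'   mapping a feature matrix to numeric scores.
#' @param instances matrix of instances to explain (rows).
#' @param background non-empty background feature matrix (typically the
#'   training set).
#' @param mc_samples Monte-Carlo permutations per instance (default 50).
#' @param n_explained number of instances to explain; when smaller than
#'   `nrow(instances)` a random subset is drawn, when larger it is clipped
#'   with a warning (default: all).
#' @param positive_class passed to the score extractor for raw randomForest
#'   models.
#' @param seed optional integer seed.
#' @return object of class `cag_shap`: list with `phi` (instances x features),
#'   `se` (per-feature MC standard errors), `baseline` (mean background
#'   prediction), `predictions`, `efficiency_gap`, `efficiency_se`
#'   (per-instance), `mc_samples`, `instance_ids`.
#' @export
shapley_mc <- function(model, instances, background, mc_samples = 50,
                       n_explained = NULL, positive_class = NULL,
                       seed = NULL) {
  f <- as_predict_fun(model, positive_class)
  instances <- as.matrix(instances)
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("background must contain at least one row")
  stopifnot(mc_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(n_explained)) {
    if (n_explained > nrow(instances)) {
      warning(sprintf("n_explained clipped from %d to %d (test-set size)",
                      n_explained, nrow(instances)))
      n_explained <- nrow(instances)
    }
    if (n_explained < nrow(instances)) {
      instances <- instances[sort(sample.int(nrow(instances), n_explained)),
                             , drop = FALSE]
    }
  }
  n <- nrow(instances); p <- ncol(instances)
  feat <- colnames(instances)
  if (is.null(feat)) feat <- sprintf("f%d", seq_len(p))
  baseline <- mean(f(background))
  predictions <- as.numeric(f(instances))
  phi <- matrix(0, n, p, dimnames = list(rownames(instances), feat))
  se <- matrix(0, n, p, dimnames = dimnames(phi))
  eff_se <- numeric(n)
  for (i in seq_len(n)) {
    x <- instances[i, ]
    # hybrid chain per permutation: row s*(p+1)+k = first k permuted features
    # from x, rest from background row z_s
    hybrids <- matrix(0, mc_samples * (p + 1L), p, dimnames = list(NULL, feat))
    perms <- matrix(0L, mc_samples, p)
    for (s in seq_len(mc_samples)) {
      perm <- sample.int(p)
      perms[s, ] <- perm
      z <- background[sample.int(nrow(background), 1L), ]
      h <- z
      base_row <- (s - 1L) * (p + 1L)
      hybrids[base_row + 1L, ] <- h
      for (k in seq_len(p)) {
        h[perm[k]] <- x[perm[k]]
        hybrids[base_row + 1L + k, ] <- h
      }
    }
    preds <- as.numeric(f(hybrids))
    contrib <- matrix(0, mc_samples, p)  # per-permutation contribution per feature
    for (s in seq_len(mc_samples)) {
      base_row <- (s - 1L) * (p + 1L)
      dif <- diff(preds[base_row + seq_len(p + 1L)])
      contrib[s, perms[s, ]] <- dif
    }
    phi[i, ] <- colMeans(contrib)
    se[i, ] <- apply(contrib, 2L, stats::sd) / sqrt(mc_samples)
    eff_se[i] <- stats::sd(rowSums(contrib)) / sqrt(mc_samples)
  }
  structure(
    list(phi = phi, se = se, baseline = baseline,
         predictions = predictions,
         efficiency_gap = rowSums(phi) - (predictions - baseline),
         efficiency_se = eff_se,
         mc_samples = mc_samples,
         instance_ids = rownames(instances)),
    class = "cag_shap"
  )
}

#' @export
print.cag_shap <- function(x, ...) {
  cat(sprintf("<cag_shap> %d instance(s) x %d feature(s), %d MC permutations; baseline %.4f\n",
              nrow(x$phi), ncol(x$phi), x$mc_samples, x$baseline))
  invisible(x)
}

#' Grouped summary of Shapley value distributions
#'
#' Selects the `top_n` features by mean absolute Shapley value and reports,
#' per feature and class, the box-plot statistics of the per-instance values
#' (median, quartiles, and whiskers at the most extreme points within 1.5 IQR
#' of the quartiles).
#'
#' @param shap a [shapley_mc()] result.
#' @param labels class label per explained instance.
#' @param top_n number of top features to keep (default 6).
#' @return data.frame: feature, class, n, mean_phi, median, q1, q3,
#'   whisker_low, whisker_high, mean_abs_phi.
#' @export
shap_group_summary <- function(shap, labels, top_n = 6) {
  stopifnot(inherits(shap, "cag_shap"))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(shap$phi))
  mean_abs <- colMeans(abs(shap$phi))
  top <- names(sort(mean_abs, decreasing = TRUE))[seq_len(min(top_n, length(mean_abs)))]
  rows <- list()
  for (ft in top) {
    for (cl in sort(unique(labels))) {
      v <- shap$phi[labels == cl, ft]
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- qs[3L] - qs[1L]
      lo <- min(v[v >= qs[1L] - 1.5 * iqr])
      hi <- max(v[v <= qs[3L] + 1.5 * iqr])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = ft, class = cl, n = length(v), mean_phi = mean(v),
        median = qs[2L], q1 = qs[1L], q3 = qs[3L],
        whisker_low = lo, whisker_high = hi,
        mean_abs_phi = mean_abs[[ft]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
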