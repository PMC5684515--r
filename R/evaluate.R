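#' Stratified train/test split
#'
#' Draws a random test set preserving per-class proportions within rounding
#' (per class, \code{round(test_fraction * n_class)} items go to the test
#' side). The split is an exact partition and is reproducible given
#' \code{seed}.
#'
#' @param y class labels (factor or character).
#' @param test_fraction fraction of each class assigned to the test set,
#'   strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
stratified_split <- function(y, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- factor(as.character(y))
  if (any(table(y) < 2L)) stop("every class needs at least 2 members")
  set.seed(seed)
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- round(test_fraction * length(idx))
    n_test <- max(1L, min(n_test, length(idx) - 1L))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Stratified cross-validation folds
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments (1..k), one per instance.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- factor(as.character(y))
  if (k < 2L) stop("k must be at least 2")
  if (any(table(y) < k)) stop("every class needs at least k members")
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n counts.
#' @param conf confidence level; default 0.95.
#' @return numeric vector \code{c(low, high)}.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  if (n == 0L) return(c(low = 0, high = 1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' ROC curve by score sweep
#'
#' Sweeps a decision threshold over the distinct scores (descending),
#' emitting one (false-positive rate, true-positive rate) point per
#' threshold; the curve starts at (0, 0) and ends at (1, 1). AUC is the
#' trapezoidal area under these points, which equals the
#' probability-of-correct-ranking estimator with ties counted half.
#'
#' @param gold gold labels.
#' @param scores real scores, larger = more positive.
#' @param positive name of the positive class.
#' @return list with \code{points} (data frame \code{fpr}, \code{tpr}) and
#'   \code{auc}.
#' @export
roc_sweep <- function(gold, scores, positive = "PIT") {
  stopifnot(length(gold) == length(scores))
  is_pos <- as.character(gold) == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("need both classes to draw a ROC")
  ord <- order(scores, decreasing = TRUE)
  is_pos <- is_pos[ord]
  s <- scores[ord]
  # one point after each group of tied scores
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(is_pos)[last_of_group] / n_pos
  fpr <- cumsum(!is_pos)[last_of_group] / n_neg
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Evaluate predictions against gold labels
#'
#' Computes per-class precision/recall/F1 from the confusion matrix, overall
#' accuracy with a 95\% Wilson score interval, and (when scores are supplied)
#' the ROC curve and AUC from a score sweep.
#'
#' @param predicted predicted labels.
#' @param gold gold labels (both classes must occur).
#' @param scores optional real scores for the ROC (larger = more positive).
#' @param positive positive class name; default \code{"PIT"}.
#' @return an object of class \code{evaluation_report}: list with
#'   \code{per_class} (data frame: class, precision, recall, f1, support),
#'   \code{accuracy}, \code{accuracy_ci}, \code{confusion}, \code{roc},
#'   \code{auc}, \code{n}.
#' @export
evaluate_predictions <- function(predicted, gold, scores = NULL,
                                 positive = "PIT") {
  predicted <- as.character(predicted)
  gold <- as.character(gold)
  if (length(predicted) != length(gold)) {
    stop("predicted and gold labels differ in length")
  }
  classes <- sort(unique(gold))
  if (length(classes) < 2L) stop("gold labels contain a single class")
  if (positive %in% classes) {
    classes <- c(setdiff(classes, positive), positive)
  }
  conf <- table(gold = factor(gold, classes),
                predicted = factor(predicted, classes))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = cl, precision = p, recall = r, f1 = f,
               support = tp + fn, stringsAsFactors = FALSE)
  }))
  acc <- sum(diag(conf)) / length(gold)
  roc <- NULL; auc <- NA_real_
  if (!is.null(scores)) {
    if (length(scores) != length(gold)) stop("scores differ in length")
    sweep <- roc_sweep(gold, scores, positive = positive)
    roc <- sweep$points
    auc <- sweep$auc
  }
  structure(list(per_class = per_class, accuracy = acc,
                 accuracy_ci = wilson_ci(sum(diag(conf)), length(gold)),
                 confusion = conf, roc = roc, auc = auc, n = length(gold)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> n = ", x$n, "\n", sep = "")
  print(x$per_class, row.names = FALSE, digits = 3)
  cat(sprintf("accuracy %.3f (95%% CI %.3f-%.3f)", x$accuracy,
              x$accuracy_ci["low"], x$accuracy_ci["high"]))
  if (!is.na(x$auc)) cat(sprintf(", AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Class-wise F1 of the positive class
#' @param report an \code{evaluation_report}.
#' @param class class name; default \code{"PIT"}.
#' @return scalar F1.
#' @export
class_f1 <- function(report, class = "PIT") {
  report$per_class$f1[report$per_class$class == class]
}

#' Stratified k-fold cross-validation
#'
#' Fits the classifier on each training fold and pools the held-out
#' predictions across folds before computing metrics (pooling, rather than
#' averaging per-fold metrics, keeps the report consistent with a
#' whole-corpus evaluation).
#'
#' @param x feature matrix.
#' @param y labels.
#' @param k number of folds; default 10.
#' @param kind,hyperparameters,scale_dense passed to [fit_classifier()].
#' @param seed integer seed (controls fold assignment and fitting).
#' @return list with \code{report} (pooled \code{evaluation_report}),
#'   \code{fold} (fold id per instance), \code{predicted}, \code{score}
#'   (pooled out-of-fold predictions, in input order).
#' @export
cross_validate <- function(x, y, k = 10L, kind = "svm",
                           hyperparameters = list(), seed = 1L,
                           scale_dense = TRUE) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  folds <- stratified_folds(y, k = k, seed = seed)
  predicted <- character(length(y))
  score <- numeric(length(y))
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- fit_classifier(x[!hold, , drop = FALSE], y[!hold], kind = kind,
                            hyperparameters = hyperparameters,
                            seed = seed + f, scale_dense = scale_dense)
    p <- predict(model, x[hold, , drop = FALSE])
    predicted[hold] <- as.character(p$label)
    score[hold] <- p$score
  }
  list(report = evaluate_predictions(predicted, y, score),
       fold = folds, predicted = predicted, score = score)
}

#' Per-pattern classifier performance
#'
#' Cross-validates once over the full instance set, then partitions the
#' pooled out-of-fold predictions by retrieval pattern and reports the
#' positive-class F1 within each pattern. Instances retrieved by several
#' patterns count toward each of them.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param pattern_ids list of integer vectors, one per instance (the patterns
#'   that retrieved it); every instance needs at least one.
#' @inheritParams cross_validate
#' @return data frame: \code{pattern_id}, \code{n}, \code{precision},
#'   \code{recall}, \code{f1} for the positive class (patterns with no
#'   instances are absent).
#' @export
per_pattern_evaluation <- function(x, y, pattern_ids, k = 10L, kind = "svm",
                                   hyperparameters = list(), seed = 1L) {
  stopifnot(length(pattern_ids) == length(y))
  if (any(lengths(pattern_ids) == 0L)) {
    stop("every instance needs at least one source pattern")
  }
  cv <- cross_validate(x, y, k = k, kind = kind,
                       hyperparameters = hyperparameters, seed = seed)
  all_ids <- sort(unique(unlist(pattern_ids)))
  rows <- lapply(all_ids, function(pid) {
    sel <- vapply(pattern_ids, function(ids) pid %in% ids, logical(1))
    gold <- as.character(y)[sel]
    if (!any(sel)) return(NULL)
    pred <- cv$predicted[sel]
    tp <- sum(pred == "PIT" & gold == "PIT")
    fp <- sum(pred == "PIT" & gold != "PIT")
    fn <- sum(pred != "PIT" & gold == "PIT")
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(pattern_id = pid, n = sum(sel), precision = p, recall = r,
               f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "cv") <- cv
  out
}

#' Learning curve with ROC/AUC per training fraction
#'
#' Trains on nested stratified subsets of the training set (the subset for a
#' smaller fraction is contained in every larger one, reducing
#' between-fraction variance) and evaluates each fit on the same fixed test
#' set.
#'
#' @param x_train,y_train training features and labels.
#' @param x_test,y_test fixed test set.
#' @param fractions increasing training fractions in (0, 1]; default
#'   \code{seq(0.1, 1, 0.1)}.
#' @inheritParams cross_validate
#' @return an object of class \code{learning_curve}: data frame with one row
#'   per usable fraction (fraction, n_train, accuracy, auc, plus per-class
#'   precision/recall/F1 for the positive class) and the full reports in
#'   \code{attr(, "reports")}. Fractions whose subset collapses to a single
#'   class are skipped with a warning.
#' @export
learning_curve <- function(x_train, y_train, x_test, y_test,
                           fractions = seq(0.1, 1, 0.1), kind = "svm",
                           hyperparameters = list(), seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions, strictly = TRUE))
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- factor(as.character(y_train))
  set.seed(seed)
  # one permutation per class; fraction f takes the first round(f * n_c)
  perm <- lapply(levels(y_train), function(cl) sample(which(y_train == cl)))
  reports <- list()
  rows <- list()
  for (f in fractions) {
    idx <- sort(unlist(lapply(perm, function(p) {
      p[seq_len(round(f * length(p)))]
    })))
    if (nlevels(droplevels(y_train[idx])) < 2L) {
      warning(sprintf("fraction %.2f yields a single-class subset; skipped", f))
      next
    }
    model <- fit_classifier(x_train[idx, , drop = FALSE], y_train[idx],
                            kind = kind, hyperparameters = hyperparameters,
                            seed = seed)
    p <- predict(model, x_test)
    rep <- evaluate_predictions(p$label, y_test, p$score)
    reports[[sprintf("%.2f", f)]] <- rep
    pos <- rep$per_class[rep$per_class$class == "PIT", ]
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, n_train = length(idx), accuracy = rep$accuracy,
      auc = rep$auc,
      precision = if (nrow(pos)) pos$precision else NA_real_,
      recall = if (nrow(pos)) pos$recall else NA_real_,
      f1 = if (nrow(pos)) pos$f1 else NA_real_)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  class(out) <- c("learning_curve", class(out))
  out
}

#' Feature-block ablation study
#'
#' Cross-validated performance for the full feature set, with each block
#' removed in turn (leave-one-out), and with each block alone. Blocks are
#' identified by the column-name prefixes that [featurize()] writes.
#'
#' @param x full feature matrix with block-prefixed column names.
#' @param y labels.
#' @param blocks block names to ablate; default: the blocks present in
#'   \code{x}.
#' @inheritParams cross_validate
#' @return data frame with one row per configuration (\code{"all"},
#'   \code{"-<block>"}, \code{"<block>"}): accuracy, AUC and positive-class
#'   precision/recall/F1. Configurations with no columns are skipped with a
#'   warning.
#' @export
ablation_study <- function(x, y, blocks = NULL, k = 10L, kind = "svm",
                           hyperparameters = list(), seed = 1L) {
  x <- as.matrix(x)
  col_block <- feature_block_of(colnames(x))
  if (is.null(blocks)) blocks <- intersect(feature_block_names,
                                           unique(col_block))
  if (length(blocks) < 2L) stop("need at least 2 feature blocks to ablate")
  configs <- c(list(all = blocks),
               stats::setNames(lapply(blocks, function(b) setdiff(blocks, b)),
                               paste0("-", blocks)),
               stats::setNames(lapply(blocks, identity), blocks))
  rows <- list()
  for (nm in names(configs)) {
    keep <- col_block %in% configs[[nm]]
    if (!any(keep)) {
      warning("configuration ", nm, " selects no columns; skipped")
      next
    }
    cv <- cross_validate(x[, keep, drop = FALSE], y, k = k, kind = kind,
                         hyperparameters = hyperparameters, seed = seed)
    rep <- cv$report
    pos <- rep$per_class[rep$per_class$class == "PIT", ]
    rows[[nm]] <- data.frame(
      configuration = nm, n_features = sum(keep), accuracy = rep$accuracy,
      auc = rep$auc, precision = pos$precision, recall = pos$recall,
      f1 = pos$f1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Brute-force AUC by pairwise ranking
#'
#' The probability that a randomly chosen positive instance outranks a
#' randomly chosen negative one (ties counted half). Quadratic; intended as
#' an independent check of [roc_sweep()] on small inputs.
#'
#' @inheritParams roc_sweep
#' @return scalar AUC.
#' @export
auc_pairwise <- function(gold, scores, positive = "PIT") {
  is_pos <- as.character(gold) == positive
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  stopifnot(length(pos) > 0L, length(neg) > 0L)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
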