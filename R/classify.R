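#' Resolve multi-annotator labels by majority vote
#'
#' @param matrix a data frame or matrix of categorical labels, one row per
#'   item, one column per annotator; \code{NA} = missing rating.
#' @param tie what to do with items whose top labels tie: \code{"discard"}
#'   (default; item dropped with a warning) or \code{"na"} (kept with
#'   \code{NA} consensus).
#' @return data frame with columns \code{item} (row index or rowname) and
#'   \code{label} (consensus); tied items are absent under the default
#'   policy.
#' @export
#' @examples
#' resolve_annotations(rbind(c("T", "T", "F"), c("T", "F", NA)), tie = "na")
resolve_annotations <- function(matrix, tie = c("discard", "na")) {
  tie <- match.arg(tie)
  m <- as.matrix(matrix)
  if (nrow(m) == 0L) stop("empty annotation matrix")
  if (any(rowSums(!is.na(m)) == 0L)) stop("item(s) with no label at all")
  items <- if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m)
  labels <- vapply(seq_len(nrow(m)), function(i) {
    tab <- table(m[i, ])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) NA_character_ else top
  }, character(1))
  tied <- is.na(labels)
  if (any(tied)) {
    warning(sum(tied), " item(s) with tied votes",
            if (tie == "discard") " discarded")
    if (tie == "discard") {
      items <- items[!tied]
      labels <- labels[!tied]
    }
  }
  data.frame(item = items, label = labels, stringsAsFactors = FALSE)
}

#' Fleiss' kappa
#'
#' Chance-corrected agreement among a fixed number of raters assigning
#' categorical labels: \eqn{\kappa = (\bar{P} - \bar{P_e}) / (1 - \bar{P_e})},
#' where \eqn{\bar{P}} is the mean observed pairwise agreement per item and
#' \eqn{\bar{P_e}} the agreement expected from the marginal category
#' proportions.
#'
#' @param matrix label matrix as in [resolve_annotations()]; every item must
#'   carry the same number of ratings.
#' @return kappa in \eqn{[-1, 1]}; \code{NA} with a warning when every rating
#'   is the same single category (agreement is then undefined, not perfect).
#' @export
#' @examples
#' fleiss_kappa(rbind(c("T", "T", "T"), c("F", "F", "F")))  # 1
fleiss_kappa <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) == 0L) stop("empty annotation matrix")
  n_ratings <- rowSums(!is.na(m))
  if (length(unique(n_ratings)) != 1L) {
    stop("every item must have the same number of ratings")
  }
  r <- n_ratings[1]
  if (r < 2L) stop("need at least 2 ratings per item")
  cats <- sort(unique(stats::na.omit(as.vector(m))))
  if (length(cats) < 2L) {
    warning("only one category present; kappa is undefined")
    return(NA_real_)
  }
  counts <- vapply(cats, function(cat) rowSums(m == cat, na.rm = TRUE),
                   numeric(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m))
  p_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (nrow(m) * r)
  p_e <- sum(p_j^2)
  (p_bar - p_e) / (1 - p_e)
}

#' Read an annotation file
#'
#' Tab-separated: \code{post_id} then one label column per annotator.
#'
#' @param path path to the annotation file.
#' @param header whether the file has a header row; default \code{TRUE}.
#' @return data frame; first column \code{post_id}, remaining columns labels.
#' @export
read_annotations <- function(path, header = TRUE) {
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  names(tab)[1] <- "post_id"
  tab
}

# -- classifiers --------------------------------------------------------------

pit_levels <- c("NOT_PIT", "PIT")

#' Train a post classifier
#'
#' Fits one of the supported classifier kinds on a feature matrix:
#' \describe{
#'   \item{\code{"svm"}}{linear-kernel support vector machine, cost 1, class
#'     weights proportional to inverse class frequency (the announcement
#'     class typically dominates the annotated data roughly 7:3);}
#'   \item{\code{"random_forest"}}{100 trees, sqrt-features per split;}
#'   \item{\code{"naive_bayes"}}{Gaussian event model over the full feature
#'     vector (dense blocks can be negative, so a count model does not
#'     apply); within-class standard deviations are floored at 0.05 as
#'     variance smoothing;}
#'   \item{\code{"ensemble"}}{all three of the above, combined at prediction
#'     time by majority voting.}
#' }
#' The dense blocks (embedding, sentiment, structural) are standardized with
#' means/sds estimated on the training data only; count blocks (ngram,
#' cluster) are left unscaled. Fitting is deterministic given \code{seed}.
#'
#' @param x numeric feature matrix (block-prefixed column names, as produced
#'   by [featurize_corpus()]).
#' @param y labels: factor or character with exactly two classes, the
#'   positive class named \code{"PIT"}.
#' @param kind one of \code{"svm"}, \code{"random_forest"},
#'   \code{"naive_bayes"}, \code{"ensemble"}.
#' @param hyperparameters named list overriding defaults (\code{cost},
#'   \code{ntree}, ...).
#' @param seed integer seed controlling all randomness in fitting.
#' @param scale_dense standardize non-count blocks; default \code{TRUE}.
#' @return an object of class \code{pit_classifier}.
#' @export
fit_classifier <- function(x, y,
                           kind = c("svm", "random_forest", "naive_bayes",
                                    "ensemble"),
                           hyperparameters = list(), seed = 1L,
                           scale_dense = TRUE) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%05d", seq_len(ncol(x)))
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("training set contains a single class")
  if (nlevels(y) > 2L) stop("expected exactly two classes")
  if (nrow(x) != length(y)) stop("feature matrix and labels differ in length")
  lv <- if (setequal(levels(y), pit_levels)) pit_levels else levels(y)
  y <- factor(as.character(y), levels = lv)

  scaler <- if (scale_dense) fit_feature_scaler(x) else NULL
  xs <- apply_feature_scaler(x, scaler)

  if (kind == "ensemble") {
    members <- lapply(c("naive_bayes", "svm", "random_forest"), function(k) {
      fit_classifier(x, y, kind = k, hyperparameters = hyperparameters,
                     seed = seed, scale_dense = scale_dense)
    })
    return(structure(list(kind = "ensemble", members = members,
                          levels = lv, features = colnames(x), seed = seed),
                     class = "pit_classifier"))
  }

  set.seed(seed)
  fitted <- switch(kind,
    svm = {
      cw <- 1 / table(y)
      cw <- cw / sum(cw) * length(cw)
      e1071::svm(xs, y, kernel = "linear",
                 cost = hyperparameters$cost %||% 1,
                 class.weights = cw, scale = FALSE, probability = FALSE)
    },
    random_forest = {
      randomForest::randomForest(
        xs, y,
        ntree = hyperparameters$ntree %||% 100L,
        mtry = hyperparameters$mtry %||% max(1L, floor(sqrt(ncol(xs)))))
    },
    naive_bayes = {
      nb <- e1071::naiveBayes(xs, y)
      # variance smoothing: floor within-class sds so that features that are
      # (near-)constant inside one class cannot contribute unbounded density
      # spikes and drown out the informative features
      nb$tables <- lapply(nb$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 0.05)
        tb
      })
      nb
    })
  structure(list(kind = kind, model = fitted, scaler = scaler,
                 levels = lv, features = colnames(x), seed = seed),
             class = "pit_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pit_classifier <- function(x, ...) {
  cat("<pit_classifier> kind = ", x$kind, ", ", length(x$features),
      " features, classes: ", paste(x$levels, collapse = " / "), "\n",
      sep = "")
  invisible(x)
}

fit_feature_scaler <- function(x) {
  blocks <- feature_block_of(colnames(x))
  scaled_cols <- blocks %in% c("embedding", "sentiment", "structural") |
    !blocks %in% feature_block_names
  if (!any(scaled_cols)) return(NULL)
  mu <- colMeans(x[, scaled_cols, drop = FALSE])
  sd <- apply(x[, scaled_cols, drop = FALSE], 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(cols = colnames(x)[scaled_cols], mean = mu, sd = sd)
}

apply_feature_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  cols <- intersect(scaler$cols, colnames(x))
  x[, cols] <- sweep(sweep(x[, cols, drop = FALSE], 2, scaler$mean[cols]),
                     2, scaler$sd[cols], "/")
  x
}

#' Predict with a fitted classifier
#'
#' @param object a \code{pit_classifier}.
#' @param newdata numeric feature matrix with the training layout.
#' @param ... unused.
#' @return data frame with columns \code{label} (factor) and \code{score}
#'   (real; larger means more announcement-like: signed margin for the SVM,
#'   positive-class vote fraction for the forest, positive-class posterior
#'   for Naive Bayes, mean member score for the ensemble).
#' @export
predict.pit_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (nrow(x) == 0L) {
    return(data.frame(label = factor(character(0), levels = object$levels),
                      score = numeric(0)))
  }
  if (is.null(colnames(x)) && ncol(x) == length(object$features)) {
    colnames(x) <- object$features
  }
  if (!identical(colnames(x), object$features)) {
    stop("feature layout does not match the training layout")
  }
  pos <- object$levels[2]
  if (object$kind == "ensemble") {
    preds <- lapply(object$members, predict, newdata = x)
    votes <- vapply(preds, function(p) p$label == pos, logical(nrow(x)))
    votes <- matrix(votes, nrow = nrow(x))
    lab <- ifelse(rowMeans(votes) > 0.5, pos, object$levels[1])
    score <- rowMeans(vapply(preds, function(p) p$score, numeric(nrow(x))))
    return(data.frame(label = factor(lab, levels = object$levels),
                      score = score))
  }
  xs <- apply_feature_scaler(x, object$scaler)
  out <- switch(object$kind,
    svm = {
      p <- stats::predict(object$model, xs, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      # orient the margin so that larger => positive class
      sgn <- if (grepl(paste0("^", pos, "/"), colnames(dv)[1])) 1 else -1
      data.frame(label = p, score = sgn * as.numeric(dv[, 1]))
    },
    random_forest = {
      pr <- stats::predict(object$model, xs, type = "prob")
      score <- pr[, pos]
      # label from the vote fraction (deterministic; exact 0.5 ties go to
      # the negative class)
      lab <- ifelse(score > 0.5, pos, object$levels[1])
      data.frame(label = factor(lab, levels = object$levels), score = score)
    },
    naive_bayes = {
      pr <- stats::predict(object$model, xs, type = "raw")
      score <- pr[, pos]
      lab <- object$levels[max.col(pr[, object$levels, drop = FALSE],
                                   ties.method = "first")]
      data.frame(label = factor(lab, levels = object$levels), score = score)
    })
  rownames(out) <- NULL
  out$label <- factor(as.character(out$label), levels = object$levels)
  stopifnot(all(is.finite(out$score)))
  out
}

#' Majority-vote ensemble prediction
#'
#' Combines an odd number (>= 3) of fitted classifiers by strict majority of
#' their predicted labels.
#'
#' @param members list of fitted \code{pit_classifier} objects sharing one
#'   feature layout.
#' @param newdata numeric feature matrix.
#' @return factor of majority labels.
#' @export
ensemble_predict <- function(members, newdata) {
  k <- length(members)
  if (k < 3L || k %% 2L == 0L) {
    stop("ensemble needs an odd number of members, at least 3")
  }
  layouts <- lapply(members, `[[`, "features")
  if (!all(vapply(layouts, identical, logical(1), layouts[[1]]))) {
    stop("members were fitted on different feature layouts")
  }
  lv <- members[[1]]$levels
  pos <- lv[2]
  x <- as.matrix(newdata)
  votes <- vapply(members,
                  function(m) predict(m, x)$label == pos,
                  logical(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  factor(ifelse(rowSums(votes) > k / 2, pos, lv[1]), levels = lv)
}

#' Save / load a classifier archive
#'
#' Persists a fitted classifier together with its seed, feature layout and
#' scaler via R's cross-platform serialization, for bit-identical reloading
#' and prediction.
#'
#' @param model a \code{pit_classifier}.
#' @param path archive path.
#' @return \code{load_classifier}: the restored model.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "pit_classifier"))
  m
}
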