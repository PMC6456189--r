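#' Binarize an NSA item rating into observable vs non-observable
#'
#' Ratings 1-2 code the symptom as non-observable, ratings 3-6 as observable.
#'
#' @param rating Integer vector of item ratings in \[1, 6\].
#' @return Factor with levels \code{non_observable}, \code{observable}.
#' @export
binarize_nsa <- function(rating) {
  if (any(!is.finite(rating)) || any(rating < 1 | rating > 6) ||
      any(rating != round(rating))) {
    stop("ratings must be integers in [1, 6]")
  }
  factor(ifelse(rating <= 2, "non_observable", "observable"),
         levels = c("non_observable", "observable"))
}

#' CFS merit of a feature subset
#'
#' Correlation-based feature selection scores a subset of k features as
#' \deqn{merit = k \bar r_{cf} / \sqrt{k + k (k - 1) \bar r_{ff}}}
#' where \eqn{\bar r_{cf}} is the mean absolute feature-label correlation in
#' the subset and \eqn{\bar r_{ff}} the mean absolute pairwise
#' feature-feature correlation: subsets highly correlated with the class but
#' mutually uncorrelated score best.
#'
#' @param subset Character or integer vector indexing the subset.
#' @param r_cf Named vector of absolute feature-label correlations.
#' @param r_ff Matrix of absolute feature-feature correlations.
#' @return The merit score.
#' @export
cfs_merit <- function(subset, r_cf, r_ff) {
  k <- length(subset)
  if (k == 0L) stop("subset must be non-empty")
  rbar_cf <- mean(r_cf[subset])
  rbar_ff <- if (k == 1L) 0 else {
    m <- r_ff[subset, subset, drop = FALSE]
    mean(m[upper.tri(m)])
  }
  k * rbar_cf / sqrt(k + k * (k - 1) * rbar_ff)
}

.abs_cor_structure <- function(features, y01) {
  X <- as.matrix(features)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  usable <- names(which(is.finite(sds) & sds > 0))
  if (length(usable) == 0L) stop("all features are constant")
  X <- X[, usable, drop = FALSE]
  r_cf <- abs(suppressWarnings(
    stats::cor(X, y01, use = "pairwise.complete.obs")))[, 1]
  r_cf[!is.finite(r_cf)] <- 0
  r_ff <- abs(suppressWarnings(
    stats::cor(X, use = "pairwise.complete.obs")))
  r_ff[!is.finite(r_ff)] <- 0
  list(r_cf = r_cf, r_ff = r_ff, features = usable)
}

#' CFS subset selection by best-first search
#'
#' Greedy best-first search over feature subsets maximizing
#' \code{\link{cfs_merit}}, stopping after \code{max_stale} consecutive
#' expansions that fail to improve the best merit. Ties are broken by
#' feature-name order, making the search deterministic.
#'
#' @param features Data frame / matrix of numeric features.
#' @param labels Two-level factor (or 0/1 vector).
#' @param max_stale Consecutive non-improving expansions tolerated
#'   (default 5).
#' @return A \code{selection_result} list: \code{selected} (ordered feature
#'   names), \code{merit}, \code{method = "cfs"}.
#' @export
cfs_select <- function(features, labels, max_stale = 5L) {
  y01 <- as.numeric(as.factor(labels)) - 1
  if (stats::sd(y01) == 0) stop("labels are constant")
  cs <- .abs_cor_structure(features, y01)
  feats <- sort(cs$features)

  key_of <- function(s) paste(sort(s), collapse = "|")
  open_keys <- character(0); open_sets <- list(); open_merit <- numeric(0)
  seen <- new.env(hash = TRUE)

  push <- function(s) {
    k <- key_of(s)
    if (!is.null(seen[[k]])) return(invisible(NULL))
    seen[[k]] <- TRUE
    open_keys <<- c(open_keys, k)
    open_sets[[length(open_sets) + 1L]] <<- s
    open_merit <<- c(open_merit, cfs_merit(s, cs$r_cf, cs$r_ff))
  }
  for (f in feats) push(f)

  best_idx <- order(-open_merit, open_keys)[1L]
  best <- open_sets[[best_idx]]
  best_merit <- open_merit[best_idx]
  stale <- 0L

  while (length(open_sets) > 0L && stale < max_stale) {
    i <- order(-open_merit, open_keys)[1L]
    s <- open_sets[[i]]
    open_sets[[i]] <- NULL
    open_keys <- open_keys[-i]
    open_merit <- open_merit[-i]

    improved <- FALSE
    for (f in setdiff(feats, s)) {
      child <- c(s, f)
      k <- key_of(child)
      if (!is.null(seen[[k]])) next
      push(child)
      m <- open_merit[length(open_merit)]
      if (m > best_merit + 1e-12) {
        best <- child; best_merit <- m; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(selected = best, merit = best_merit, method = "cfs"),
            class = "selection_result")
}

#' Top-k features by absolute correlation with the class label
#'
#' @param features Data frame / matrix of numeric features.
#' @param labels Two-level factor (or 0/1 vector).
#' @param k Number of features to keep (default 5; clipped with a warning
#'   when it exceeds the number of usable features).
#' @return A \code{selection_result}: \code{selected} in decreasing
#'   \code{|r|} order (name order on ties), \code{merit} = the |r| scores.
#' @export
correlation_rank_select <- function(features, labels, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  y01 <- as.numeric(as.factor(labels)) - 1
  if (stats::sd(y01) == 0) stop("labels are constant")
  cs <- .abs_cor_structure(features, y01)
  ord <- order(-cs$r_cf, names(cs$r_cf))
  if (k > length(ord)) {
    warning("k exceeds the number of usable features; clipping")
    k <- length(ord)
  }
  sel <- names(cs$r_cf)[ord][seq_len(k)]
  structure(list(selected = sel, merit = cs$r_cf[sel],
                 method = "correlation"),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %s\n", x$method,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' The matrix convention is rows = true class (positive first), columns =
#' predicted class (positive first), matching published confusion tables.
#'
#' @param m 2x2 matrix of non-negative counts with a positive total.
#' @return List: \code{accuracy} (percent), \code{precision},
#'   \code{recall}, \code{f_score} for the positive class; zero denominators
#'   give \code{NA}.
#' @export
metrics_from_confusion <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || any(m != round(m))) {
    stop("need a 2x2 matrix of non-negative integer counts")
  }
  total <- sum(m)
  if (total == 0) stop("confusion matrix is all zero")
  tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  list(accuracy = 100 * (tp + tn) / total,
       precision = prec, recall = rec, f_score = f)
}

# rank-statistic AUC over pooled held-out scores, midranks on ties
.auc_from_scores <- function(scores, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.fit_score <- function(classifier, x_train, y_train, x_test, positive, seed) {
  neg_first <- factor(y_train,
                      levels = c(setdiff(levels(y_train), positive), positive))
  if (classifier == "svm") {
    m <- e1071::svm(x_train, neg_first, kernel = "linear", cost = 1,
                    scale = FALSE)
    pr <- stats::predict(m, x_test, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    lv <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
    score <- if (lv[1] == positive) dv[1, 1] else -dv[1, 1]
  } else if (classifier == "rf") {
    set.seed(seed)
    m <- randomForest::randomForest(x_train, neg_first, ntree = 100)
    score <- stats::predict(m, x_test, type = "prob")[1, positive]
  } else if (classifier == "mlp") {
    set.seed(seed)
    d <- data.frame(x_train, .y = neg_first, check.names = FALSE)
    m <- nnet::nnet(.y ~ ., data = d, size = 16, decay = 0.01,
                    maxit = 200, trace = FALSE)
    raw <- stats::predict(m, data.frame(x_test, check.names = FALSE),
                          type = "raw")[1, 1]
    score <- if (levels(neg_first)[2] == positive) raw else 1 - raw
  } else if (classifier == "bagging") {
    set.seed(seed)
    d <- data.frame(x_train, .y = neg_first, check.names = FALSE)
    nd <- data.frame(x_test, check.names = FALSE)
    probs <- vapply(seq_len(50L), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      t <- rpart::rpart(.y ~ ., data = d[idx, , drop = FALSE],
                        method = "class",
                        control = rpart::rpart.control(cp = 0.01, minsplit = 5))
      stats::predict(t, nd, type = "prob")[1, positive]
    }, numeric(1))
    score <- mean(probs)
  } else {
    stop("unknown classifier: ", classifier)
  }
  unname(score)
}

.score_threshold <- function(classifier) {
  if (classifier == "svm") 0 else 0.5
}

#' Leave-one-subject-out cross-validated classification
#'
#' For each held-out subject, median imputation, standardization and feature
#' selection are fitted on the training fold only (no leakage), the chosen
#' classifier is trained, and the held-out subject is scored. Folds whose
#' training set collapses to a single class are skipped with a warning.
#' Classifiers: \code{"svm"} (maximum-margin linear, C = 1), \code{"rf"}
#' (100-tree random forest), \code{"mlp"} (one hidden layer of 16 units),
#' \code{"bagging"} (50 bootstrap-aggregated trees). Hyperparameters are
#' fixed; stochastic learners are reseeded per fold from \code{seed}.
#'
#' @param features Data frame of numeric features (a \code{subject_id}
#'   column, if present, is dropped).
#' @param labels Two-level factor, one label per row.
#' @param classifier One of "svm", "rf", "mlp", "bagging".
#' @param selection "none", "cfs" or "correlation" (nested in each fold).
#' @param k Number of features for correlation ranking (default 5).
#' @param positive Positive class (default: second factor level).
#' @param standardize Standardize features on the training fold
#'   (default TRUE).
#' @param seed Base seed for stochastic classifiers.
#' @return A \code{classification_report}: confusion matrix (rows = true,
#'   positive first), accuracy (percent), AUC over pooled held-out scores,
#'   per-class precision/recall/F, the five most frequently selected
#'   features, and fold bookkeeping.
#' @export
loocv <- function(features, labels,
                  classifier = c("svm", "rf", "mlp", "bagging"),
                  selection = c("none", "cfs", "correlation"),
                  k = 5L, positive = NULL, standardize = TRUE, seed = 1L) {
  classifier <- match.arg(classifier)
  selection <- match.arg(selection)
  features <- features[setdiff(names(features), "subject_id")]
  X <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 classes")
  if (nrow(X) < 4L) stop("need at least 4 subjects")
  if (is.null(positive)) positive <- levels(labels)[2]
  negative <- setdiff(levels(labels), positive)

  n <- nrow(X)
  scores <- rep(NA_real_, n)
  pred <- rep(NA_character_, n)
  sel_counts <- integer(0)
  skipped <- integer(0)

  for (i in seq_len(n)) {
    y_tr <- labels[-i]
    if (length(unique(y_tr)) < 2L) {
      warning("fold ", i, " skipped: single-class training set")
      skipped <- c(skipped, i)
      next
    }
    x_tr <- X[-i, , drop = FALSE]
    x_te <- X[i, , drop = FALSE]

    # median imputation + standardization, fitted on the training fold
    med <- apply(x_tr, 2, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(x_tr))) {
      x_tr[is.na(x_tr[, j]), j] <- med[j]
      x_te[is.na(x_te[, j]), j] <- med[j]
    }
    keep <- which(apply(x_tr, 2, stats::sd) > 0 & is.finite(med))
    if (length(keep) == 0L) {
      # no usable features in this fold: majority vote, uninformative score
      pred[i] <- if (mean(y_tr == positive) > 0.5) positive else negative
      scores[i] <- 0.5
      next
    }
    x_tr <- x_tr[, keep, drop = FALSE]
    x_te <- x_te[, keep, drop = FALSE]
    if (standardize) {
      mu <- colMeans(x_tr); sdv <- apply(x_tr, 2, stats::sd)
      x_tr <- sweep(sweep(x_tr, 2, mu), 2, sdv, "/")
      x_te <- sweep(sweep(x_te, 2, mu), 2, sdv, "/")
    }

    if (selection != "none") {
      sel <- if (selection == "cfs") {
        cfs_select(x_tr, y_tr)
      } else {
        correlation_rank_select(x_tr, y_tr, k = min(k, ncol(x_tr)))
      }
      for (f in sel$selected) {
        sel_counts[f] <- (if (is.na(sel_counts[f])) 0L else sel_counts[f]) + 1L
      }
      x_tr <- x_tr[, sel$selected, drop = FALSE]
      x_te <- x_te[, sel$selected, drop = FALSE]
    }

    scores[i] <- .fit_score(classifier, x_tr, y_tr, x_te, positive,
                            seed = seed + i)
    pred[i] <- if (scores[i] > .score_threshold(classifier)) positive else negative
  }

  done <- !is.na(pred)
  if (!any(done)) stop("all folds were skipped")
  truth <- as.character(labels)[done]
  confusion <- matrix(
    c(sum(truth == positive & pred[done] == positive),
      sum(truth == positive & pred[done] == negative),
      sum(truth == negative & pred[done] == positive),
      sum(truth == negative & pred[done] == negative)),
    nrow = 2, byrow = TRUE,
    dimnames = list(true = c(positive, negative),
                    predicted = c(positive, negative)))
  pos_metrics <- metrics_from_confusion(confusion)
  neg_metrics <- metrics_from_confusion(confusion[2:1, 2:1])
  auc <- .auc_from_scores(scores[done], truth == positive)

  best <- if (length(sel_counts)) {
    names(sel_counts)[order(-sel_counts, names(sel_counts))]
  } else {
    character(0)
  }

  structure(
    list(confusion = confusion,
         accuracy = pos_metrics$accuracy,
         auc = auc,
         precision = c(stats::setNames(pos_metrics$precision, positive),
                       stats::setNames(neg_metrics$precision, negative)),
         recall = c(stats::setNames(pos_metrics$recall, positive),
                    stats::setNames(neg_metrics$recall, negative)),
         f_score = c(stats::setNames(pos_metrics$f_score, positive),
                     stats::setNames(neg_metrics$f_score, negative)),
         best_features = utils::head(best, 5L),
         classifier = classifier, selection = selection,
         positive = positive, n = sum(done), skipped_folds = skipped,
         scores = scores, predicted = pred),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s + %s selection (n = %d)\n",
              x$classifier, x$selection, x$n))
  print(x$confusion)
  cat(sprintf("accuracy %.1f%%, AUC %.2f\n", x$accuracy, x$auc))
  cat(sprintf("precision(%s) %.2f, recall(%s) %.2f, F(%s) %.2f\n",
              x$positive, x$precision[x$positive],
              x$positive, x$recall[x$positive],
              x$positive, x$f_score[x$positive]))
  if (length(x$best_features)) {
    cat("best features:", paste(x$best_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.classification_report <- function(object, ...) {
  print(object)
  invisible(object)
}
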