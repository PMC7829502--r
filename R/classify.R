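## F-score feature ranking, leave-one-out SVM discrimination, ROC/AUC,
## and permutation significance.

#' F-score of each feature for a two-class problem
#'
#' For feature i with overall mean x-bar, class means x-bar+ / x-bar- and
#' sample variances (n - 1 denominators) s2+ / s2-:
#'
#'   F(i) = ((x-bar+ - x-bar)^2 + (x-bar- - x-bar)^2) / (s2+ + s2-)
#'
#' Larger F means stronger between-class separation relative to
#' within-class spread. When both class variances are zero the score is
#' \code{Inf} for unequal class means (ranked first, with a warning) and
#' 0 for equal ones.
#'
#' @param x subjects x features numeric matrix.
#' @param y logical vector (or factor/character coercible to it) marking
#'   the positive class.
#' @return numeric vector of F-scores, one per feature.
#' @export
f_score <- function(x, y) {
  x <- as.matrix(x)
  pos <- as_positive(y)
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("need at least 2 samples in each class")
  xp <- x[pos, , drop = FALSE]; xn <- x[!pos, , drop = FALSE]
  m <- colMeans(x); mp <- colMeans(xp); mn <- colMeans(xn)
  num <- (mp - m)^2 + (mn - m)^2
  den <- apply(xp, 2L, var) + apply(xn, 2L, var)
  f <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  if (any(is.infinite(f)))
    warning("feature(s) with zero within-class variance and unequal ",
            "means: infinite F-score, ranked first")
  f
}

as_positive <- function(y) {
  if (is.logical(y)) return(y)
  y <- as.character(y)
  if (all(y %in% c("MHE", "noHE"))) return(y == "MHE")
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("labels must have exactly two classes")
  y == lev[2L]
}

# Rank features by F-score (descending), ties broken by feature index.
rank_features <- function(x, y) order(-f_score(x, y), seq_len(ncol(x)))

#' Leave-one-out SVM classification with per-fold feature selection
#'
#' For each held-out subject, features are ranked by F-score on the
#' training fold only, the top \code{k} are z-scored with training-fold
#' mean/SD, and an SVM is fitted and applied to the held-out subject.
#' Confusion counts are aggregated over the n folds; consensus features
#' are the \code{k} most frequently selected across folds.
#'
#' @param x subjects x features numeric matrix (e.g. node disjointness).
#' @param y labels; \code{"MHE"} (or \code{TRUE}) is the positive class.
#' @param k number of features selected per fold.
#' @param kernel \code{"radial"} (default) or \code{"linear"}.
#' @param cost SVM cost parameter C.
#' @return a \code{cv_result}: accuracy/sensitivity/specificity (percent),
#'   \code{auc}, per-fold \code{predictions} and decision \code{scores}
#'   (positive = MHE side), \code{confusion}, \code{selected} (features
#'   per fold) and \code{consensus_features}.
#' @export
loocv_classify <- function(x, y, k = 23L, kernel = c("radial", "linear"),
                           cost = 1) {
  x <- as.matrix(x)
  kernel <- match.arg(kernel)
  pos <- as_positive(y)
  k <- as.integer(k)
  if (k < 1L || k > ncol(x))
    stop(sprintf("k must be in 1..%d features", ncol(x)))
  if (sum(pos) < 3L || sum(!pos) < 3L)
    stop("need at least 3 subjects per class")
  n <- nrow(x)
  pred <- logical(n); score <- numeric(n)
  selected <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]; tr_y <- pos[-i]
    feat <- rank_features(tr_x, tr_y)[seq_len(k)]
    selected[i, ] <- feat
    mu <- colMeans(tr_x[, feat, drop = FALSE])
    sg <- apply(tr_x[, feat, drop = FALSE], 2L, sd)
    sg[sg == 0] <- 1
    ztr <- scale(tr_x[, feat, drop = FALSE], center = mu, scale = sg)
    zte <- (x[i, feat] - mu) / sg
    yf <- factor(ifelse(tr_y, "pos", "neg"), levels = c("neg", "pos"))
    fit <- e1071::svm(ztr, yf, kernel = kernel, cost = cost,
                      gamma = 1 / k, scale = FALSE)
    dv <- attr(predict(fit, matrix(zte, nrow = 1L),
                       decision.values = TRUE), "decision.values")
    # orient the decision value so positive scores mean the MHE side
    flip <- if (grepl("^pos/", colnames(dv)[1L])) 1 else -1
    score[i] <- flip * dv[1L]
    pred[i] <- score[i] > 0
  }
  tp <- sum(pred & pos); tn <- sum(!pred & !pos)
  fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  roc <- roc_auc(score, pos)
  freq <- tabulate(as.vector(selected), nbins = ncol(x))
  consensus <- order(-freq, seq_len(ncol(x)))[seq_len(k)]
  structure(list(
    accuracy = 100 * (tp + tn) / n,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    auc = roc$auc, roc = roc$points,
    predictions = pred, scores = score, labels = pos,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    selected = selected, consensus_features = consensus,
    k = k, kernel = kernel, cost = cost), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' ROC curve and AUC from decision scores
#'
#' Threshold sweep over the unique scores; the AUC is the trapezoid area,
#' which equals the Mann-Whitney pair-counting statistic
#' U / (n+ * n-) with ties counted half.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels positive-class indicator (see \code{\link{f_score}}).
#' @return list with \code{points} (data frame \code{fpr}, \code{tpr})
#'   and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  np <- sum(pos); nn <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores so ties contribute diagonal segments
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Permutation test of LOOCV accuracy
#'
#' Labels are shuffled \code{n_perm} times (seeded); the full LOOCV,
#' including per-fold feature selection, is rerun on each shuffle. The
#' p-value uses the add-one estimator
#' \code{(1 + #\{perm accuracy >= observed\}) / (n_perm + 1)}, which never
#' returns 0.
#'
#' @inheritParams loocv_classify
#' @param n_perm number of label permutations.
#' @param seed integer seed for the shuffles.
#' @return list with \code{p}, \code{observed} accuracy, and the
#'   \code{null} accuracy distribution (percent).
#' @export
permutation_test <- function(x, y, k = 23L, n_perm = 1000L, seed = 1L,
                             kernel = "radial", cost = 1) {
  pos <- as_positive(y)
  obs <- loocv_classify(x, pos, k = k, kernel = kernel, cost = cost)
  seeds <- derive_seeds(seed, n_perm)
  null <- vapply(seeds, function(s) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    yp <- sample(pos)
    loocv_classify(x, yp, k = k, kernel = kernel, cost = cost)$accuracy
  }, numeric(1L))
  list(p = (1 + sum(null >= obs$accuracy)) / (n_perm + 1),
       observed = obs$accuracy, null = null, result = obs)
}

#' Choose the selected-feature count from cross-validated accuracy
#'
#' Runs the full LOOCV at each candidate k and returns the k with the
#' best mean accuracy (ties: smallest k). Because each fold's selection
#' already happens inside the training fold, this grid is the average
#' classification performance over all loops.
#'
#' @inheritParams loocv_classify
#' @param k_grid candidate feature counts.
#' @return list with \code{k}, and \code{accuracy} per candidate.
#' @export
select_k <- function(x, y, k_grid = c(5L, 10L, 15L, 23L, 30L),
                     kernel = "radial", cost = 1) {
  k_grid <- k_grid[k_grid <= ncol(x)]
  acc <- vapply(k_grid, function(k)
    loocv_classify(x, y, k = k, kernel = kernel, cost = cost)$accuracy,
    numeric(1L))
  list(k = k_grid[which.max(acc)], k_grid = k_grid, accuracy = acc)
}
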