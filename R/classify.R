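## Ensemble classification (bagging / random forest) of 500 bp windows and
## the promoter-prediction evaluation metrics: sensitivity (SN), positive
## predictive value (PPV), Matthews correlation coefficient (MCC) and
## true-positive cost (TPC = FP/TP).

#' Promoter-prediction performance metrics from confusion counts
#'
#' Computes the four standard promoter-prediction metrics from a binary
#' confusion matrix:
#' \deqn{SN = 100\, TP/(TP+FN), \quad PPV = 100\, TP/(TP+FP),}
#' \deqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)},}
#' \deqn{TPC = FP/TP.}
#' A metric whose denominator is 0 is reported as 0 and flagged in the
#' `degenerate` field. All four metrics are invariant to scaling the four
#' counts by a common factor, and MCC is symmetric under the simultaneous
#' swap TP<->TN, FP<->FN.
#'
#' @param tp,fn,tn,fp non-negative confusion counts.
#' @return list with `sn` (percent), `ppv` (percent), `mcc`, `tpc`, the four
#'   counts, and `degenerate` (character vector of zero-denominator
#'   metrics).
#' @examples
#' m <- evalMetrics(tp = 7603, fn = 1190, tn = 34354, fp = 332)
#' round(c(m$sn, m$ppv, m$mcc, m$tpc), 2)
#' @export
evalMetrics <- function(tp, fn, tn, fp) {
  tp <- as.numeric(tp); fn <- as.numeric(fn)
  tn <- as.numeric(tn); fp <- as.numeric(fp)
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  degenerate <- character()
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    degenerate <- c(degenerate, "sn"); 0 }
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
    degenerate <- c(degenerate, "ppv"); 0 }
  denTerms <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (all(denTerms > 0))
    (tp * tn - fp * fn) / exp(0.5 * sum(log(denTerms))) else {
    degenerate <- c(degenerate, "mcc"); 0 }
  tpc <- if (tp > 0) fp / tp else {
    degenerate <- c(degenerate, "tpc"); 0 }
  list(sn = sn, ppv = ppv, mcc = mcc, tpc = tpc,
       tp = tp, fn = fn, tn = tn, fp = fp, degenerate = degenerate)
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth vectors coercible to character; the positive class
#'   is `"promoter"`.
#' @param positive name of the positive class.
#' @return named numeric vector `c(tp, fn, tn, fp)`.
#' @export
confusionCounts <- function(predicted, truth, positive = "promoter") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  c(tp = sum(predicted == positive & truth == positive),
    fn = sum(predicted != positive & truth == positive),
    tn = sum(predicted != positive & truth != positive),
    fp = sum(predicted == positive & truth != positive))
}

.asFeatureDf <- function(features) {
  stopifnot(is.data.frame(features) || is.matrix(features))
  as.data.frame(features)
}

.labelFactor <- function(labels) {
  factor(as.character(labels), levels = c("nonpromoter", "promoter"))
}

#' Train a bagging or random-forest promoter classifier
#'
#' Both algorithms are ensembles of classification trees over bootstrap
#' samples; bagging uses every feature at each split (`mtry = p`) while
#' random forest samples `floor(sqrt(p))` features. Fits are deterministic
#' given the seed. Constant feature columns are allowed (they are simply
#' never chosen for a split) and reported via a message.
#'
#' @param features data.frame of feature columns (rows = records).
#' @param labels vector of `"promoter"` / `"nonpromoter"` labels.
#' @param algorithm `"random_forest"` or `"bagging"`.
#' @param ntree number of trees (default 100).
#' @param mtry features tried per split; defaults to `floor(sqrt(p))` for
#'   random forest and `p` for bagging.
#' @param seed integer seed.
#' @return a [PromoterModel-class].
#' @export
trainModel <- function(features, labels,
                       algorithm = c("random_forest", "bagging"),
                       ntree = 100L, mtry = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- .asFeatureDf(features)
  y <- .labelFactor(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both classes")
  if (anyNA(x)) stop("features contain NA")
  const <- vapply(x, function(v) length(unique(v)) == 1L, logical(1))
  if (any(const))
    message(sum(const), " constant feature column(s): ",
            paste(names(x)[const], collapse = ", "))
  p <- ncol(x)
  if (is.null(mtry))
    mtry <- if (algorithm == "bagging") p else max(1L, floor(sqrt(p)))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry)
  new("PromoterModel", algorithm = algorithm, fit = fit,
      featureNames = colnames(x),
      hyperparameters = list(ntree = as.integer(ntree),
                             mtry = as.integer(mtry)),
      seed = as.integer(seed))
}

#' Predict promoter probabilities and labels
#'
#' Refuses to predict when the feature columns do not match the model's
#' training columns; columns given in a different order (same set) are
#' reordered.
#'
#' @param model a [PromoterModel-class].
#' @param features data.frame of feature columns.
#' @param threshold probability cutoff; label is `"promoter"` iff the score
#'   is >= threshold (default 0.5).
#' @return data.frame with columns `score` and `label`.
#' @export
predictPromoter <- function(model, features, threshold = 0.5) {
  stopifnot(is(model, "PromoterModel"))
  x <- .asFeatureDf(features)
  if (!identical(colnames(x), model@featureNames)) {
    if (setequal(colnames(x), model@featureNames))
      x <- x[, model@featureNames, drop = FALSE]
    else
      stop("feature columns do not match the model's training columns")
  }
  score <- stats::predict(model@fit, x, type = "prob")[, "promoter"]
  data.frame(score = as.numeric(score),
             label = ifelse(score >= threshold, "promoter", "nonpromoter"),
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation with pooled confusion counts
#'
#' Folds are stratified by label; per-fold confusion counts are pooled
#' before computing the metrics, and the pooled counts always sum to the
#' number of records.
#'
#' @param features data.frame of feature columns.
#' @param labels vector of `"promoter"` / `"nonpromoter"` labels.
#' @param k number of folds (default 10).
#' @param algorithm,ntree,mtry passed to [trainModel()].
#' @param threshold probability cutoff for the promoter label.
#' @param seed integer seed (fold assignment and fits).
#' @return list with `report` (pooled [evalMetrics()]), `confusion` (named
#'   counts), `perFold` (list of per-fold reports), `scores` and `labels`
#'   (out-of-fold scores usable for ROC), and `auc`.
#' @export
crossValidate <- function(features, labels, k = 10L,
                          algorithm = c("random_forest", "bagging"),
                          ntree = 100L, mtry = NULL, threshold = 0.5,
                          seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 2)
  x <- .asFeatureDf(features)
  y <- .labelFactor(labels)
  n <- nrow(x)
  set.seed(seed)
  fold <- integer(n)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  scores <- numeric(n)
  predicted <- character(n)
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    model <- trainModel(x[tr, , drop = FALSE], y[tr], algorithm,
                        ntree = ntree, mtry = mtry, seed = seed + f)
    pr <- predictPromoter(model, x[te, , drop = FALSE], threshold)
    scores[te] <- pr$score
    predicted[te] <- pr$label
    cmF <- confusionCounts(pr$label, y[te])
    perFold[[f]] <- evalMetrics(cmF["tp"], cmF["fn"], cmF["tn"], cmF["fp"])
  }
  cm <- confusionCounts(predicted, y)
  roc <- rocPoints(scores, y == "promoter")
  list(report = evalMetrics(cm["tp"], cm["fn"], cm["tn"], cm["fp"]),
       confusion = cm, perFold = perFold,
       scores = scores, labels = as.character(y), auc = roc$auc)
}

#' ROC points and trapezoid AUC
#'
#' Thresholds sweep the distinct score values from high to low; tied scores
#' move together. AUC is the trapezoid area under the (FPR, TPR) curve: 1
#' for perfectly separating scores, 0 for anti-perfect ones, and equal to
#' the pairwise-comparison probability (ties counted half).
#'
#' @param scores numeric prediction scores (higher = more promoter-like).
#' @param labels logical or `"promoter"`/`"nonpromoter"` vector of truths.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
rocPoints <- function(scores, labels) {
  if (!is.logical(labels)) labels <- as.character(labels) == "promoter"
  stopifnot(length(scores) == length(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0)
    stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cumTp <- cumsum(l); cumFp <- cumsum(!l)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tpr <- c(0, cumTp[last] / P)
  fpr <- c(0, cumFp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, s[last])),
       auc = auc)
}

#' Permutation variable importance averaged over repeated forests
#'
#' Fits `nRepeats` random forests and averages the out-of-bag permutation
#' importance: for each tree, the prediction accuracy on the untouched
#' out-of-bag sample minus the accuracy on the out-of-bag sample with one
#' predictor permuted, averaged over trees and normalized by its standard
#' error (mean decrease in accuracy), alongside the mean decrease in Gini
#' impurity.
#'
#' @param features data.frame of feature columns.
#' @param labels vector of `"promoter"` / `"nonpromoter"` labels.
#' @param nRepeats number of forests to average (default 100).
#' @param ntree trees per forest (default 100).
#' @param seed integer seed.
#' @return data.frame with one row per feature: `feature`,
#'   `meanDecreaseAccuracy`, `meanDecreaseGini`, sorted by decreasing
#'   accuracy importance.
#' @export
variableImportance <- function(features, labels, nRepeats = 100L,
                               ntree = 100L, seed = 1L) {
  x <- .asFeatureDf(features)
  y <- .labelFactor(labels)
  accSum <- giniSum <- numeric(ncol(x))
  for (r in seq_len(nRepeats)) {
    set.seed(seed + r)
    fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                      importance = TRUE)
    imp <- randomForest::importance(fit, scale = TRUE)
    accSum <- accSum + imp[, "MeanDecreaseAccuracy"]
    giniSum <- giniSum + imp[, "MeanDecreaseGini"]
  }
  out <- data.frame(feature = colnames(x),
                    meanDecreaseAccuracy = accSum / nRepeats,
                    meanDecreaseGini = giniSum / nRepeats,
                    stringsAsFactors = FALSE)
  out[order(-out$meanDecreaseAccuracy), ]
}

#' Save / load a fitted promoter model
#'
#' The archive stores a format version, the algorithm id, hyperparameters,
#' feature column order and the fitted state; [predictPromoter()] refuses a
#' mismatched feature order.
#'
#' @param model a [PromoterModel-class].
#' @param path file path (.rds).
#' @return `savePromoterModel` the path invisibly; `loadPromoterModel` the
#'   model.
#' @export
savePromoterModel <- function(model, path) {
  stopifnot(is(model, "PromoterModel"))
  saveRDS(list(format = "PolPromoter-model-v1",
               algorithm = model@algorithm,
               hyperparameters = model@hyperparameters,
               featureNames = model@featureNames,
               seed = model@seed,
               fit = model@fit), path)
  invisible(path)
}

#' @rdname savePromoterModel
#' @export
loadPromoterModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "PolPromoter-model-v1"))
    stop("unrecognized model archive format")
  new("PromoterModel", algorithm = obj$algorithm, fit = obj$fit,
      featureNames = obj$featureNames,
      hyperparameters = obj$hyperparameters, seed = obj$seed)
}
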