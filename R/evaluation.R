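# Evaluation: confusion counts, Sn/Sp/Acc/MCC, ROC curves with AUC, and the
# stratified k-fold cross-validation harness.

#' Classification metrics from confusion counts
#'
#' Vectorized evaluation of the four standard two-class formulas:
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/total` and the
#' Matthews correlation
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' with `MCC = 0` whenever a factor of the denominator is 0.
#'
#' @param tp,tn,fp,fn non-negative integer vectors (recycled).
#' @return data frame with columns `Sn`, `Sp`, `Acc`, `MCC`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative counts", call. = FALSE)
  # compute in doubles: the MCC denominator product overflows 32-bit
  # integers already at a few hundred counts per cell
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  num <- tp * tn - fp * fn
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  data.frame(Sn = tp / (tp + fn),
             Sp = tn / (tn + fp),
             Acc = (tp + tn) / (tp + tn + fp + fn),
             MCC = ifelse(den2 == 0, 0, num / sqrt(den2)))
}

#' Confusion matrix and summary metrics for binary predictions
#'
#' @param labels true labels (`"positive"`/`"negative"`, logical or 0/1).
#' @param predicted predicted labels, same encoding.
#' @return an object of class `evaluation_report` with counts `tp`, `tn`,
#'   `fp`, `fn` and metrics `Sn`, `Sp`, `Acc`, `MCC`.
#' @export
confusion_metrics <- function(labels, predicted) {
  if (!length(labels)) stop("empty input", call. = FALSE)
  if (length(labels) != length(predicted)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  to01 <- function(v) {
    if (is.character(v)) v == "positive"
    else if (is.factor(v)) v == levels(v)[2L]
    else v > 0
  }
  y <- to01(labels); p <- to01(predicted)
  tp <- sum(y & p); tn <- sum(!y & !p)
  fp <- sum(!y & p); fn <- sum(y & !p)
  m <- classification_metrics(tp, tn, fp, fn)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  Sn=%.4f Sp=%.4f Acc=%.4f MCC=%.4f", x$Sn, x$Sp, x$Acc,
              x$MCC))
  if (!is.null(x$auc)) cat(sprintf(" AUC=%.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps all score thresholds (tied scores grouped), producing a monotone
#' curve from (0, 0) to (1, 1); the trapezoid-rule area equals the
#' Mann-Whitney statistic with ties counted 1/2.
#'
#' @param labels two-class labels, both classes present.
#' @param scores numeric decision scores, higher = more positive.
#' @return list with `roc` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  y <- if (is.character(labels)) labels == "positive"
       else if (is.factor(labels)) labels == levels(labels)[2L]
       else labels > 0
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0 || nneg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_end <- c(which(diff(ss) != 0), length(ss))  # last index of each tie run
  tpr <- c(0, cumsum(ys)[grp_end] / npos)
  fpr <- c(0, cumsum(!ys)[grp_end] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified k-fold cross-validation of an RBF C-SVC
#'
#' Assigns every sample to exactly one test fold (stratified by class,
#' seeded by `config$seed`), trains on the remaining folds with
#' `config$C` / `config$gamma`, and evaluates the out-of-fold decision
#' values. Pooled metrics are computed over the concatenated out-of-fold
#' predictions, so the counts-based formulas stay exact; a pooled ROC/AUC is
#' attached to the pooled report.
#'
#' @param matrix feature matrix with column names.
#' @param labels two-class labels.
#' @param config an [svm_config()]; `gamma = NULL` defaults to
#'   `1/ncol(matrix)`.
#' @return list with `folds` (per-fold `evaluation_report`s, each with an
#'   `auc` element), `pooled` (`evaluation_report` with `auc`), `scores`
#'   (out-of-fold decision values in input order) and `fold_id`.
#' @export
cross_validate <- function(matrix, labels, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  n <- nrow(matrix)
  if (n < config$folds) stop("fewer samples than folds", call. = FALSE)
  gamma <- if (is.null(config$gamma)) 1 / ncol(matrix) else config$gamma
  fold <- stratified_folds(labels, config$folds, config$seed)
  scores <- numeric(n)
  reports <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    te <- fold == f
    m <- svm_fit(matrix[!te, , drop = FALSE], labels[!te],
                 C = config$C, gamma = gamma)
    s <- decision_values(m, matrix[te, , drop = FALSE])
    scores[te] <- s
    rep_f <- confusion_metrics(labels[te], s > 0)
    rep_f$auc <- roc_auc(labels[te], s)$auc
    reports[[f]] <- rep_f
  }
  pooled <- confusion_metrics(labels, scores > 0)
  pr <- roc_auc(labels, scores)
  pooled$auc <- pr$auc
  pooled$roc <- pr$roc
  list(folds = reports, pooled = pooled, scores = scores, fold_id = fold)
}
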