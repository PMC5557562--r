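# RBF-kernel C-SVC: training (SMO in C++), decision values, and grid search
# under stratified k-fold cross-validated ROC AUC.

#' RBF kernel value
#'
#' `K(x1, x2) = exp(-gamma * ||x1 - x2||^2)`, in (0, 1].
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param gamma positive kernel width parameter.
#' @return kernel value.
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), 1)  # exp(-1)
rbf_kernel <- function(x1, x2, gamma) {
  if (length(x1) != length(x2)) stop("dimension mismatch", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0",
                                             call. = FALSE)
  exp(-gamma * sum((x1 - x2)^2))
}

# Cross-kernel matrix K[i, j] = exp(-gamma ||A_i - B_j||^2).
rbf_kernel_matrix <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' SVM training configuration
#'
#' Holds a fixed (C, gamma) pair plus the candidate grid, fold count and
#' seed used by [grid_search_cv()] and [cross_validate()]. The default grid
#' is the canonical coarse LIBSVM-style grid `C = 2^(-5, -3, ..., 15)`,
#' `gamma = 2^(-15, -13, ..., 3)`.
#'
#' @param C,gamma fixed parameters used when no search is run.
#' @param grid_C,grid_gamma candidate values for the grid search.
#' @param folds number of stratified CV folds (default 10).
#' @param seed integer seed driving fold assignment.
#' @return an object of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = NULL,
                       grid_C = 2^seq(-5, 15, by = 2),
                       grid_gamma = 2^seq(-15, 3, by = 2),
                       folds = 10, seed = 1) {
  stopifnot(C > 0, is.null(gamma) || gamma > 0, all(grid_C > 0),
            all(grid_gamma > 0), folds >= 2)
  structure(list(C = C, gamma = gamma, grid_C = sort(grid_C),
                 grid_gamma = sort(grid_gamma), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "svm_config")
}

# Coerce labels to +/-1 with "positive"/1/TRUE as the positive class.
svm_labels <- function(labels) {
  if (is.character(labels)) y <- ifelse(labels == "positive", 1, -1)
  else if (is.logical(labels)) y <- ifelse(labels, 1, -1)
  else if (is.factor(labels)) y <- ifelse(labels == levels(labels)[2L], 1, -1)
  else y <- ifelse(labels > 0, 1, -1)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  y
}

#' Train an RBF C-SVC
#'
#' Min-max scales each feature to \[0, 1\] using training bounds (stored in
#' the model and re-applied at prediction time), then solves the soft-margin
#' dual by deterministic SMO. Constant features scale to 0.
#'
#' @param matrix numeric feature matrix with column names.
#' @param labels two-class labels (`"positive"`/`"negative"`, logical, 0/1
#'   or +/-1).
#' @param C soft-margin cost parameter.
#' @param gamma RBF width; default `1 / ncol(matrix)`.
#' @param tol SMO stopping tolerance on the KKT violation (default 1e-3).
#' @return an object of class `rbf_svm` holding support vectors (scaled),
#'   dual coefficients, intercept, scaling bounds and feature names.
#' @export
svm_fit <- function(matrix, labels, C = 1, gamma = 1 / ncol(matrix),
                    tol = 1e-3) {
  if (is.null(colnames(matrix))) stop("matrix must have column names",
                                      call. = FALSE)
  y <- svm_labels(labels)
  lo <- apply(matrix, 2L, min)
  hi <- apply(matrix, 2L, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(matrix, 2L, lo), 2L, rng, "/")
  fit <- .smo_train(Xs, y, C, gamma, tol, max_iter = 5e5)
  if (!fit$converged) {
    warning("SMO hit the iteration cap before reaching tolerance ", tol,
            call. = FALSE)
  }
  sv <- fit$alpha > 1e-12
  structure(list(C = C, gamma = gamma,
                 features = colnames(matrix),
                 scale_min = lo, scale_range = rng,
                 sv = Xs[sv, , drop = FALSE],
                 coef = fit$alpha[sv] * y[sv],
                 b = fit$b,
                 n_sv = sum(sv),
                 iterations = fit$iterations),
            class = "rbf_svm")
}

#' @export
print.rbf_svm <- function(x, ...) {
  cat("rbf_svm: C =", format(x$C), " gamma =", format(x$gamma),
      " support vectors =", x$n_sv, "/", length(x$features), "features\n")
  invisible(x)
}

#' Decision values of a trained SVM
#'
#' `f(x) = sum_i coef_i K(sv_i, x) + b`; the predicted class is positive
#' when `f(x) > 0`. Columns must carry exactly the model's feature names in
#' order.
#'
#' @param model an `rbf_svm`.
#' @param matrix feature matrix with matching column names.
#' @return numeric vector of decision values, one per row.
#' @export
decision_values <- function(model, matrix) {
  stopifnot(inherits(model, "rbf_svm"))
  if (is.null(dim(matrix))) matrix <- t(as.matrix(matrix))
  if (!identical(colnames(matrix), model$features)) {
    missing <- setdiff(model$features, colnames(matrix))
    extra <- setdiff(colnames(matrix), model$features)
    stop("feature mismatch; missing: ",
         paste(missing, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "), "; (order must also match)",
         call. = FALSE)
  }
  Xs <- sweep(sweep(matrix, 2L, model$scale_min), 2L, model$scale_range, "/")
  drop(rbf_kernel_matrix(Xs, model$sv, model$gamma) %*% model$coef + model$b)
}

#' @export
predict.rbf_svm <- function(object, newdata, ...) {
  scores <- decision_values(object, newdata)
  ifelse(scores > 0, "positive", "negative")
}

# Stratified fold assignment: shuffles each class under the seed and deals
# round-robin into folds. Returns an integer fold id per sample.
stratified_folds <- function(labels, folds, seed) {
  y <- svm_labels(labels)
  id <- integer(length(y))
  with_seed(seed, {
    for (cls in c(1, -1)) {
      ix <- sample(which(y == cls))
      id[ix] <- rep_len(seq_len(folds), length(ix))
    }
  })
  if (any(tabulate(id, folds) < 1L)) {
    stop("some folds are empty; reduce the fold count", call. = FALSE)
  }
  id
}

#' Grid search for (C, gamma) under cross-validated ROC AUC
#'
#' Exhaustively evaluates every pair of `config$grid_C` x
#' `config$grid_gamma` by stratified `config$folds`-fold cross-validation
#' (folds fixed across the grid, seeded) and returns the pair with the
#' highest mean out-of-fold AUC. Ties resolve to the smaller C, then the
#' smaller gamma.
#'
#' @param matrix feature matrix with column names.
#' @param labels two-class labels.
#' @param config an [svm_config()].
#' @return list with `best_C`, `best_gamma`, `cv_auc` and `grid` (a data
#'   frame of all evaluated points).
#' @export
grid_search_cv <- function(matrix, labels, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  if (nrow(matrix) < config$folds) {
    stop("fewer samples than folds", call. = FALSE)
  }
  fold <- stratified_folds(labels, config$folds, config$seed)
  grid <- expand.grid(C = config$grid_C, gamma = config$grid_gamma,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), , drop = FALSE]
  grid$cv_auc <- NA_real_
  best <- list(auc = -Inf, C = NA_real_, gamma = NA_real_)
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(seq_len(config$folds), function(f) {
      tr <- fold != f
      m <- svm_fit(matrix[tr, , drop = FALSE], labels[tr],
                   C = grid$C[g], gamma = grid$gamma[g])
      s <- decision_values(m, matrix[!tr, , drop = FALSE])
      roc_auc(labels[!tr], s)$auc
    }, 0)
    grid$cv_auc[g] <- mean(aucs)
    if (grid$cv_auc[g] > best$auc) {
      best <- list(auc = grid$cv_auc[g], C = grid$C[g], gamma = grid$gamma[g])
    }
  }
  list(best_C = best$C, best_gamma = best$gamma, cv_auc = best$auc,
       grid = grid)
}
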