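# Top-level fit: the full training pipeline as one modelling function
# returning a classed object, plus persistence and prediction on new
# sequences.

#' Fit an arginine methylation site predictor
#'
#' Runs the complete training pipeline on annotated proteins:
#' \enumerate{
#'   \item extract arginine-centered windows of `window_length`;
#'   \item reduce redundancy in the positive and unlabeled sets (greedy,
#'     `identity_threshold`); derive pseudo-negatives by removing unlabeled
#'     windows similar to any positive;
#'   \item split 4:1 into training/test with an equal-sized negative test
#'     set; draw `n_negative_subsets` balanced (1:1) negative training
#'     subsets;
#'   \item fit the positional frequency table on positive training windows
#'     and encode all sets (`10 * L + 4` features);
#'   \item per negative subset: rank features by information gain, sweep
#'     incremental subsets (`feature_step`), and grid-search (C, gamma)
#'     under stratified cross-validated AUC;
#'   \item retain the candidate with the highest CV AUC, refit it on its
#'     full training set, and evaluate on the held-out test set.
#' }
#'
#' @param proteins an `annotated_proteins` object.
#' @param window_length odd window length (default 19, the best-performing
#'   length in the selection sweep).
#' @param identity_threshold redundancy/identity cut-off (default 0.4).
#' @param n_negative_subsets balanced negative subsets (default 5).
#' @param feature_step increment of the feature-subset sweep (default 50).
#' @param subset_sizes optional explicit feature-subset sizes (overrides
#'   the step-based sweep).
#' @param config an [svm_config()]. The pipeline default uses a condensed
#'   grid (`C = 2^(-3..7)`, `gamma = 2^(-11..-3)`) for desk-scale runtime;
#'   pass `svm_config()` for the full canonical grid.
#' @param provider ASA/disorder [default_property_provider()] or a custom
#'   provider honouring the same contract.
#' @param seed integer seed driving the split, the subsets and the CV folds.
#' @return an object of class `metharg`; see [predict.metharg()],
#'   [summary.metharg()], [plot.metharg()].
#' @export
metharg <- function(proteins, window_length = 19,
                    identity_threshold = 0.4,
                    n_negative_subsets = 5,
                    feature_step = 50,
                    subset_sizes = NULL,
                    config = svm_config(grid_C = 2^seq(-3, 7, by = 2),
                                        grid_gamma = 2^seq(-11, -3, by = 2)),
                    provider = default_property_provider(),
                    seed = 1) {
  stopifnot(inherits(proteins, "annotated_proteins"),
            inherits(config, "svm_config"))
  window_length <- check_window_length(window_length)
  cl <- match.call()

  windows <- extract_windows(proteins, window_length)
  positives <- reduce_redundancy(
    windows[windows$label == "positive", , drop = FALSE] |>
      recast_windows(window_length), identity_threshold)
  unlabeled <- reduce_redundancy(
    windows[windows$label == "unlabeled", , drop = FALSE] |>
      recast_windows(window_length), identity_threshold)
  negatives <- derive_negatives(unlabeled, positives, identity_threshold)

  split <- split_dataset(positives, negatives, seed = seed)
  n_train_pos <- nrow(split$train_pos)
  subsets <- make_negative_subsets(split$train_neg, n_train_pos,
                                   k = n_negative_subsets, seed = seed + 1L)

  freq <- fit_positional_frequency(split$train_pos)
  enc <- function(w) encode_windows(w, freq, provider)
  X_train_pos <- enc(split$train_pos)
  X_test <- rbind(enc(split$test_pos), enc(split$test_neg))
  y_test <- c(rep("positive", nrow(split$test_pos)),
              rep("negative", nrow(split$test_neg)))

  sweep_rows <- list()
  best <- list(cv_auc = -Inf)
  rankings <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    X_train <- rbind(X_train_pos, enc(subsets[[s]]))
    y_train <- c(rep("positive", n_train_pos),
                 rep("negative", nrow(subsets[[s]])))
    ranking <- rank_features(X_train, y_train)
    if (!nrow(ranking$entries)) {
      # uninformative data: every feature pruned; fall back to the full
      # canonical feature list so a model can still be fit (and honestly
      # sit at chance)
      ranking$entries <- data.frame(feature = colnames(X_train),
                                    score = 0, stringsAsFactors = FALSE)
      ranking$pruned <- character()
    }
    rankings[[s]] <- ranking
    sizes <- if (is.null(subset_sizes)) {
      vapply(incremental_subsets(ranking, feature_step), length, 1L)
    } else {
      pmin(subset_sizes, nrow(ranking$entries))
    }
    for (sz in unique(sizes)) {
      feats <- ranking$entries$feature[seq_len(sz)]
      gs <- grid_search_cv(X_train[, feats, drop = FALSE], y_train, config)
      model <- svm_fit(X_train[, feats, drop = FALSE], y_train,
                       C = gs$best_C, gamma = gs$best_gamma)
      scores <- decision_values(model, X_test[, feats, drop = FALSE])
      rep_t <- confusion_metrics(y_test, scores > 0)
      test_auc <- roc_auc(y_test, scores)$auc
      sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
        window_length = window_length, subset_size = sz, negative_subset = s,
        C = gs$best_C, gamma = gs$best_gamma, cv_auc = gs$cv_auc,
        Sn = rep_t$Sn, Sp = rep_t$Sp, Acc = rep_t$Acc, MCC = rep_t$MCC,
        test_auc = test_auc)
      if (gs$cv_auc > best$cv_auc) {
        best <- list(cv_auc = gs$cv_auc, model = model, features = feats,
                     subset = s, subset_size = sz, scores = scores,
                     report = rep_t, test_auc = test_auc)
      }
    }
  }
  best$report$auc <- best$test_auc
  roc <- roc_auc(y_test, best$scores)$roc

  structure(list(call = cl, window_length = window_length,
                 identity_threshold = identity_threshold,
                 seed = seed, config = config,
                 frequency_table = freq, provider = provider,
                 rankings = rankings,
                 sweep = do.call(rbind, sweep_rows),
                 selected_features = best$features,
                 negative_subset = best$subset,
                 svm = best$model,
                 cv_auc = best$cv_auc,
                 test_report = best$report,
                 test_roc = roc,
                 n_train = c(positive = n_train_pos,
                             negative_pool = nrow(split$train_neg)),
                 n_test = c(positive = nrow(split$test_pos),
                            negative = nrow(split$test_neg))),
            class = "metharg")
}

# Re-attach window_set class after data.frame subsetting.
recast_windows <- function(df, window_length) {
  window_set(df$peptide, df$label, df$protein_id, df$center_position,
             window_length)
}

#' @export
print.metharg <- function(x, ...) {
  cat("metharg model (arginine methylation site predictor)\n")
  cat("  window length:", x$window_length,
      " selected features:", length(x$selected_features),
      " (negative subset", x$negative_subset, ")\n")
  cat("  SVM: C =", format(x$svm$C), " gamma =", format(x$svm$gamma),
      " CV AUC =", sprintf("%.4f", x$cv_auc), "\n")
  cat(sprintf("  held-out test: Sn=%.3f Sp=%.3f Acc=%.3f MCC=%.3f AUC=%.4f\n",
              x$test_report$Sn, x$test_report$Sp, x$test_report$Acc,
              x$test_report$MCC, x$test_report$auc))
  invisible(x)
}

#' Summary of a fitted metharg model
#'
#' @param object a `metharg` fit.
#' @param ... unused.
#' @return the sweep data frame (one row per feature-subset size x negative
#'   subset), invisibly; printed together with the chosen configuration.
#' @export
summary.metharg <- function(object, ...) {
  print(object)
  cat("\nTraining sizes:", object$n_train["positive"], "positives,",
      object$n_train["negative_pool"], "negative pool;",
      "test:", object$n_test["positive"], "per class\n")
  cat("\nSelection sweep (CV AUC per subset size and negative subset):\n")
  print(object$sweep, row.names = FALSE, digits = 4)
  cat("\nTop 10 selected features:\n  ")
  cat(paste(utils::head(object$selected_features, 10L), collapse = ", "),
      "\n")
  invisible(object$sweep)
}

#' Plot the held-out ROC curve of a metharg fit
#'
#' @param x a `metharg` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metharg <- function(x, ...) {
  graphics::plot(x$test_roc$fpr, x$test_roc$tpr, type = "l",
                 xlab = "False positive rate (1 - Sp)",
                 ylab = "True positive rate (Sn)",
                 main = sprintf("Held-out ROC (AUC = %.4f)",
                                x$test_report$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Predict methylation sites on new sequences
#'
#' Scores every arginine of the supplied proteins: extracts its window,
#' encodes it with the model's stored frequency table and provider, and
#' applies the trained SVM restricted to the selected features. Sites score
#' `"positive"` at decision values above 0.
#'
#' @param object a `metharg` fit.
#' @param newdata an `annotated_proteins` object, a named character vector
#'   of sequences, or a FASTA file path.
#' @param ... unused.
#' @return data frame with columns `protein_id`, `position`, `window`,
#'   `score`, `label`; zero rows if no arginine is present.
#' @export
predict.metharg <- function(object, newdata, ...) {
  if (is.character(newdata) && length(newdata) == 1L && file.exists(newdata)) {
    seqs <- Biostrings::readAAStringSet(newdata)
    if (!length(seqs)) stop("empty FASTA: ", newdata, call. = FALSE)
    sequences <- toupper(as.character(seqs))
    names(sequences) <- sub("\\s.*$", "", names(seqs))
    newdata <- annotated_proteins(sequences)
  } else if (is.character(newdata)) {
    if (is.null(names(newdata))) {
      names(newdata) <- sprintf("query_%d", seq_along(newdata))
    }
    newdata <- annotated_proteins(toupper(newdata))
  }
  stopifnot(inherits(newdata, "annotated_proteins"))
  windows <- extract_windows(newdata, object$window_length)
  empty <- data.frame(protein_id = character(), position = integer(),
                      window = character(), score = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  if (!nrow(windows)) return(empty)
  X <- encode_windows(windows, object$frequency_table, object$provider)
  scores <- decision_values(object$svm,
                            X[, object$selected_features, drop = FALSE])
  data.frame(protein_id = windows$protein_id,
             position = windows$center_position,
             window = windows$peptide,
             score = scores,
             label = ifelse(scores > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Save / load a metharg model
#'
#' Serializes the fitted model as a single self-describing JSON archive
#' (configuration, selected feature names, scaling bounds, dual
#' coefficients, support vectors and the positional frequency table) at
#' full double precision, so restored models reproduce decision values to
#' machine accuracy. The property provider is stored by name; custom
#' providers must be re-attached after loading.
#'
#' @param model a `metharg` fit.
#' @param path output/input file path.
#' @return `write_metharg` returns `path` invisibly; `read_metharg` returns
#'   a `metharg` object usable with [predict.metharg()].
#' @export
write_metharg <- function(model, path) {
  stopifnot(inherits(model, "metharg"))
  payload <- list(
    format = "metharg-model", version = 1L,
    window_length = model$window_length,
    seed = model$seed,
    selected_features = model$selected_features,
    svm = list(C = model$svm$C, gamma = model$svm$gamma,
               features = model$svm$features,
               scale_min = as.numeric(model$svm$scale_min),
               scale_range = as.numeric(model$svm$scale_range),
               sv = model$svm$sv, coef = model$svm$coef, b = model$svm$b),
    frequency_table = list(values = unclass(model$frequency_table),
                           rows = rownames(model$frequency_table),
                           cols = colnames(model$frequency_table)),
    provider = model$provider$name,
    test_report = model$test_report[c("tp", "tn", "fp", "fn", "Sn", "Sp",
                                      "Acc", "MCC", "auc")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_metharg
#' @export
read_metharg <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "metharg-model")) {
    stop("not a metharg model archive: ", path, call. = FALSE)
  }
  as_matrix <- function(v, ncol) {
    if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
    if (is.null(dim(v))) v <- matrix(as.numeric(v), ncol = ncol)
    v
  }
  freq <- as_matrix(p$frequency_table$values,
                    length(p$frequency_table$cols))
  dimnames(freq) <- list(p$frequency_table$rows, p$frequency_table$cols)
  class(freq) <- c("positional_frequency", class(freq))
  sv <- as_matrix(p$svm$sv, length(p$svm$features))
  colnames(sv) <- p$svm$features
  svm <- structure(list(C = p$svm$C, gamma = p$svm$gamma,
                        features = p$svm$features,
                        scale_min = stats::setNames(p$svm$scale_min,
                                                    p$svm$features),
                        scale_range = stats::setNames(p$svm$scale_range,
                                                      p$svm$features),
                        sv = sv, coef = p$svm$coef, b = p$svm$b,
                        n_sv = nrow(sv)),
                   class = "rbf_svm")
  structure(list(window_length = as.integer(p$window_length),
                 seed = p$seed,
                 selected_features = p$selected_features,
                 svm = svm, frequency_table = freq,
                 provider = default_property_provider(),
                 test_report = p$test_report),
            class = "metharg")
}
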