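# Feature relevance: information gain with supervised MDL discretization,
# zero-score pruning, and incremental subset construction.

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Best binary split of a sorted label vector by the Fayyad-Irani MDL
# criterion. `y` is an integer class vector sorted by feature value,
# `vals` the sorted values. Returns the accepted cut index (split after
# position i) or 0L if MDL rejects every cut.
mdl_best_cut <- function(vals, y, n_classes) {
  n <- length(y)
  cand <- which(diff(vals) > 0)           # cuts only between distinct values
  if (!length(cand)) return(0L)
  tab <- vapply(sort(unique(y)), function(k) cumsum(y == k),
                numeric(n))               # n x classes cumulative counts
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = n)
  total <- tab[n, ]
  hs <- entropy_bits(total)
  ent_left <- apply(tab[cand, , drop = FALSE], 1L, entropy_bits)
  right <- sweep(tab[cand, , drop = FALSE], 2L, total, function(a, b) b - a)
  ent_right <- apply(right, 1L, entropy_bits)
  nl <- cand
  went <- (nl * ent_left + (n - nl) * ent_right) / n
  best <- which.min(went)
  gain <- hs - went[best]
  k1 <- sum(tab[cand[best], ] > 0)
  k2 <- sum(right[best, ] > 0)
  k <- sum(total > 0)
  delta <- log2(3^k - 2) -
    (k * hs - k1 * ent_left[best] - k2 * ent_right[best])
  if (gain <= (log2(n - 1) + delta) / n) return(0L)
  cand[best]
}

# Recursive Fayyad-Irani MDL discretization; returns cut values (midpoints).
mdl_cuts <- function(values, y) {
  ord <- order(values)
  vals <- values[ord]; ys <- y[ord]
  n_classes <- length(unique(y))
  rec <- function(lo, hi) {
    if (hi - lo < 1L) return(numeric())
    i <- mdl_best_cut(vals[lo:hi], ys[lo:hi], n_classes)
    if (i == 0L) return(numeric())
    cut <- (vals[lo + i - 1L] + vals[lo + i]) / 2
    c(rec(lo, lo + i - 1L), cut, rec(lo + i, hi))
  }
  rec(1L, length(vals))
}

#' Information gain of one feature for a binary class
#'
#' Reduction in class entropy (bits, log2) achieved by conditioning on the
#' discretized feature: `H(Y) - H(Y | bin(X))`. Features with at most two
#' distinct values are used as their own bins; continuous features are
#' discretized by recursive Fayyad-Irani MDL splitting, and a feature for
#' which MDL accepts no cut scores exactly 0 ("irrelevant"). For binary
#' labels the score lies in \[0, 1\].
#'
#' @param values numeric feature vector.
#' @param labels class labels (two classes, both present).
#' @return information gain in bits.
#' @export
#' @examples
#' info_gain(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1: perfect balanced separator
info_gain <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop("values and labels differ in length", call. = FALSE)
  }
  if (length(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  y <- as.integer(factor(labels))
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class", call. = FALSE)
  }
  ux <- unique(values)
  if (length(ux) <= 1L) return(0)
  if (length(ux) <= 2L) {
    bins <- match(values, sort(ux))
  } else {
    cuts <- mdl_cuts(values, y)
    if (!length(cuts)) return(0)
    bins <- findInterval(values, sort(cuts))
  }
  hy <- entropy_bits(table(y))
  cond <- 0
  n <- length(y)
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + sum(sel) / n * entropy_bits(table(y[sel]))
  }
  max(0, hy - cond)
}

#' Rank features by information gain
#'
#' Scores every column of a feature matrix with [info_gain()], removes
#' zero-score (irrelevant) features, and sorts the remainder by descending
#' score. Ties keep the canonical column order (family-major,
#' position-minor), so rankings are reproducible.
#'
#' @param matrix numeric feature matrix with column names.
#' @param labels binary class labels, one per row.
#' @return an object of class `feature_ranking`: a list with `entries`
#'   (data frame `feature`, `score`, descending) and `pruned` (character
#'   vector of zero-score feature names).
#' @export
rank_features <- function(matrix, labels) {
  if (nrow(matrix) != length(labels)) {
    stop("matrix rows and labels differ in length", call. = FALSE)
  }
  if (is.null(colnames(matrix))) stop("matrix must have column names",
                                      call. = FALSE)
  scores <- vapply(seq_len(ncol(matrix)), function(j) {
    info_gain(matrix[, j], labels)
  }, 0)
  names(scores) <- colnames(matrix)
  zero <- scores == 0
  kept <- scores[!zero]
  ord <- order(-kept)                      # stable: ties keep column order
  structure(list(entries = data.frame(feature = names(kept)[ord],
                                      score = unname(kept[ord]),
                                      stringsAsFactors = FALSE),
                 pruned = names(scores)[zero]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("feature_ranking:", nrow(x$entries), "retained,",
      length(x$pruned), "pruned (zero gain)\n")
  print(utils::head(x$entries, 10L))
  invisible(x)
}

#' Incremental feature subsets from a ranking
#'
#' Prefixes of the retained ranking of sizes `step`, `2*step`, ... up to the
#' full retained set; a final partial prefix is included. Used for the
#' incremental feature-selection sweep.
#'
#' @param ranking a `feature_ranking`.
#' @param step subset size increment (default 50).
#' @return list of character vectors of feature names; element k is always a
#'   superset of element k-1.
#' @export
incremental_subsets <- function(ranking, step = 50) {
  stopifnot(inherits(ranking, "feature_ranking"))
  feats <- ranking$entries$feature
  if (!length(feats)) stop("empty ranking", call. = FALSE)
  if (!is.numeric(step) || step < 1) stop("step must be >= 1", call. = FALSE)
  sizes <- if (length(feats) >= step) {
    seq.int(step, length(feats), by = step)
  } else {
    integer()
  }
  sizes <- unique(c(sizes, length(feats)))
  lapply(sizes, function(s) feats[seq_len(s)])
}
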