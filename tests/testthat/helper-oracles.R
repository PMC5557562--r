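# Independent oracles used by the tests. These deliberately do not share
# code with the package implementation.

# Brute-force C-SVC dual solve: cyclic sweeps over every index pair with the
# analytic two-variable update, until no alpha moves. Returns training-set
# decision values. Applies the same min-max scaling contract as svm_fit.
oracle_svm_scores <- function(X, y, C, gamma, max_sweeps = 20000) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(X, 2, lo), 2, rng, "/")
  K <- exp(-gamma * as.matrix(stats::dist(Xs))^2)
  n <- nrow(Xs)
  a <- numeric(n)
  G <- rep(-1, n)                       # gradient of 0.5 a'Qa - e'a
  Q <- outer(y, y) * K
  for (s in seq_len(max_sweeps)) {
    moved <- 0
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta < 1e-12) eta <- 1e-12
      # direction: a_i += y_i t, a_j -= y_j t (keeps y'a fixed)
      t_opt <- (y[j] * G[j] - y[i] * G[i]) / eta
      t_lo <- max(if (y[i] > 0) -a[i] else a[i] - C,
                  if (y[j] > 0) a[j] - C else -a[j])
      t_hi <- min(if (y[i] > 0) C - a[i] else a[i],
                  if (y[j] > 0) a[j] else C - a[j])
      t_cl <- min(max(t_opt, t_lo), t_hi)
      if (abs(t_cl) < 1e-14) next
      dai <- y[i] * t_cl; daj <- -y[j] * t_cl
      a[i] <- a[i] + dai; a[j] <- a[j] + daj
      G <- G + Q[, i] * dai + Q[, j] * daj
      moved <- max(moved, abs(t_cl))
    }
    if (moved < 1e-12) break
  }
  free <- a > 1e-8 & a < C - 1e-8
  if (any(free)) {
    b <- mean(-y[free] * G[free])
  } else {
    up <- ifelse(y > 0, a < C - 1e-8, a > 1e-8)
    lo_ <- ifelse(y > 0, a > 1e-8, a < C - 1e-8)
    b <- (max((-y * G)[up]) + min((-y * G)[lo_])) / 2
  }
  drop(K %*% (a * y) + b)
}

# Independent greedy redundancy reduction driven by the scalar
# window_identity() definition.
oracle_greedy_reduce <- function(peptides, threshold) {
  keep <- integer()
  for (i in seq_along(peptides)) {
    ok <- TRUE
    for (k in keep) {
      if (window_identity(peptides[i], peptides[k]) >= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}

# Mann-Whitney AUC with ties counted 1/2, by explicit pair enumeration.
oracle_mw_auc <- function(labels, scores) {
  pos <- scores[labels == "positive" | labels == 1 | labels == TRUE]
  neg <- scores[!(labels == "positive" | labels == 1 | labels == TRUE)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Shannon entropy (bits) of a label vector.
oracle_entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Random R-centered peptides over a small alphabet (high collision rate so
# redundancy filters actually trigger).
random_windows <- function(n, L, alphabet = c("A", "G", "S", "X")) {
  half <- (L - 1) / 2
  vapply(seq_len(n), function(i) {
    chars <- sample(alphabet, L, replace = TRUE)
    chars[half + 1] <- "R"
    paste(chars, collapse = "")
  }, "")
}
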