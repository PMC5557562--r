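# Small fixture builders.

# One protein of given residues (padded with alanine to >= 30 aa).
tiny_protein <- function(seq, sites = integer(), id = "p1", pad_to = 30) {
  if (nchar(seq) < pad_to) {
    seq <- paste0(seq, strrep("A", pad_to - nchar(seq)))
  }
  annotated_proteins(stats::setNames(seq, id),
                     if (length(sites)) stats::setNames(list(sites), id)
                     else list())
}

# A window_set built directly from peptide strings.
ws_from_peptides <- function(peptides, label = "unlabeled") {
  window_set(peptides, rep(label, length(peptides)),
             sprintf("w%d", seq_along(peptides)),
             seq_along(peptides), nchar(peptides[1]))
}

# Two well-separated Gaussian clusters, for separable-SVM tests.
separable_toy <- function(n_per_class, d = 2, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = rep(c("positive", "negative"), each = n_per_class))
}
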