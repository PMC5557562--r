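# Dataset construction: annotated proteins, arginine-centered peptide
# windows, identity-based redundancy reduction, pseudo-negative derivation,
# train/test splitting and balanced negative subsets.

#' Read annotated proteins from FASTA plus a site table
#'
#' Loads protein sequences and a table of experimentally verified methylated
#' arginine positions. Each site row must name a FASTA record and a 1-based
#' position that carries an `R` in that sequence; violations are hard errors.
#' Records shorter than 30 residues (small fragments) are dropped with a
#' warning, mirroring the curation rule the training data assume.
#'
#' @param fasta_path path to a FASTA file (multi-line records allowed).
#' @param sites_path path to a tab-separated table with header columns
#'   `protein_id` and `position` (1-based).
#' @return an object of class `annotated_proteins`: a list of records, each
#'   with `id`, `sequence` and sorted integer `methylated_positions`.
#' @export
read_annotated_proteins <- function(fasta_path, sites_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- toupper(as.character(seqs))
  names(sequences) <- ids
  sites <- utils::read.delim(sites_path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "position") %in% names(sites))) {
    stop("site table must have columns protein_id and position", call. = FALSE)
  }
  sites$position <- as.integer(sites$position)
  missing <- setdiff(unique(sites$protein_id), ids)
  if (length(missing)) {
    stop("site table references FASTA IDs not present: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  annotated_proteins(sequences, split(sites$position, sites$protein_id))
}

#' Construct annotated proteins from in-memory sequences
#'
#' @param sequences named character vector of upper-case amino-acid sequences.
#' @param sites named list mapping protein IDs to integer vectors of 1-based
#'   methylated arginine positions; IDs absent from the list get no sites.
#' @return `annotated_proteins` object.
#' @export
annotated_proteins <- function(sequences, sites = list()) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  ids <- names(sequences)
  extra <- setdiff(names(sites), ids)
  if (length(extra)) {
    stop("sites given for unknown proteins: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  recs <- vector("list", length(ids))
  keep <- logical(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    seqk <- sequences[[k]]
    pos <- sort(unique(as.integer(sites[[id]])))
    if (length(pos)) {
      bad <- pos < 1L | pos > nchar(seqk)
      if (any(bad)) {
        stop("position ", pos[bad][1], " of ", id, " is out of range",
             call. = FALSE)
      }
      res <- substring(seqk, pos, pos)
      notR <- res != "R"
      if (any(notR)) {
        stop("position ", pos[notR][1], " of ", id, " is not R (found ",
             res[notR][1], ")", call. = FALSE)
      }
    }
    if (nchar(seqk) < 30L) {
      warning("dropping ", id, ": sequence shorter than 30 aa", call. = FALSE)
      next
    }
    keep[k] <- TRUE
    recs[[k]] <- list(id = id, sequence = seqk, methylated_positions = pos)
  }
  structure(recs[keep], class = "annotated_proteins")
}

#' @export
print.annotated_proteins <- function(x, ...) {
  nsites <- sum(vapply(x, function(p) length(p$methylated_positions), 1L))
  cat("annotated_proteins:", length(x), "proteins,", nsites,
      "methylated arginine sites\n")
  invisible(x)
}

#' Write annotated proteins to FASTA plus a site table
#'
#' Inverse of [read_annotated_proteins()]; the synthetic generator uses this
#' so that tests exercise the real readers.
#'
#' @param proteins `annotated_proteins` object.
#' @param fasta_path,sites_path output paths.
#' @return invisibly, the input.
#' @export
write_annotated_proteins <- function(proteins, fasta_path, sites_path) {
  stopifnot(inherits(proteins, "annotated_proteins"))
  seqs <- Biostrings::AAStringSet(
    stats::setNames(vapply(proteins, `[[`, "", "sequence"),
                    vapply(proteins, `[[`, "", "id")))
  Biostrings::writeXStringSet(seqs, fasta_path)
  tab <- do.call(rbind, lapply(proteins, function(p) {
    if (!length(p$methylated_positions)) return(NULL)
    data.frame(protein_id = p$id, position = p$methylated_positions,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(protein_id = character(), position = integer())
  }
  utils::write.table(tab, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(proteins)
}

#' Construct a peptide window set
#'
#' A window set is a data frame with columns `peptide`, `label`
#' (`"positive"`, `"unlabeled"` or `"negative"`), `protein_id` and
#' `center_position`, plus a `window_length` attribute. All peptides share
#' the odd window length and are centered on an arginine.
#'
#' @param peptide character vector of equal-length odd peptides.
#' @param label character vector of labels.
#' @param protein_id,center_position provenance columns.
#' @param window_length the shared odd length.
#' @return a `window_set` data frame.
#' @export
window_set <- function(peptide, label, protein_id, center_position,
                       window_length) {
  window_length <- check_window_length(window_length)
  stopifnot(all(nchar(peptide) == window_length),
            all(label %in% c("positive", "unlabeled", "negative")))
  half <- (window_length + 1L) %/% 2L
  if (length(peptide) && any(substring(peptide, half, half) != "R")) {
    stop("window center must be R", call. = FALSE)
  }
  out <- data.frame(peptide = as.character(peptide),
                    label = as.character(label),
                    protein_id = as.character(protein_id),
                    center_position = as.integer(center_position),
                    stringsAsFactors = FALSE)
  attr(out, "window_length") <- window_length
  class(out) <- c("window_set", "data.frame")
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set: ", nrow(x), " peptides of length ",
      attr(x, "window_length"), " (",
      paste(names(table(x$label)), table(x$label), sep = ":",
            collapse = ", "), ")\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

window_length_of <- function(windows) {
  L <- attr(windows, "window_length")
  if (is.null(L)) stop("not a window_set (no window_length)", call. = FALSE)
  L
}

# rbind that preserves the window_set class and length attribute.
bind_windows <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, NROW, 1L) > 0]
  L <- unique(vapply(parts, window_length_of, 1L))
  if (length(L) != 1L) stop("window lengths differ", call. = FALSE)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  window_set(out$peptide, out$label, out$protein_id, out$center_position, L)
}

#' Extract arginine-centered peptide windows
#'
#' Produces exactly one window per `R` residue of each protein: label
#' `"positive"` if the position is annotated as methylated, otherwise
#' `"unlabeled"`. Windows are padded with `X` at protein termini so every
#' peptide is symmetric about its central arginine. Windows that contain a
#' nonstandard residue (B, Z, U, O, J) are dropped with a warning.
#'
#' @param proteins an `annotated_proteins` object (or a single record).
#' @param window_length odd integer >= 7.
#' @return a `window_set`.
#' @export
extract_windows <- function(proteins, window_length) {
  window_length <- check_window_length(window_length)
  if (window_length < 7L) stop("window_length must be >= 7", call. = FALSE)
  if (!inherits(proteins, "annotated_proteins")) {
    proteins <- structure(list(proteins), class = "annotated_proteins")
  }
  half <- (window_length - 1L) %/% 2L
  pep <- character(); lab <- character(); pid <- character(); cen <- integer()
  for (p in proteins) {
    chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
    rpos <- which(chars == "R")
    if (!length(rpos)) next
    padded <- c(rep("X", half), chars, rep("X", half))
    for (r in rpos) {
      w <- paste(padded[r:(r + 2L * half)], collapse = "")
      pep <- c(pep, w)
      lab <- c(lab, if (r %in% p$methylated_positions) "positive"
               else "unlabeled")
      pid <- c(pid, p$id)
      cen <- c(cen, r)
    }
  }
  out <- window_set(pep, lab, pid, cen, window_length)
  bad <- grepl(paste0("[", paste(NONSTANDARD_AA, collapse = ""), "]"),
               out$peptide)
  if (any(bad)) {
    warning("dropping ", sum(bad), " window(s) containing nonstandard ",
            "residues (B/Z/U/O/J)", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
    out <- window_set(out$peptide, out$label, out$protein_id,
                      out$center_position, window_length)
  }
  out
}

#' Ungapped identity between two equal-length peptides
#'
#' Fraction of positions carrying identical residues, with the padding
#' symbol `X` matching nothing (not even another `X`), divided by the full
#' window length. For fixed-length windows this ungapped positional identity
#' stands in for alignment-based clustering identity.
#'
#' @param a,b peptide strings of equal length.
#' @return identity fraction in \[0, 1\].
#' @export
#' @examples
#' window_identity("AAAA", "AAAT")  # 0.75
window_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) stop("peptides differ in length", call. = FALSE)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca == cb & ca != "X")
}

# One-hot encoding of peptides over the 20 standard residues (X rows are
# all-zero, so X matches nothing); identity(i, j) is then the dot product
# of rows divided by window length, computable in bulk via BLAS.
onehot_windows <- function(peptides) {
  mat <- peptide_matrix(peptides)
  n <- nrow(mat); L <- ncol(mat)
  out <- matrix(0, n, L * 20L)
  code <- match(mat, AA20)                 # NA for X
  hit <- which(!is.na(code))
  cols <- (col(mat)[hit] - 1L) * 20L + code[hit]
  out[cbind(row(mat)[hit], cols)] <- 1
  out
}

#' Greedy redundancy reduction within a window set
#'
#' Scans windows in input order and retains a window only if its identity to
#' every previously retained window is below `threshold`. The retained set
#' therefore contains no pair at or above the threshold, emulating
#' 40%-identity clustering for equal-length peptides.
#'
#' @param windows a `window_set`.
#' @param threshold identity threshold in (0, 1\]; default 0.4.
#' @return the retained `window_set` (a subset of the input, input order).
#' @export
reduce_redundancy <- function(windows, threshold = 0.4) {
  if (!nrow(windows)) stop("empty window set", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  L <- window_length_of(windows)
  idm <- tcrossprod(onehot_windows(windows$peptide)) / L
  keep <- integer()
  for (i in seq_len(nrow(windows))) {
    if (!length(keep) || max(idm[i, keep]) < threshold) {
      keep <- c(keep, i)
    }
  }
  out <- windows[keep, , drop = FALSE]
  window_set(out$peptide, out$label, out$protein_id, out$center_position, L)
}

#' Derive the negative set from unlabeled windows
#'
#' Keeps only the unlabeled windows whose identity to every positive window
#' is below `threshold`, and relabels them `"negative"`. This removes
#' unlabeled sites that resemble known methylation contexts (potential
#' not-yet-verified positives).
#'
#' @param unlabeled,positives `window_set`s of equal window length.
#' @param threshold identity threshold in (0, 1\]; default 0.4.
#' @return a `window_set` of negatives.
#' @export
derive_negatives <- function(unlabeled, positives, threshold = 0.4) {
  if (window_length_of(unlabeled) != window_length_of(positives)) {
    stop("window lengths differ between unlabeled and positive sets",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  L <- window_length_of(unlabeled)
  if (!nrow(positives)) {
    keep <- rep(TRUE, nrow(unlabeled))
  } else {
    cross <- onehot_windows(unlabeled$peptide) %*%
      t(onehot_windows(positives$peptide)) / L
    keep <- apply(cross, 1L, max) < threshold
  }
  out <- unlabeled[keep, , drop = FALSE]
  window_set(out$peptide, rep("negative", nrow(out)), out$protein_id,
             out$center_position, L)
}

#' Split positives and negatives into training and test sets
#'
#' The positive set is split 4:1 (test size = `round(n/5)`, remainder to
#' training); an equally sized negative test set is sampled and the
#' remaining negatives form the negative training pool. Reproducible under
#' `seed`.
#'
#' @param positives,negatives `window_set`s of equal window length.
#' @param seed integer seed.
#' @return list with elements `train_pos`, `test_pos`, `train_neg`,
#'   `test_neg`.
#' @export
split_dataset <- function(positives, negatives, seed) {
  if (window_length_of(positives) != window_length_of(negatives)) {
    stop("window lengths differ", call. = FALSE)
  }
  n_pos <- nrow(positives)
  n_test <- round(n_pos / 5)
  # need the equal-sized negative test set plus a nonempty training pool
  if (nrow(negatives) <= n_test) {
    stop("too few negatives (", nrow(negatives), ") for a negative test set ",
         "of size ", n_test, " plus a training pool", call. = FALSE)
  }
  idx <- with_seed(seed, {
    ti_pos <- sample.int(n_pos, n_test)
    ti_neg <- sample.int(nrow(negatives), n_test)
    list(pos = ti_pos, neg = ti_neg)
  })
  subset_ws <- function(w, rows) {
    out <- w[rows, , drop = FALSE]
    window_set(out$peptide, out$label, out$protein_id, out$center_position,
               window_length_of(w))
  }
  list(train_pos = subset_ws(positives, setdiff(seq_len(n_pos), idx$pos)),
       test_pos = subset_ws(positives, sort(idx$pos)),
       train_neg = subset_ws(negatives,
                             setdiff(seq_len(nrow(negatives)), idx$neg)),
       test_neg = subset_ws(negatives, sort(idx$neg)))
}

#' Balanced negative training subsets (1:1 undersampling)
#'
#' Draws `k` subsets of the negative training pool, each of size
#' `n_positive_train` (without replacement within a subset), to balance the
#' classes during training. When the pool size equals the subset size the k
#' subsets are forced to be identical (the whole pool) and a message is
#' emitted.
#'
#' @param train_neg negative training `window_set`.
#' @param n_positive_train size of the positive training set.
#' @param k number of subsets (default 5).
#' @param seed integer seed.
#' @return list of `k` `window_set`s.
#' @export
make_negative_subsets <- function(train_neg, n_positive_train, k = 5,
                                  seed = 1) {
  n <- nrow(train_neg)
  if (n < n_positive_train) {
    stop("negative pool (", n, ") smaller than requested subset size (",
         n_positive_train, ")", call. = FALSE)
  }
  if (n == n_positive_train) {
    message("negative pool equals subset size; the ", k,
            " subsets are identical")
  }
  L <- window_length_of(train_neg)
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      rows <- sort(sample.int(n, n_positive_train))
      out <- train_neg[rows, , drop = FALSE]
      window_set(out$peptide, out$label, out$protein_id, out$center_position,
                 L)
    })
  })
}

#' Write / read a window set as TSV
#'
#' Columns: `peptide`, `label`, `protein_id`, `center_position`,
#' `window_length`.
#'
#' @param windows a `window_set`.
#' @param path file path.
#' @return `write_window_set` returns the input invisibly;
#'   `read_window_set` returns a `window_set`.
#' @export
write_window_set <- function(windows, path) {
  df <- as.data.frame(windows)
  df$window_length <- window_length_of(windows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(windows)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  L <- unique(df$window_length)
  if (length(L) != 1L) stop("mixed window lengths in ", path, call. = FALSE)
  window_set(df$peptide, df$label, df$protein_id, df$center_position, L)
}
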