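# Feature encoding: per-position physicochemical scales, positional amino
# acid frequency, ASA/disorder propensities from a pluggable provider, and
# four whole-peptide features (average van der Waals volume, GRAVY, net
# charge at pH 7, isoelectric point). A window of length L yields 10L + 4
# named features.

FEATURE_FAMILIES <- c("atchley_1", "atchley_2", "atchley_3", "atchley_4",
                      "atchley_5", "aafreq", "asa", "disorder", "hydro",
                      "vdwv")
GLOBAL_FEATURES <- c("avg_vdwv", "gravy", "net_charge", "pI")

#' Canonical feature names for a window length
#'
#' Family-major, position-minor order: all positions of `atchley_1`, then
#' `atchley_2`, ..., then `aafreq`, `asa`, `disorder`, `hydro`, `vdwv`,
#' followed by the four whole-peptide features `avg_vdwv`, `gravy`,
#' `net_charge`, `pI`. Positions are labelled by signed offset from the
#' central arginine, e.g. `atchley_1_-9`, `aafreq_+3`, `asa_0`.
#'
#' @param window_length odd window length L.
#' @return character vector of length `10 * L + 4`.
#' @export
feature_names <- function(window_length) {
  labs <- offset_labels(window_offsets(window_length))
  c(as.vector(t(outer(FEATURE_FAMILIES, labs, paste, sep = "_"))),
    GLOBAL_FEATURES)
}

#' Fit the positional amino-acid frequency table
#'
#' Counts each of the 21 symbols (20 amino acids + `X`) at each window
#' position across the supplied windows and normalizes per position, giving
#' a 21 x L table whose columns each sum to 1. Fit this on the positive
#' *training* windows only, so no test information leaks into the encoding.
#'
#' @param windows a nonempty `window_set` (typically positive training
#'   windows).
#' @return a `positional_frequency` matrix: 21 rows (amino acids + X),
#'   L columns named by signed offset.
#' @export
fit_positional_frequency <- function(windows) {
  if (!nrow(windows)) stop("empty window set", call. = FALSE)
  L <- window_length_of(windows)
  mat <- peptide_matrix(windows$peptide)
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = AA21))
    as.numeric(tab) / nrow(mat)
  }, numeric(length(AA21)))
  dimnames(freq) <- list(AA21, offset_labels(window_offsets(L)))
  class(freq) <- c("positional_frequency", class(freq))
  freq
}

#' Positional-frequency encoding of one peptide
#'
#' Element p of the result is the fitted frequency of the peptide's residue
#' at position p, at that position. Residues unseen at a position during
#' fitting encode as 0; `X` uses the fitted X row.
#'
#' @param peptide peptide string whose length matches the table.
#' @param table a `positional_frequency` matrix from
#'   [fit_positional_frequency()].
#' @return numeric vector of length L.
#' @export
positional_frequency_feature <- function(peptide, table) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (length(chars) != ncol(table)) {
    stop("peptide length ", length(chars), " does not match table width ",
         ncol(table), call. = FALSE)
  }
  table[cbind(match(chars, rownames(table)), seq_along(chars))]
}

#' Whole-peptide scale averages (GRAVY and mean van der Waals volume)
#'
#' Sum-average of the per-residue scale over the non-`X` residues of the
#' peptide; terminal padding does not dilute the average.
#'
#' @param peptide peptide string with at least one non-`X` residue.
#' @return named numeric vector with elements `gravy` and `avg_vdwv`.
#' @export
#' @examples
#' global_scale_features("AAA")[["gravy"]]  # 1.8
global_scale_features <- function(peptide) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  chars <- chars[chars != "X"]
  if (!length(chars)) stop("peptide is all X", call. = FALSE)
  c(gravy = mean(scale_values(chars, aa_scale("kd_hydrophobicity"))),
    avg_vdwv = mean(scale_values(chars, aa_scale("vdw_volume"))))
}

#' Peptide net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the free termini and the ionizable side
#' chains (C, D, E, H, K, R, Y) using the package's embedded simplified
#' Bjellqvist-style pKa set (see `inst/extdata/scales/pka.tsv`). `X`
#' residues are ignored.
#'
#' @param peptide peptide string.
#' @param pH evaluation pH (default 7.0).
#' @return net charge (positive = basic).
#' @export
net_charge <- function(peptide, pH = 7) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  chars <- chars[chars != "X"]
  unknown <- setdiff(unique(chars), AA20)
  if (length(unknown)) {
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pka <- pka_set()
  counts <- c(n_term = 1, c_term = 1,
              table(factor(chars, levels = AA20))[c("C", "D", "E", "H",
                                                    "K", "R", "Y")])
  names(counts) <- c("n_term", "c_term", "C", "D", "E", "H", "K", "R", "Y")
  ix <- match(pka$group, names(counts))
  n <- as.numeric(counts[ix])
  pos <- pka$charge > 0
  # positive groups: +n/(1+10^(pH-pKa)); negative: -n/(1+10^(pKa-pH))
  sum(n[pos] / (1 + 10^(pH - pka$pka[pos]))) -
    sum(n[!pos] / (1 + 10^(pka$pka[!pos] - pH)))
}

#' Peptide isoelectric point
#'
#' The pH in \[0, 14\] at which [net_charge()] crosses zero, found by
#' bisection; net charge is strictly decreasing in pH so the root is unique.
#'
#' @param peptide peptide string.
#' @return pH value with `|net_charge| < 1e-6`.
#' @export
isoelectric_point <- function(peptide) {
  f <- function(pH) net_charge(peptide, pH)
  if (f(0) <= 0 || f(14) >= 0) {
    stop("net charge does not change sign on [0, 14]", call. = FALSE)
  }
  stats::uniroot(f, c(0, 14), tol = 1e-9)$root
}

#' Default ASA / disorder property provider
#'
#' A deterministic, self-contained stand-in for external per-residue
#' structure predictors. It maps each residue to an embedded propensity
#' value (`asa_propensity`: theoretical maximum solvent accessibility;
#' `disorder_propensity`: TOP-IDP), min-max scales each scale to \[0, 1\],
#' assigns 0.5 to `X` positions, and smooths with a symmetric sliding mean
#' of half-width `half_window` (truncated at the peptide ends). Real
#' predictors can replace it through the same contract: a list with `name`
#' and `predict(peptide) -> list(asa=, disorder=)`, both vectors of the
#' peptide's length with values in \[0, 1\].
#'
#' @param half_window smoothing half-width (default 3).
#' @return an object of class `property_provider`.
#' @export
default_property_provider <- function(half_window = 3) {
  scale01 <- function(v) (v - min(v)) / (max(v) - min(v))
  asa <- scale01(aa_scale("asa_propensity"))
  dis <- scale01(aa_scale("disorder_propensity"))
  smooth <- function(x) {
    n <- length(x)
    vapply(seq_len(n), function(i) {
      mean(x[max(1L, i - half_window):min(n, i + half_window)])
    }, 0)
  }
  prov <- list(
    name = sprintf("propensity_smooth_hw%d", as.integer(half_window)),
    predict = function(peptide) {
      chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
      a <- ifelse(chars == "X", 0.5, c(asa, X = 0.5)[chars])
      d <- ifelse(chars == "X", 0.5, c(dis, X = 0.5)[chars])
      if (anyNA(a) || anyNA(d)) {
        stop("unknown residue letter in peptide", call. = FALSE)
      }
      list(asa = smooth(unname(a)), disorder = smooth(unname(d)))
    })
  class(prov) <- "property_provider"
  prov
}

#' Encode peptide windows as a named feature matrix
#'
#' Builds the full feature vector for each window: per position, the five
#' Atchley factors, the positional amino-acid frequency, the provider's ASA
#' and disorder values, Kyte-Doolittle hydropathy and van der Waals volume;
#' then the four whole-peptide features (`avg_vdwv`, `gravy`, `net_charge`
#' at pH 7, `pI`). Total length `10 * L + 4` — 194/234/274/314/354 features
#' for window lengths 19/23/27/31/35.
#'
#' @param windows a `window_set`.
#' @param table `positional_frequency` table fitted on positive training
#'   windows.
#' @param provider a `property_provider`; default
#'   [default_property_provider()].
#' @return numeric matrix, one row per window, columns named by
#'   [feature_names()].
#' @export
encode_windows <- function(windows, table,
                           provider = default_property_provider()) {
  L <- window_length_of(windows)
  if (ncol(table) != L) {
    stop("frequency table width ", ncol(table),
         " does not match window length ", L, call. = FALSE)
  }
  n <- nrow(windows)
  out <- matrix(NA_real_, n, 10L * L + 4L,
                dimnames = list(NULL, feature_names(L)))
  if (!n) return(out)
  mat <- peptide_matrix(windows$peptide)
  cols <- function(fam) paste0(fam, "_", offset_labels(window_offsets(L)))
  for (k in 1:5) {
    out[, cols(paste0("atchley_", k))] <-
      scale_values(mat, aa_scale(paste0("atchley_", k)))
  }
  out[, cols("hydro")] <- scale_values(mat, aa_scale("kd_hydrophobicity"))
  out[, cols("vdwv")] <- scale_values(mat, aa_scale("vdw_volume"))
  for (i in seq_len(n)) {
    pep <- windows$peptide[i]
    out[i, cols("aafreq")] <- positional_frequency_feature(pep, table)
    pr <- provider$predict(pep)
    out[i, cols("asa")] <- pr$asa
    out[i, cols("disorder")] <- pr$disorder
    gs <- global_scale_features(pep)
    out[i, "avg_vdwv"] <- gs[["avg_vdwv"]]
    out[i, "gravy"] <- gs[["gravy"]]
    out[i, "net_charge"] <- net_charge(pep, 7)
    out[i, "pI"] <- isoelectric_point(pep)
  }
  out
}

#' Encode a single peptide window
#'
#' @param peptide peptide string (odd length, R-centered).
#' @param table,provider as in [encode_windows()].
#' @return named numeric vector of length `10 * nchar(peptide) + 4`.
#' @export
encode_window <- function(peptide, table,
                          provider = default_property_provider()) {
  ws <- window_set(peptide, "unlabeled", "query", 1L, nchar(peptide))
  encode_windows(ws, table, provider)[1L, ]
}
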