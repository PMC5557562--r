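# Residue-level physicochemical scales, shipped as auditable TSV resources
# under inst/extdata/scales/ and cached after first load.
#
# atchley_1..atchley_5   five-factor summary of AAIndex physicochemical space
#                        (polarity/accessibility; secondary structure; size;
#                        codon diversity/composition; electrostatic charge)
# kd_hydrophobicity      Kyte-Doolittle hydropathy
# vdw_volume             van der Waals volume (A^3), Darby-Creighton values
# asa_propensity         residue maximum accessible surface area (A^2),
#                        theoretical Gly-X-Gly values; exposure stand-in
# disorder_propensity    TOP-IDP intrinsic disorder propensity

.scale_cache <- new.env(parent = emptyenv())

scale_file <- function(stem) {
  path <- system.file("extdata", "scales", paste0(stem, ".tsv"),
                      package = "metharg")
  if (path == "") stop("scale resource not found: ", stem, call. = FALSE)
  path
}

load_scale_table <- function(stem) {
  if (!exists(stem, envir = .scale_cache)) {
    tab <- utils::read.delim(scale_file(stem), stringsAsFactors = FALSE)
    assign(stem, tab, envir = .scale_cache)
  }
  get(stem, envir = .scale_cache)
}

#' Residue physicochemical scale tables
#'
#' Returns one of the residue-level scales embedded in the package as a named
#' numeric vector over the 20 standard amino acids. Available scales:
#' `atchley_1` ... `atchley_5` (the five-factor physicochemical summary of
#' amino-acid space), `kd_hydrophobicity` (Kyte-Doolittle hydropathy),
#' `vdw_volume` (van der Waals volume), `asa_propensity` (theoretical maximum
#' solvent-accessible surface area, used by the default property provider)
#' and `disorder_propensity` (TOP-IDP disorder propensity).
#'
#' @param name scale identifier, see above.
#' @return named numeric vector of length 20.
#' @export
#' @examples
#' aa_scale("kd_hydrophobicity")[["A"]]  # 1.8
aa_scale <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (grepl("^atchley_[1-5]$", name)) {
    tab <- load_scale_table("atchley")
    v <- tab[[name]]
  } else if (name %in% c("kd_hydrophobicity", "vdw_volume",
                         "asa_propensity", "disorder_propensity")) {
    tab <- load_scale_table(name)
    v <- tab[["value"]]
  } else {
    stop("unknown scale: ", name, call. = FALSE)
  }
  stats::setNames(v, tab[["residue"]])
}

#' Look up a residue in a scale
#'
#' The padding symbol `X` maps to 0 in every scale, so terminal padding
#' carries no physicochemical signal.
#'
#' @param residue single upper-case amino-acid letter (or `X`).
#' @param scale a named numeric vector as returned by [aa_scale()], or a
#'   scale name.
#' @return scale value, or 0 for `X`.
#' @export
residue_scale_lookup <- function(residue, scale) {
  if (is.character(scale) && length(scale) == 1L) scale <- aa_scale(scale)
  stopifnot(is.character(residue), nchar(residue) == 1L)
  if (residue == "X") return(0)
  if (!residue %in% names(scale)) {
    stop("unknown residue letter: ", residue, call. = FALSE)
  }
  unname(scale[[residue]])
}

# Vectorised lookup over a character matrix/vector; X -> 0.
scale_values <- function(residues, scale) {
  v <- c(scale, X = 0)[residues]
  bad <- is.na(v)
  if (any(bad)) {
    stop("unknown residue letter(s): ",
         paste(unique(residues[bad]), collapse = ", "), call. = FALSE)
  }
  out <- unname(v)
  if (is.matrix(residues)) dim(out) <- dim(residues)
  out
}

# pKa set used for net charge and pI: a simplified Bjellqvist-style set with
# constant termini (n_term 7.5, c_term 3.55) and side chains C/D/E/H/K/R/Y.
pka_set <- function() {
  tab <- load_scale_table("pka")
  tab
}
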