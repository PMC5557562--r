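# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")
NONSTANDARD_AA <- c("B", "Z", "U", "O", "J")

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Window position offsets -(L-1)/2 ... +(L-1)/2 and their printed labels
# ("-9", "0", "+3"); position 0 is the central arginine.
window_offsets <- function(window_length) {
  check_window_length(window_length)
  half <- (window_length - 1L) %/% 2L
  seq.int(-half, half)
}

offset_labels <- function(offsets) {
  ifelse(offsets > 0, paste0("+", offsets), as.character(offsets))
}

check_window_length <- function(window_length) {
  if (length(window_length) != 1L || !is.numeric(window_length) ||
      window_length != as.integer(window_length) ||
      window_length < 1 || window_length %% 2 == 0) {
    stop("window_length must be a single odd positive integer, got: ",
         deparse(window_length), call. = FALSE)
  }
  invisible(as.integer(window_length))
}

# Split peptide strings into an n x L character matrix.
peptide_matrix <- function(peptides) {
  if (!length(peptides)) return(matrix(character(), 0L, 0L))
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("peptides differ in length", call. = FALSE)
  matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
         nrow = length(peptides), ncol = L, byrow = TRUE)
}
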