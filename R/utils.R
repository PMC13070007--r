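# Shared constants and small helpers.

# Canonical 20 amino acids, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Display order of the six CDR loops: light chain first, then heavy.
CDR_NAMES <- c("L1", "L2", "L3", "H1", "H2", "H3")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Split character vector of equal-length strings into a matrix of single
# characters (rows = strings). Used for vectorized peptide comparison.
char_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0))
  n <- unique(nchar(x))
  if (length(n) != 1L) stopf("strings must have equal length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}

# Hamming distance between one reference string and a vector of strings of
# the same length.
hamming_to <- function(ref, x) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- char_matrix(x)
  if (ncol(m) != length(rc)) stopf("length mismatch in hamming_to()")
  as.integer(rowSums(m != matrix(rc, nrow = nrow(m), ncol = length(rc),
                                 byrow = TRUE)))
}
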