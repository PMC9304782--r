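#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

crcs_stop <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "crcs_error")))
}

is_codon <- function(x) {
  is.character(x) && length(x) == 1L && nchar(x) == 3L &&
    all(strsplit(x, "")[[1]] %in% BASES)
}

codon_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' 32-bit FNV-1a hash of a character string
#'
#' Used to fingerprint the canonical dictionary ordering so that embedding
#' matrices can be checked against the encoder that produced the sequences.
#' @param x a character scalar
#' @return hexadecimal hash string
#' @keywords internal
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # XOR touches the low byte only (b < 256); stay in doubles mod 2^32
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves (doubles stay exact)
    h_hi <- h %/% 65536
    h_lo <- h %% 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", h)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
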