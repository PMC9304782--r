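#' Build the canonical codon-switch dictionary
#'
#' A codon switch is a directional pair of codons (reference codon ->
#' alternative codon) differing in at most one base. Every codon has nine
#' single-base neighbours, giving 9 x 64 = 576 substitution switches; adding
#' the 64 identity switches (reference equals alternative) yields the full
#' 640-element vocabulary in which any coding sequence, altered or not, can be
#' written.
#'
#' The ordering is canonical and deterministic: reference codons in
#' lexicographic order (AAA..TTT); within each reference codon the identity
#' switch first, then substitutions ordered by codon position (1..3) and
#' alternative base (A<C<G<T). Indices run 0..639 so that downstream index
#' sequences and embedding rows agree across runs.
#'
#' @return an object of class `switch_dictionary`: a data.frame with columns
#'   `index` (0-based), `ref`, `alt`, carrying a lookup map and an ordering
#'   fingerprint as attributes.
#' @examples
#' d <- build_switch_dictionary()
#' nrow(d)                 # 640
#' sum(d$ref == d$alt)     # 64 identity switches
#' @export
build_switch_dictionary <- function() {
  codons <- all_codons()
  ref <- character(0)
  alt <- character(0)
  for (cd in codons) {
    ref <- c(ref, cd)
    alt <- c(alt, cd)
    chars <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(BASES, chars[pos])) {
        sub <- chars
        sub[pos] <- b
        ref <- c(ref, cd)
        alt <- c(alt, paste(sub, collapse = ""))
      }
    }
  }
  d <- data.frame(index = seq_along(ref) - 1L, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  key <- paste0(ref, ">", alt)
  map <- stats::setNames(d$index, key)
  attr(d, "key_map") <- map
  attr(d, "fingerprint") <- fnv1a32(paste(key, collapse = ";"))
  class(d) <- c("switch_dictionary", "data.frame")
  d
}

all_codons <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Dictionary-ordering fingerprint
#'
#' @param dict a `switch_dictionary`
#' @return hexadecimal hash of the canonical ordering
#' @export
dict_fingerprint <- function(dict) {
  attr(dict, "fingerprint")
}

validate_switch <- function(ref_codon, alt_codon) {
  if (!is_codon(ref_codon) || !is_codon(alt_codon))
    crcs_stop("not a valid codon pair: %s -> %s", "crcs_invalid_switch",
              ref_codon, alt_codon)
  if (codon_hamming(ref_codon, alt_codon) > 1L)
    crcs_stop("codon pair %s -> %s differs at more than one base",
              "crcs_invalid_switch", ref_codon, alt_codon)
  invisible(TRUE)
}

#' Index of a codon switch in the dictionary
#'
#' @param dict a `switch_dictionary`
#' @param ref_codon,alt_codon the reference and alternative codons
#' @return integer index in 0..639
#' @export
switch_index <- function(dict, ref_codon, alt_codon) {
  validate_switch(ref_codon, alt_codon)
  unname(attr(dict, "key_map")[paste0(ref_codon, ">", alt_codon)])
}

#' Codon switch at a given dictionary index
#'
#' @param dict a `switch_dictionary`
#' @param index integer in 0..639
#' @return list with elements `ref` and `alt`
#' @export
switch_of <- function(dict, index) {
  if (any(index < 0L | index > 639L))
    crcs_stop("switch index out of range 0..639", "crcs_invalid_switch")
  list(ref = dict$ref[index + 1L], alt = dict$alt[index + 1L])
}

# vectorised lookup used by the encoder (no per-call validation)
switch_index_vec <- function(dict, ref_codons, alt_codons) {
  unname(attr(dict, "key_map")[paste0(ref_codons, ">", alt_codons)])
}

#' Classify a codon switch by its amino-acid effect
#'
#' Categories follow the standard genetic code: `identity` when the two
#' codons are equal, `synonymous` when they encode the same amino acid (or
#' both are stops), `nonsense` when a non-stop codon becomes a stop, and
#' `missense` otherwise (including stop-loss).
#'
#' @param ref_codon,alt_codon the reference and alternative codons
#' @return one of `"identity"`, `"synonymous"`, `"missense"`, `"nonsense"`
#' @export
classify_switch <- function(ref_codon, alt_codon) {
  validate_switch(ref_codon, alt_codon)
  if (ref_codon == alt_codon) return("identity")
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[ref_codon])
  aa_alt <- unname(gc[alt_codon])
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_alt == "*" && aa_ref != "*") return("nonsense")
  "missense"
}
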