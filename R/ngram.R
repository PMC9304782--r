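AA_ALPHABET_21 <- c(sort(setdiff(unique(Biostrings::GENETIC_CODE), "*")), "*")

#' Translate a CDS to its amino-acid string
#'
#' One symbol per codon under the standard genetic code; stop codons map to
#' `"*"`. Internal stops are translated like any other codon (and show up in
#' n-gram profiles).
#'
#' @param cds nucleotide string, length divisible by 3
#' @return amino-acid string including stop symbols
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L)
    crcs_stop("CDS length %d not divisible by 3", "crcs_malformed_model",
              nchar(cds))
  cods <- codons_of(toupper(cds))
  aa <- Biostrings::GENETIC_CODE[cods]
  if (any(is.na(aa)))
    crcs_stop("ambiguous or invalid codon(s): %s", "crcs_validation_error",
              paste(unique(cods[is.na(aa)]), collapse = ", "))
  paste(aa, collapse = "")
}

ngram_names <- function(n) {
  if (n == 1L) return(AA_ALPHABET_21)
  grids <- rev(rep(list(AA_ALPHABET_21), n))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  do.call(paste0, rev(g))
}

#' Amino-acid n-gram frequency profile
#'
#' Counts overlapping n-grams (stride 1) within each protein -- n-grams
#' never cross protein boundaries -- over the 21-symbol alphabet (20 amino
#' acids plus the stop symbol) and normalizes to frequencies.
#'
#' @param proteins character vector of amino-acid strings
#' @param n n-gram order, 1, 2 or 3
#' @return named numeric vector of length 21^n summing to 1
#' @export
ngram_frequencies <- function(proteins, n = 1L) {
  if (!n %in% 1:3)
    crcs_stop("n must be 1, 2 or 3", "crcs_config_error")
  nms <- ngram_names(n)
  counts <- stats::setNames(numeric(length(nms)), nms)
  found_any <- FALSE
  for (p in proteins) {
    np <- nchar(p)
    if (np < n) next
    found_any <- TRUE
    grams <- substring(p, seq_len(np - n + 1L), seq_len(np - n + 1L) + n - 1L)
    t <- table(grams)
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  if (!found_any)
    crcs_stop("all proteins shorter than n = %d", "crcs_empty_input", n)
  counts / sum(counts)
}

#' Spearman correlation matrix of n-gram profiles
#'
#' @param profiles named list of equal-length profiles from
#'   [ngram_frequencies()] (e.g. one per chromosome)
#' @return symmetric correlation matrix with unit diagonal
#' @export
spearman_matrix <- function(profiles) {
  if (length(profiles) < 2L)
    crcs_stop("need at least 2 profiles", "crcs_validation_error")
  dims <- vapply(profiles, length, integer(1))
  if (length(unique(dims)) != 1L)
    crcs_stop("profiles have mismatched dimensions", "crcs_validation_error")
  m <- do.call(cbind, profiles)
  stats::cor(m, method = "spearman")
}

#' Per-chromosome amino-acid n-gram profiles of a gene set
#'
#' Translates every model's spliced CDS and pools proteins by chromosome.
#'
#' @param models list of `gene_model`s
#' @param ref named character vector of chromosome sequences
#' @param n n-gram order
#' @return named list of profiles, one per chromosome with >= 1 model
#' @export
chromosome_ngram_profiles <- function(models, ref, n = 1L) {
  chroms <- vapply(models, function(gm) gm$chrom, character(1))
  prots <- vapply(models, function(gm) translate_cds(spliced_cds(gm, ref)),
                  character(1))
  lapply(split(prots, chroms), ngram_frequencies, n = n)
}
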