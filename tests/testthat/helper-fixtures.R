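# Shared fixtures, all built in code.

DICT <- build_switch_dictionary()

# Hand-built toy reference: chromosome "chrT" carrying
#  - TXF: single-exon forward gene with CDS "ATGGAAGTA"
#  - TXR: two-exon minus-strand gene with CDS "ATGTAA"
#    (genomic exon content "TTA" + "CAT"; revcomp("TTACAT") == "ATGTAA")
toy_reference <- function() {
  pad1 <- "CCCCC"
  fwd_cds <- "ATGGAAGTA"
  pad2 <- "GGGG"
  rev_ex1 <- "TTA"
  intron <- "TTTTT"
  rev_ex2 <- "CAT"
  pad3 <- "AAAA"
  seq <- paste0(pad1, fwd_cds, pad2, rev_ex1, intron, rev_ex2, pad3)
  o1 <- nchar(pad1)
  o2 <- o1 + nchar(fwd_cds) + nchar(pad2)
  o3 <- o2 + nchar(rev_ex1) + nchar(intron)
  list(
    ref = c(chrT = seq),
    fwd = gene_model("TXF", "GF", "chrT", "+", o1, o1 + 9L),
    rev = gene_model("TXR", "GR", "chrT", "-", c(o2, o3),
                     c(o2 + 3L, o3 + 3L)))
}

random_embedding <- function(L = 8L, seed = 1L, dict = DICT) {
  set.seed(seed)
  crcs_embedding(matrix(stats::rnorm(640 * L, sd = 0.3), 640, L),
                 chromosome_tag = "toy",
                 dict_fingerprint = dict_fingerprint(dict))
}

# Directly constructed, strongly separable index-sequence classes: class 1
# sequences are identity switches of GC-rich codons, class 0 of AT-rich
# codons, each with a single random substitution switch planted inside.
separable_pool <- function(n_per_class = 50L, len = 20L, n_genes = 8L,
                           seed = 1L, dict = DICT) {
  set.seed(seed)
  sets <- context_codon_sets()
  id_idx <- function(cods) switch_index_vec(dict, cods, cods)
  mk <- function(i, type, label) {
    cods <- sample(sets[[type]], len, replace = TRUE)
    idx <- id_idx(cods)
    at <- sample(len, 1)
    sw <- switch_of(dict, idx[at])
    alt <- sw$ref
    pos <- sample(3, 1)
    substr(alt, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(alt, pos, pos)), 1)
    idx[at] <- switch_index(dict, sw$ref, alt)
    s <- crcs:::switch_seq(sprintf("TX%s%03d", type, i),
                           sprintf("G%03d", (i %% n_genes) + 1L),
                           idx, at - 1L, sprintf("key%s%d", type, i), label)
    s
  }
  seqs <- c(lapply(seq_len(n_per_class), mk, type = "A", label = 1L),
            lapply(seq_len(n_per_class), mk, type = "B", label = 0L))
  list(seqs = seqs, labels = c(rep(1L, n_per_class), rep(0L, n_per_class)))
}

# Encode a simulated variant table against its genome, one sequence per
# variant (first mapped transcript).
encode_variant_table <- function(variants, genome, dict = DICT) {
  lapply(seq_len(nrow(variants)), function(i)
    map_to_transcripts(variants[i, ], genome$models, genome$ref, dict,
                       label = variants$label[i])[[1]])
}

# Mean fraction of switches within +/-ws of the variant that are identity
# switches of GC-rich context codons -- a deliberately simple
# flanking-composition classifier used as an oracle for planted signal.
context_score <- function(s, ws = 3L, dict = DICT) {
  idx <- s$indices
  at <- s$variant_offset + 1L
  fl <- setdiff(max(1L, at - ws):min(length(idx), at + ws), at)
  sw <- switch_of(dict, idx[fl])
  mean(sw$ref %in% context_codon_sets()$A & sw$ref == sw$alt)
}

make_patients <- function(n, type = "T1", n_mut = 6L, score = 0.5,
                          time = 1, event = 1L) {
  lapply(seq_len(n), function(i)
    patient_profile(sprintf("%s-%03d", type, i), type,
                    rep(score, n_mut), time, event))
}
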