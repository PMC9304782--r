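#' Codon switch sequence constructor
#' @keywords internal
switch_seq <- function(transcript_id, gene_symbol, indices, variant_offset,
                       variant_key, label = NA) {
  structure(list(transcript_id = transcript_id, gene_symbol = gene_symbol,
                 indices = as.integer(indices),
                 variant_offset = variant_offset,
                 variant_key = variant_key, label = label),
            class = "switch_seq")
}

#' @export
print.switch_seq <- function(x, ...) {
  cat(sprintf("<switch_seq %s [%s] %d codons, variant@%s>\n",
              x$transcript_id, x$variant_key %||% "reference",
              length(x$indices),
              if (is.na(x$variant_offset)) "none" else x$variant_offset))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

codons_of <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

#' Encode the unaltered reference transcript
#'
#' Produces the all-identity codon switch sequence of a gene model.
#' @param gm a `gene_model`
#' @param ref named character vector of chromosome sequences
#' @param dict a `switch_dictionary`
#' @return a `switch_seq` with no variant offset
#' @export
encode_reference <- function(gm, ref, dict) {
  cods <- codons_of(spliced_cds(gm, ref))
  switch_seq(gm$transcript_id, gm$gene_symbol,
             switch_index_vec(dict, cods, cods),
             NA_integer_, NA_character_)
}

#' Encode a variant as a codon switch sequence
#'
#' Renders a transcript's CDS as identity switches except at the codon
#' containing the variant, which becomes (reference codon -> codon with the
#' transcript-oriented alternate base substituted). Codons are defined in
#' spliced transcript space, so variants in codons spanning exon junctions
#' are handled naturally; on minus-strand models the alternate base is
#' complemented into transcript orientation.
#'
#' @param v list or one-row data.frame with `chrom`, `pos` (1-based), `ref`,
#'   `alt` single bases on the genomic strand
#' @param gm a `gene_model`
#' @param ref named character vector of chromosome sequences
#' @param dict a `switch_dictionary`
#' @param label optional class label carried on the sequence
#' @return a `switch_seq`
#' @export
encode_variant <- function(v, gm, ref, dict, label = NA) {
  if (v$chrom != gm$chrom)
    crcs_stop("variant on %s does not touch transcript %s (%s)",
              "crcs_not_coding", v$chrom, gm$transcript_id, gm$chrom)
  cds0 <- genomic_to_cds(gm, v$pos)
  if (is.na(cds0))
    crcs_stop("variant %s:%d outside the CDS of %s", "crcs_not_coding",
              v$chrom, v$pos, gm$transcript_id)
  genome_base <- substr(ref[[v$chrom]], v$pos, v$pos)
  if (genome_base != v$ref)
    crcs_stop("reference mismatch at %s:%d (genome %s, variant ref %s)",
              "crcs_ref_mismatch", v$chrom, v$pos, genome_base, v$ref)
  cds <- spliced_cds(gm, ref)
  alt_t <- if (gm$strand == "+") v$alt else complement_base(v$alt)
  codon_idx <- cds0 %/% 3L
  within <- cds0 %% 3L
  cods <- codons_of(cds)
  ref_codon <- cods[codon_idx + 1L]
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_t
  idx <- switch_index_vec(dict, cods, cods)
  idx[codon_idx + 1L] <- switch_index_vec(dict, ref_codon, alt_codon)
  switch_seq(gm$transcript_id, gm$gene_symbol, idx, as.integer(codon_idx),
             sprintf("%s:%d:%s:%s", v$chrom, v$pos, v$ref, v$alt), label)
}

#' Encode a variant against every transcript whose CDS contains it
#'
#' @param v variant record (see [encode_variant()])
#' @param models list of `gene_model`s
#' @param ref named character vector of chromosome sequences
#' @param dict a `switch_dictionary`
#' @param label optional class label
#' @return list of `switch_seq` (possibly empty)
#' @export
map_to_transcripts <- function(v, models, ref, dict, label = NA) {
  out <- list()
  for (gm in models) {
    s <- tryCatch(encode_variant(v, gm, ref, dict, label = label),
                  crcs_not_coding = function(e) NULL)
    if (!is.null(s)) out[[length(out) + 1L]] <- s
  }
  out
}

#' Amino-acid effect of a variant on one transcript
#' @keywords internal
variant_effect <- function(v, gm, ref) {
  cds0 <- genomic_to_cds(gm, v$pos)
  if (is.na(cds0)) return(NA_character_)
  cds <- spliced_cds(gm, ref)
  alt_t <- if (gm$strand == "+") v$alt else complement_base(v$alt)
  codon_idx <- cds0 %/% 3L
  ref_codon <- substr(cds, 3L * codon_idx + 1L, 3L * codon_idx + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, cds0 %% 3L + 1L, cds0 %% 3L + 1L) <- alt_t
  classify_switch(ref_codon, alt_codon)
}

#' Variant pruning pipeline
#'
#' Applies, in order, the configured subset of pruning stages to a table of
#' variant-like records (which may include indels):
#' \describe{
#'   \item{snv_only}{keep single-base substitutions over A/C/G/T}
#'   \item{coding}{keep records falling in the CDS of at least one model}
#'   \item{dedupe}{remove duplicate records; the canonical key is the set of
#'     (transcript, CDS position, ref, alt) mappings after splice inflation,
#'     which collapses to the genomic key (chrom, pos, ref, alt, source)}
#'   \item{drop_synonymous}{remove records whose every transcript mapping is
#'     synonymous}
#'   \item{drop_pathogenic}{remove records whose pathogenicity flag matches
#'     `pathogenic_values` (case-insensitive substring)}
#' }
#' When `embedding_fraction > 0` the retained set is split (seeded) into a
#' held-out embedding-training subset and a disjoint classification subset.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   optionally `source_label` and `pathogenic`
#' @param models list of `gene_model`s
#' @param ref named character vector of chromosome sequences
#' @param stages character vector of stage names, applied in the given order
#' @param embedding_fraction fraction of retained variants reserved for
#'   embedding training (default 0.4)
#' @param seed seed for the embedding split
#' @param pathogenic_values values of the flag that trigger removal
#' @return list with `variants` (retained), `counts` (per-stage data.frame),
#'   `embedding_set` and `classification_set`
#' @export
variant_filter_pipeline <- function(variants, models, ref,
                                    stages = c("snv_only", "coding", "dedupe",
                                               "drop_synonymous",
                                               "drop_pathogenic"),
                                    embedding_fraction = 0.4, seed = 1L,
                                    pathogenic_values = "pathogenic") {
  known <- c("snv_only", "coding", "dedupe", "drop_synonymous",
             "drop_pathogenic")
  bad <- setdiff(stages, known)
  if (length(bad))
    crcs_stop("unknown pipeline stage(s): %s", "crcs_config_error",
              paste(bad, collapse = ", "))
  if (is.null(variants$source_label))
    variants$source_label <- rep("unlabeled", nrow(variants))
  counts <- data.frame(stage = character(0), n_in = integer(0),
                       n_removed = integer(0), n_out = integer(0))
  cur <- variants
  for (st in stages) {
    n_in <- nrow(cur)
    keep <- rep(TRUE, n_in)
    if (n_in > 0L) keep <- switch(
      st,
      snv_only = nchar(cur$ref) == 1L & nchar(cur$alt) == 1L &
        cur$ref %in% BASES & cur$alt %in% BASES & cur$ref != cur$alt,
      coding = vapply(seq_len(n_in), function(i) {
        any(vapply(models, function(gm) {
          cur$chrom[i] == gm$chrom && !is.na(genomic_to_cds(gm, cur$pos[i]))
        }, logical(1)))
      }, logical(1)),
      dedupe = !duplicated(paste(cur$chrom, cur$pos, cur$ref, cur$alt,
                                 cur$source_label)),
      drop_synonymous = vapply(seq_len(n_in), function(i) {
        eff <- vapply(models, function(gm) {
          if (cur$chrom[i] != gm$chrom) return(NA_character_)
          variant_effect(cur[i, , drop = FALSE], gm, ref)
        }, character(1))
        eff <- eff[!is.na(eff)]
        length(eff) == 0L || any(eff != "synonymous")
      }, logical(1)),
      drop_pathogenic = {
        if (is.null(cur$pathogenic)) rep(TRUE, n_in)
        else {
          flag <- tolower(as.character(cur$pathogenic))
          flag[is.na(flag)] <- ""
          !vapply(flag, function(f) any(vapply(
            tolower(pathogenic_values),
            function(p) grepl(p, f, fixed = TRUE), logical(1))), logical(1))
        }
      })
    counts <- rbind(counts, data.frame(stage = st, n_in = n_in,
                                       n_removed = sum(!keep),
                                       n_out = sum(keep)))
    cur <- cur[keep, , drop = FALSE]
  }
  rownames(cur) <- NULL
  emb <- cur[0, , drop = FALSE]
  cls <- cur
  if (embedding_fraction > 0 && nrow(cur) > 0L) {
    set.seed(seed)
    n_emb <- floor(embedding_fraction * nrow(cur))
    pick <- sample.int(nrow(cur), n_emb)
    emb <- cur[pick, , drop = FALSE]
    cls <- cur[setdiff(seq_len(nrow(cur)), pick), , drop = FALSE]
    rownames(emb) <- rownames(cls) <- NULL
  }
  list(variants = cur, counts = counts,
       embedding_set = emb, classification_set = cls)
}
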