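test_that("a coding variant becomes a single non-identity switch", {
  tr <- toy_reference()
  # CDS "ATG GAA GTA"; variant at CDS offset 3 (0-based), genomic pos 9: G->A
  v <- data.frame(chrom = "chrT", pos = cds_to_genomic(tr$fwd, 3L),
                  ref = "G", alt = "A", stringsAsFactors = FALSE)
  s <- encode_variant(v, tr$fwd, tr$ref, DICT)
  want <- c(switch_index(DICT, "ATG", "ATG"),
            switch_index(DICT, "GAA", "AAA"),
            switch_index(DICT, "GTA", "GTA"))
  expect_equal(s$indices, want)
  expect_equal(s$variant_offset, 1L)
  expect_equal(length(s$indices), 3L)
  sw <- switch_of(DICT, s$indices)
  expect_equal(sum(sw$ref != sw$alt), 1L)
})

test_that("reference encoding is all-identity with no offset", {
  tr <- toy_reference()
  s <- encode_reference(tr$fwd, tr$ref, DICT)
  sw <- switch_of(DICT, s$indices)
  expect_true(all(sw$ref == sw$alt))
  expect_true(is.na(s$variant_offset))
  # decoding the reference side reproduces the spliced CDS exactly
  expect_equal(paste(sw$ref, collapse = ""), spliced_cds(tr$fwd, tr$ref))
})

test_that("non-coding and mismatched variants are rejected", {
  tr <- toy_reference()
  intron <- data.frame(chrom = "chrT", pos = 2L, ref = "C", alt = "A")
  expect_error(encode_variant(intron, tr$fwd, tr$ref, DICT),
               class = "crcs_not_coding")
  wrong <- data.frame(chrom = "chrT", pos = cds_to_genomic(tr$fwd, 0L),
                      ref = "T", alt = "C")
  expect_error(encode_variant(wrong, tr$fwd, tr$ref, DICT),
               class = "crcs_ref_mismatch")
})

test_that("minus-strand encoding equals the forward encoding of the
           reverse-complemented locus", {
  g <- simulate_genome(genome_sim_config(n_genes = 6), seed = 31)
  minus <- Filter(function(m) m$strand == "-", g$models)[[1]]
  cds <- spliced_cds(minus, g$ref)
  for (cds0 in c(0L, 4L, minus$cds_length - 1L)) {
    pos <- cds_to_genomic(minus, cds0)
    gref <- substr(g$ref[[minus$chrom]], pos, pos)
    galt <- setdiff(c("A", "C", "G", "T"), gref)[1]
    v <- data.frame(chrom = minus$chrom, pos = pos, ref = gref, alt = galt)
    s1 <- encode_variant(v, minus, g$ref, DICT)
    # same locus rewritten as a naked forward gene over its own CDS
    ref2 <- c(F1 = cds)
    fwd <- gene_model("F1", "F1", "F1", "+", 0L, nchar(cds))
    v2 <- data.frame(chrom = "F1", pos = cds0 + 1L,
                     ref = substr(cds, cds0 + 1L, cds0 + 1L),
                     alt = crcs:::complement_base(galt))
    s2 <- encode_variant(v2, fwd, ref2, DICT)
    expect_equal(s1$indices, s2$indices)
    expect_equal(s1$variant_offset, s2$variant_offset)
  }
})

test_that("splice mapping hits every covering transcript", {
  tr <- toy_reference()
  # third transcript sharing the forward exon
  shared <- gene_model("TXS", "GS", "chrT", "+", tr$fwd$cds_starts - 3L,
                       tr$fwd$cds_ends)
  models <- list(tr$fwd, tr$rev, shared)
  v <- data.frame(chrom = "chrT", pos = cds_to_genomic(tr$fwd, 3L),
                  ref = "G", alt = "A")
  hits <- map_to_transcripts(v, models, tr$ref, DICT)
  expect_length(hits, 2L)
  expect_setequal(vapply(hits, function(s) s$transcript_id, ""),
                  c("TXF", "TXS"))
  # the same substitution switch appears in both, at shifted offsets
  non_id <- vapply(hits, function(s) {
    sw <- switch_of(DICT, s$indices)
    s$indices[which(sw$ref != sw$alt)]
  }, integer(1))
  expect_equal(non_id[1], non_id[2])
  offs <- vapply(hits, function(s) s$variant_offset, integer(1))
  expect_equal(sort(offs), c(1L, 2L))
  # intergenic variant maps nowhere
  none <- map_to_transcripts(data.frame(chrom = "chrT", pos = 2L, ref = "C",
                                        alt = "G"), models, tr$ref, DICT)
  expect_length(none, 0L)
})

test_that("encoding conserves the reference side over simulated genes", {
  g <- simulate_genome(genome_sim_config(n_genes = 5), seed = 32)
  v <- simulate_variants(g, n_per_class = 10, beta = 0.5, seed = 33)
  for (i in seq_len(nrow(v))) {
    for (s in map_to_transcripts(v[i, ], g$models, g$ref, DICT)) {
      gm <- Filter(function(m) m$transcript_id == s$transcript_id,
                   g$models)[[1]]
      sw <- switch_of(DICT, s$indices)
      expect_equal(paste(sw$ref, collapse = ""), spliced_cds(gm, g$ref))
      expect_lte(sum(sw$ref != sw$alt), 1L)
      expect_equal(length(s$indices), gm$cds_length %/% 3L)
    }
  }
})

test_that("pruning pipeline applies the documented stages", {
  tr <- toy_reference()
  models <- list(tr$fwd)
  p_syn <- cds_to_genomic(tr$fwd, 8L)  # GTA -> GTx third base: synonymous
  p_mis <- cds_to_genomic(tr$fwd, 4L)  # GAA -> GCA missense
  p_non <- cds_to_genomic(tr$fwd, 3L)  # GAA -> TAA nonsense
  vars <- data.frame(
    chrom = "chrT",
    pos = c(p_mis, p_syn, p_mis, p_mis, p_non),
    ref = c("A", "A", "A", "A", "G"),
    alt = c("CT", "G", "C", "C", "T"),  # first record is an indel
    stringsAsFactors = FALSE)
  out <- variant_filter_pipeline(vars, models, tr$ref,
                                 embedding_fraction = 0)
  # indel out, synonymous out, duplicate missense collapsed -> 2 retained
  expect_equal(nrow(out$variants), 2L)
  expect_setequal(out$variants$pos, c(p_mis, p_non))
  expect_equal(out$counts$n_removed,
               c(1L, 0L, 1L, 1L, 0L))
  # monotonicity: every stage's output is a subset of its input
  expect_true(all(out$counts$n_out == out$counts$n_in -
                    out$counts$n_removed))
  expect_true(all(diff(c(nrow(vars), out$counts$n_out)) <= 0))
})

test_that("pipeline handles pathogenic flags, splits and bad config", {
  tr <- toy_reference()
  models <- list(tr$fwd)
  p_mis <- cds_to_genomic(tr$fwd, 4L)
  vars <- data.frame(chrom = "chrT", pos = rep(p_mis, 2), ref = "A",
                     alt = c("C", "G"),
                     pathogenic = c("Likely_pathogenic", NA),
                     stringsAsFactors = FALSE)
  out <- variant_filter_pipeline(vars, models, tr$ref,
                                 embedding_fraction = 0)
  expect_equal(nrow(out$variants), 1L)
  expect_equal(out$variants$alt, "G")

  empty <- variant_filter_pipeline(vars[0, ], models, tr$ref)
  expect_equal(nrow(empty$variants), 0L)
  expect_true(all(empty$counts$n_removed == 0L))

  expect_error(variant_filter_pipeline(vars, models, tr$ref,
                                       stages = "drop_everything"),
               class = "crcs_config_error")

  # embedding split is disjoint and seeded
  many <- data.frame(chrom = "chrT",
                     pos = rep(c(p_mis, cds_to_genomic(tr$fwd, 3L)), 5),
                     ref = rep(c("A", "G"), 5), alt = rep(c("C", "T"), 5))
  many$pos <- many$pos + 0L
  sp1 <- variant_filter_pipeline(many, models, tr$ref,
                                 stages = c("snv_only", "coding"),
                                 embedding_fraction = 0.4, seed = 9)
  sp2 <- variant_filter_pipeline(many, models, tr$ref,
                                 stages = c("snv_only", "coding"),
                                 embedding_fraction = 0.4, seed = 9)
  expect_equal(nrow(sp1$embedding_set), floor(0.4 * nrow(sp1$variants)))
  expect_equal(nrow(sp1$embedding_set) + nrow(sp1$classification_set),
               nrow(sp1$variants))
  expect_identical(sp1$embedding_set, sp2$embedding_set)
})
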