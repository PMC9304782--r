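# Seeded generators for toy genomes, two-class variant sets with a tunable
# contextual signal, and survival cohorts. The planted signal lives in the
# flanking codon composition around the variant, never in the variant's own
# codon switch: a classifier can only succeed by reading the neighborhood.

#' Context codon sets used to plant the class signal
#'
#' Two disjoint 8-codon sets: class-1 ("cancer-like") contexts are built
#' from GC-rich codons, class-0 contexts from AT-rich codons. Variant
#' center codons are always drawn from the shared background, so the codon
#' switch itself carries no class information.
#' @return list with elements `A` and `B`
#' @export
context_codon_sets <- function() {
  list(A = c("GCA", "GCC", "GCG", "GCT", "CGA", "CGC", "CGG", "CGT"),
       B = c("ATA", "ATC", "ATG", "ATT", "TAC", "TAG", "TAT", "TAA"))
}

#' Genome simulation configuration
#'
#' @param n_chromosomes,n_genes toy genome dimensions
#' @param cds_codons inclusive range of CDS lengths in codons
#' @param exons inclusive range of CDS exon counts per gene
#' @param intron_len,gap_len ranges of intron and intergenic lengths (nt)
#' @param gc GC content of background sequence
#' @param strand_prob probability of the minus strand (the first two genes
#'   are forced onto opposite strands)
#' @param sites_per_gene context sites planted per gene (split between the
#'   two context types)
#' @param ws flank width of a context site, in codons
#' @return named list
#' @export
genome_sim_config <- function(n_chromosomes = 2L, n_genes = 12L,
                              cds_codons = c(30L, 60L), exons = c(1L, 3L),
                              intron_len = c(20L, 80L),
                              gap_len = c(60L, 150L), gc = 0.5,
                              strand_prob = 0.5, sites_per_gene = 4L,
                              ws = 3L) {
  stopifnot(n_chromosomes >= 1, n_genes >= 1, cds_codons[1] >= 2 * ws + 1,
            gc > 0, gc < 1, ws >= 1)
  as.list(environment())
}

random_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a toy genome with gene models
#'
#' Generates multi-exon, two-strand gene models on short chromosomes.
#' Each gene's CDS carries planted context sites: windows whose `ws`
#' flanking codons on both sides are drawn from one of the two context
#' codon sets (see [context_codon_sets()]) while the center codon stays
#' background. All generators are pure functions of (config, seed).
#'
#' @param cfg from [genome_sim_config()]
#' @param seed integer seed
#' @return list with `ref` (named character vector) and `models` (list of
#'   `gene_model`)
#' @export
simulate_genome <- function(cfg = genome_sim_config(), seed = 1L) {
  set.seed(seed)
  sets <- context_codon_sets()
  ws <- cfg$ws
  chrom_seqs <- stats::setNames(rep("", cfg$n_chromosomes),
                                paste0("chrS", seq_len(cfg$n_chromosomes)))
  models <- list()
  for (g in seq_len(cfg$n_genes)) {
    n_cod <- sample(cfg$cds_codons[1]:cfg$cds_codons[2], 1L)
    cods <- vapply(seq_len(n_cod), function(i)
      paste(random_bases(3L, cfg$gc), collapse = ""), character(1))
    # plant alternating A/B context sites at non-overlapping centers
    span <- 2L * ws + 2L
    centers <- integer(0)
    avail <- (ws + 1L):(n_cod - ws)
    for (s in seq_len(cfg$sites_per_gene)) {
      ok <- avail[vapply(avail, function(c0)
        all(abs(c0 - centers) >= span), logical(1))]
      if (length(ok) == 0L) break
      c0 <- if (length(ok) == 1L) ok else sample(ok, 1L)
      centers <- c(centers, c0)
      type <- if (s %% 2L == 1L) "A" else "B"
      flanks <- c((c0 - ws):(c0 - 1L), (c0 + 1L):(c0 + ws))
      cods[flanks] <- sample(sets[[type]], 2L * ws, replace = TRUE)
    }
    cds <- paste(cods, collapse = "")
    n_ex <- sample(cfg$exons[1]:cfg$exons[2], 1L)
    cds_nt <- nchar(cds)
    n_ex <- min(n_ex, cds_nt %/% 3L)
    cuts <- if (n_ex > 1L)
      sort(sample(seq_len(cds_nt - 1L), n_ex - 1L)) else integer(0)
    piece_len <- diff(c(0L, cuts, cds_nt))
    strand <- if (g == 1L) "+" else if (g == 2L) "-"
              else if (stats::runif(1) < cfg$strand_prob) "-" else "+"
    genomic_concat <- if (strand == "+") cds else revcomp(cds)
    chrom <- names(chrom_seqs)[(g - 1L) %% cfg$n_chromosomes + 1L]
    cursor <- nchar(chrom_seqs[[chrom]])
    starts <- integer(n_ex); ends <- integer(n_ex)
    pieces <- character(0)
    off <- 0L
    for (e in seq_len(n_ex)) {
      gap <- if (e == 1L) sample(cfg$gap_len[1]:cfg$gap_len[2], 1L)
             else sample(cfg$intron_len[1]:cfg$intron_len[2], 1L)
      pieces <- c(pieces, paste(random_bases(gap, cfg$gc), collapse = ""))
      cursor <- cursor + gap
      starts[e] <- cursor
      exon_seq <- substr(genomic_concat, off + 1L, off + piece_len[e])
      off <- off + piece_len[e]
      pieces <- c(pieces, exon_seq)
      cursor <- cursor + piece_len[e]
      ends[e] <- cursor
    }
    chrom_seqs[[chrom]] <- paste0(chrom_seqs[[chrom]],
                                  paste(pieces, collapse = ""))
    models[[g]] <- gene_model(sprintf("TX%03d", g), sprintf("GENE%03d", g),
                              chrom, strand, starts, ends)
  }
  # trailing spacer so no CDS touches a chromosome end
  for (ch in names(chrom_seqs))
    chrom_seqs[[ch]] <- paste0(chrom_seqs[[ch]],
                               paste(random_bases(50L, cfg$gc),
                                     collapse = ""))
  list(ref = chrom_seqs, models = models, config = cfg)
}

#' Locate planted context sites in a gene set
#'
#' A codon position is an `A` (resp. `B`) site center when all `ws` codons
#' on both sides belong to the corresponding context codon set.
#'
#' @param models list of `gene_model`s
#' @param ref reference sequences
#' @param ws flank width in codons
#' @return data.frame (transcript_idx, codon, type)
#' @export
find_context_sites <- function(models, ref, ws = 3L) {
  sets <- context_codon_sets()
  rows <- list()
  for (mi in seq_along(models)) {
    cods <- codons_of(spliced_cds(models[[mi]], ref))
    n <- length(cods)
    in_a <- cods %in% sets$A
    in_b <- cods %in% sets$B
    for (j in (ws + 1L):(n - ws)) {
      fl <- c((j - ws):(j - 1L), (j + 1L):(j + ws))
      if (all(in_a[fl]))
        rows[[length(rows) + 1L]] <- data.frame(transcript_idx = mi,
                                                codon = j, type = "A")
      else if (all(in_b[fl]))
        rows[[length(rows) + 1L]] <- data.frame(transcript_idx = mi,
                                                codon = j, type = "B")
    }
  }
  if (length(rows) == 0L)
    return(data.frame(transcript_idx = integer(0), codon = integer(0),
                      type = character(0)))
  do.call(rbind, rows)
}

#' Simulate two labeled variant classes with a contextual signal
#'
#' Class-1 ("cancer") variants are placed at A-type context sites with
#' probability `beta` and uniformly over coding positions otherwise;
#' class-0 ("population") variants analogously with B-type sites. At
#' `beta = 0` the two class-conditional flanking-context distributions
#' coincide (both uniform). The substituted base is always drawn uniformly
#' at the chosen codon, so the switch itself is uninformative.
#'
#' @param genome list from [simulate_genome()] (or any `ref` + `models`)
#' @param n_per_class variants per class
#' @param beta signal strength in \[0, 1\]
#' @param ws context flank width (must match the genome's)
#' @param seed integer seed
#' @return data.frame (chrom, pos, ref, alt, source_label, label),
#'   VCF-writable via [write_vcf()]
#' @export
simulate_variants <- function(genome, n_per_class = 500L, beta = 0.5,
                              ws = 3L, seed = 1L) {
  set.seed(seed)
  ref <- genome$ref; models <- genome$models
  sites <- find_context_sites(models, ref, ws = ws)
  if (nrow(sites) == 0L && beta > 0)
    crcs_stop("no eligible context sites in the genome", "crcs_empty_input")
  n_cods <- vapply(models, function(gm) gm$cds_length %/% 3L, integer(1))
  draw_one <- function(type) {
    typed <- sites[sites$type == type, , drop = FALSE]
    if (beta > 0 && nrow(typed) > 0L && stats::runif(1) < beta) {
      r <- typed[sample.int(nrow(typed), 1L), ]
      mi <- r$transcript_idx; codon <- r$codon
    } else {
      mi <- sample.int(length(models), 1L)
      codon <- sample.int(n_cods[mi], 1L)
    }
    gm <- models[[mi]]
    within <- sample.int(3L, 1L) - 1L
    cds0 <- (codon - 1L) * 3L + within
    pos <- cds_to_genomic(gm, cds0)
    gref <- substr(ref[[gm$chrom]], pos, pos)
    galt <- sample(setdiff(BASES, gref), 1L)
    data.frame(chrom = gm$chrom, pos = pos, ref = gref, alt = galt,
               stringsAsFactors = FALSE)
  }
  cls1 <- do.call(rbind, replicate(n_per_class, draw_one("A"),
                                   simplify = FALSE))
  cls0 <- do.call(rbind, replicate(n_per_class, draw_one("B"),
                                   simplify = FALSE))
  cls1$source_label <- "cancer"; cls1$label <- 1L
  cls0$source_label <- "population"; cls0$label <- 0L
  out <- rbind(cls1, cls0)
  rownames(out) <- NULL
  out
}

#' Simulate survival outcomes from per-patient cumulative scores
#'
#' Survival times are exponential with hazard `base_rate * exp(gamma *
#' blacs)`; censoring is independent exponential, calibrated so that about
#' `censoring_rate` of a gamma = 0 cohort is censored. `censoring_rate = 0`
#' yields all-event data.
#'
#' @param blacs numeric vector of per-patient BLACs scores
#' @param gamma log-hazard effect per BLACs unit
#' @param base_rate baseline hazard
#' @param censoring_rate target censored fraction in \[0, 1)
#' @param seed integer seed
#' @return data.frame (blacs, time, event)
#' @export
simulate_survival <- function(blacs, gamma = 0, base_rate = 0.1,
                              censoring_rate = 0.2, seed = 1L) {
  stopifnot(base_rate > 0, censoring_rate >= 0, censoring_rate < 1)
  set.seed(seed)
  n <- length(blacs)
  t_event <- stats::rexp(n, rate = base_rate * exp(gamma * blacs))
  if (censoring_rate > 0) {
    t_cens <- stats::rexp(n, rate = base_rate * censoring_rate /
                            (1 - censoring_rate))
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(blacs = blacs, time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Simulate a survival cohort of patient profiles
#'
#' Each patient gets a latent risk in \[0, 1\], per-mutation scores drawn
#' from a risk-tilted beta distribution, and survival generated by
#' [simulate_survival()] from the resulting BLACs score.
#'
#' @param n_patients cohort size
#' @param cancer_type label attached to every patient
#' @param n_mutations inclusive range of mutation counts per patient
#' @param gamma,base_rate,censoring_rate hazard link (see
#'   [simulate_survival()])
#' @param k BLACs scaling factor
#' @param seed integer seed
#' @return list of `patient_profile`
#' @export
simulate_patient_profiles <- function(n_patients = 150L, cancer_type = "T1",
                                      n_mutations = c(5L, 30L), gamma = 0,
                                      base_rate = 0.1, censoring_rate = 0.2,
                                      k = 4, seed = 1L) {
  set.seed(seed)
  u <- stats::runif(n_patients)
  muts <- lapply(seq_len(n_patients), function(i) {
    m <- sample(n_mutations[1]:n_mutations[2], 1L)
    stats::rbeta(m, shape1 = 0.5 + 2.5 * u[i], shape2 = 3 - 2 * u[i])
  })
  blacs <- vapply(muts, blacs_score, numeric(1), k = k)
  surv <- simulate_survival(blacs, gamma = gamma, base_rate = base_rate,
                            censoring_rate = censoring_rate,
                            seed = seed + 1L)
  lapply(seq_len(n_patients), function(i)
    patient_profile(sprintf("P%04d", i), cancer_type, muts[[i]],
                    surv$time[i], surv$event[i]))
}
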