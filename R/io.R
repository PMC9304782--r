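#' Read a reference FASTA
#'
#' @param path FASTA file
#' @return named character vector of uppercased sequences
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e)
                   crcs_stop("malformed FASTA %s: %s", "crcs_parse_error",
                             path, conditionMessage(e)))
  if (length(ss) == 0L)
    crcs_stop("FASTA %s contains no records", "crcs_parse_error", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    crcs_stop("duplicate sequence ids in %s", "crcs_parse_error", path)
  seqs
}

#' Write a reference FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models
#'
#' Two dialects are supported. `bed12`: standard 12-column BED where
#' thickStart/thickEnd delimit the CDS and the name field is either
#' `transcript` or `transcript|gene`. `tab`: a simple table with columns
#' transcript_id, gene_symbol, chrom, strand, cds_starts, cds_ends (the last
#' two comma-joined 0-based half-open coordinates).
#'
#' Models whose CDS length is not divisible by 3 are skipped with a warning;
#' the number skipped is recorded in the `n_skipped` attribute.
#'
#' @param path input file
#' @param dialect `"bed12"` or `"tab"`
#' @return list of `gene_model`s
#' @export
read_gene_models <- function(path, dialect = c("bed12", "tab")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  models <- list()
  skipped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    parsed <- if (dialect == "bed12") parse_bed12_line(f)
              else parse_tab_line(f)
    gm <- tryCatch(do.call(gene_model, parsed),
                   crcs_malformed_model = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(gm)) skipped <- skipped + 1L else models[[length(models) + 1L]] <- gm
  }
  attr(models, "n_skipped") <- skipped
  models
}

parse_bed12_line <- function(f) {
  if (length(f) < 12L)
    crcs_stop("BED12 line has %d columns, expected 12", "crcs_parse_error",
              length(f))
  chrom <- f[1]; chrom_start <- as.integer(f[2])
  name <- f[4]; strand <- f[6]
  thick_start <- as.integer(f[7]); thick_end <- as.integer(f[8])
  n_blocks <- as.integer(f[10])
  sizes <- as.integer(strsplit(f[11], ",")[[1]])[seq_len(n_blocks)]
  starts <- as.integer(strsplit(f[12], ",")[[1]])[seq_len(n_blocks)]
  bs <- chrom_start + starts
  be <- bs + sizes
  # CDS = intersection of each block with [thickStart, thickEnd)
  cs <- pmax(bs, thick_start); ce <- pmin(be, thick_end)
  keep <- ce > cs
  if (!any(keep))
    crcs_stop("BED12 record %s has an empty CDS", "crcs_parse_error", name)
  ids <- strsplit(name, "|", fixed = TRUE)[[1]]
  list(transcript_id = ids[1],
       gene_symbol = if (length(ids) > 1L) ids[2] else ids[1],
       chrom = chrom, strand = strand,
       cds_starts = cs[keep], cds_ends = ce[keep])
}

parse_tab_line <- function(f) {
  if (length(f) != 6L)
    crcs_stop("gene table line has %d columns, expected 6",
              "crcs_parse_error", length(f))
  list(transcript_id = f[1], gene_symbol = f[2], chrom = f[3], strand = f[4],
       cds_starts = as.integer(strsplit(f[5], ",")[[1]]),
       cds_ends = as.integer(strsplit(f[6], ",")[[1]]))
}

#' Write gene models in the `tab` dialect
#' @param models list of `gene_model`s
#' @param path output file
#' @export
write_gene_models <- function(models, path) {
  lines <- vapply(models, function(gm) {
    paste(gm$transcript_id, gm$gene_symbol, gm$chrom, gm$strand,
          paste(gm$cds_starts, collapse = ","),
          paste(gm$cds_ends, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read SNVs from a VCF
#'
#' Parses a minimal VCF (CHROM, POS, ID, REF, ALT; other columns ignored),
#' keeps only single-base substitutions, decomposes multi-allelic records
#' into one variant per alternative allele, and reads an optional
#' pathogenicity flag from the INFO field. Records skipped as non-SNV are
#' counted in the `n_skipped` attribute.
#'
#' @param path VCF file
#' @param source_label label attached to every variant (e.g. `"population"`,
#'   `"cancer"`)
#' @param pathogenicity_key INFO key whose value is carried as the
#'   pathogenicity flag (default `"CLNSIG"`)
#' @return data.frame with columns chrom, pos, ref, alt, source_label,
#'   pathogenic
#' @export
read_vcf_snvs <- function(path, source_label = "unlabeled",
                          pathogenicity_key = "CLNSIG") {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  crcs_stop("malformed VCF %s: %s", "crcs_parse_error",
                            path, conditionMessage(e)))
  fix <- v@fix
  if (is.null(dim(fix)) || !all(c("CHROM", "POS", "REF", "ALT") %in%
                                colnames(fix)))
    crcs_stop("VCF %s lacks mandatory columns", "crcs_parse_error", path)
  out <- list()
  skipped <- 0L
  info <- if ("INFO" %in% colnames(fix)) fix[, "INFO"] else rep(NA, nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    flag <- parse_info_key(info[i], pathogenicity_key)
    for (alt in alts) {
      if (is.na(ref) || is.na(alt) || nchar(ref) != 1L || nchar(alt) != 1L ||
          !ref %in% BASES || !alt %in% BASES || ref == alt) {
        skipped <- skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt, source_label = source_label,
        pathogenic = flag, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         source_label = character(0),
                         pathogenic = character(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}

parse_info_key <- function(info, key) {
  if (is.na(info) || info == ".") return(NA_character_)
  fields <- strsplit(info, ";", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", key, "="), fields, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Write variants as a minimal VCF
#' @param variants data.frame with chrom, pos, ref, alt and optionally
#'   `pathogenic` (emitted as a CLNSIG INFO key)
#' @param path output file
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    info <- rep(".", nrow(variants))
    if (!is.null(variants$pathogenic)) {
      has <- !is.na(variants$pathogenic)
      info[has] <- paste0("CLNSIG=", variants$pathogenic[has])
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", variants$chrom,
                       variants$pos, variants$ref, variants$alt, info), con)
  }
  invisible(path)
}

#' Write / read scored variants
#'
#' Lossless round trip of (variant_key, transcript_id, score, label, fold) as
#' a tab-separated table.
#' @param scored data.frame with columns variant_key, transcript_id, score,
#'   label, fold
#' @param path file path
#' @export
write_scores <- function(scored, path) {
  cols <- c("variant_key", "transcript_id", "score", "label", "fold")
  missing_cols <- setdiff(cols, names(scored))
  if (length(missing_cols))
    crcs_stop("scored table lacks column(s): %s", "crcs_validation_error",
              paste(missing_cols, collapse = ", "))
  if (nrow(scored) && any(scored$score < 0 | scored$score > 1))
    crcs_stop("scores must lie in [0, 1]", "crcs_validation_error")
  utils::write.table(scored[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(df) && any(df$score < 0 | df$score > 1))
    crcs_stop("scores must lie in [0, 1]", "crcs_validation_error")
  df
}

#' Write / read an embedding matrix
#'
#' The matrix is stored as a headered numeric text table: comment lines
#' record the embedding length, chromosome tag and the dictionary-ordering
#' fingerprint; row i holds the vector of switch index i-1.
#' @param emb a `crcs_embedding`
#' @param path file path
#' @export
write_embedding <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# L=%d", ncol(emb$values)),
               sprintf("# chromosome_tag=%s", emb$chromosome_tag),
               sprintf("# dict_fingerprint=%s", emb$dict_fingerprint)), con)
  utils::write.table(format(emb$values, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(hit) == 0L)
      crcs_stop("embedding file lacks header key %s", "crcs_parse_error", key)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  vals <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            sep = "\t")
  m <- as.matrix(vals)
  dimnames(m) <- NULL
  if (nrow(m) != 640L || ncol(m) != as.integer(get("L")))
    crcs_stop("embedding matrix has wrong shape", "crcs_parse_error")
  crcs_embedding(m, chromosome_tag = get("chromosome_tag"),
                 dict_fingerprint = get("dict_fingerprint"))
}

#' Default run configuration
#'
#' Flat list of every tunable the toolkit uses, with the method defaults:
#' window size `ws = 3`, negative sampling rate `nsr = 0.2`, subsampling
#' floor `epsilon = 0.001`, embedding length `L = 300` trained for 200
#' epochs, 4 gene-disjoint folds, sequence-length cap 1500, minimum 200
#' variants per gene, decision threshold 0.9, BLACs scaling `k = 4`, and the
#' survival cohort filters (>= 5 mutations per patient, >= 100 patients per
#' cancer type).
#'
#' @param ... overrides of the defaults
#' @return named list
#' @export
crcs_config <- function(...) {
  cfg <- list(ws = 3L, nsr = 0.2, epsilon = 0.001, L = 300L,
              embedding_epochs = 200L, folds = 4L, blac_epochs = 200L,
              max_len = 1500L, min_gene_variants = 200L, threshold = 0.9,
              k = 4, min_mutations = 5L, min_patients = 100L,
              min_group_size = 5L, alpha = 0.05, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    crcs_stop("unknown config key(s): %s", "crcs_config_error",
              paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$ws >= 1, cfg$nsr > 0, cfg$nsr <= 1,
            cfg$epsilon > 0, cfg$epsilon < 1, cfg$L >= 1, cfg$folds >= 2,
            cfg$max_len >= 1, cfg$k > 0)
  cfg
}

#' Read / write a flat key=value configuration file
#' @param path file path
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  do.call(crcs_config, stats::setNames(vals, trimws(vapply(kv, `[`, "", 1))))
}

#' @rdname read_config
#' @param cfg configuration list from [crcs_config()]
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s=%s", names(cfg), unlist(cfg)), path)
  invisible(path)
}
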