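#' Construct a gene model
#'
#' A gene model is a transcript with CDS exon coordinates on a chromosome.
#' Coordinates are 0-based half-open in ascending genomic order (BED
#' convention); variant positions handed to the encoder are 1-based (VCF
#' convention).
#'
#' @param transcript_id,gene_symbol identifiers
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param cds_starts,cds_ends integer vectors of 0-based half-open CDS exon
#'   intervals, ascending and non-overlapping
#' @return an object of class `gene_model`
#' @export
gene_model <- function(transcript_id, gene_symbol, chrom, strand,
                       cds_starts, cds_ends) {
  if (!strand %in% c("+", "-"))
    crcs_stop("strand must be '+' or '-'", "crcs_malformed_model")
  if (length(cds_starts) != length(cds_ends) || length(cds_starts) == 0L)
    crcs_stop("cds_starts/cds_ends must be equal-length, nonempty",
              "crcs_malformed_model")
  if (any(cds_ends <= cds_starts))
    crcs_stop("empty or inverted CDS exon interval", "crcs_malformed_model")
  o <- order(cds_starts)
  cds_starts <- cds_starts[o]; cds_ends <- cds_ends[o]
  if (length(cds_starts) > 1L &&
      any(cds_starts[-1L] < cds_ends[-length(cds_ends)]))
    crcs_stop("overlapping CDS exons", "crcs_malformed_model")
  len <- sum(cds_ends - cds_starts)
  if (len %% 3L != 0L)
    crcs_stop("CDS length %d not divisible by 3 (%s)", "crcs_malformed_model",
              len, transcript_id)
  structure(list(transcript_id = transcript_id, gene_symbol = gene_symbol,
                 chrom = chrom, strand = strand,
                 cds_starts = as.integer(cds_starts),
                 cds_ends = as.integer(cds_ends),
                 cds_length = as.integer(len)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s (%s) %s%s, %d CDS exon(s), %d nt>\n",
              x$transcript_id, x$gene_symbol, x$chrom, x$strand,
              length(x$cds_starts), x$cds_length))
  invisible(x)
}

#' Spliced CDS sequence of a gene model
#'
#' Concatenates the CDS exons in transcript orientation; minus-strand models
#' are reverse-complemented so the returned string always reads 5'->3' on the
#' coding strand.
#'
#' @param gm a `gene_model`
#' @param ref named character vector of chromosome sequences
#' @return nucleotide string whose length is the CDS length
#' @export
spliced_cds <- function(gm, ref) {
  if (!gm$chrom %in% names(ref))
    crcs_stop("chromosome %s not in reference", "crcs_coordinate_error",
              gm$chrom)
  chrom_seq <- ref[[gm$chrom]]
  if (any(gm$cds_ends > nchar(chrom_seq)) || any(gm$cds_starts < 0L))
    crcs_stop("CDS exon outside chromosome bounds (%s)",
              "crcs_coordinate_error", gm$transcript_id)
  pieces <- substring(chrom_seq, gm$cds_starts + 1L, gm$cds_ends)
  cds <- paste(pieces, collapse = "")
  if (gm$strand == "-") cds <- revcomp(cds)
  cds
}

#' Map a 1-based genomic position into 0-based CDS coordinates
#'
#' @param gm a `gene_model`
#' @param pos 1-based genomic position
#' @return 0-based offset into the spliced CDS (transcript orientation), or
#'   `NA` if the position does not fall in the CDS
#' @export
genomic_to_cds <- function(gm, pos) {
  p0 <- pos - 1L
  hit <- which(p0 >= gm$cds_starts & p0 < gm$cds_ends)
  if (length(hit) == 0L) return(NA_integer_)
  before <- if (hit > 1L) sum(gm$cds_ends[seq_len(hit - 1L)] -
                                gm$cds_starts[seq_len(hit - 1L)]) else 0L
  f0 <- before + (p0 - gm$cds_starts[hit])
  if (gm$strand == "+") as.integer(f0) else as.integer(gm$cds_length - 1L - f0)
}

#' Map a 0-based CDS offset back to a 1-based genomic position
#'
#' Inverse of [genomic_to_cds()].
#' @param gm a `gene_model`
#' @param cds0 0-based CDS offset in transcript orientation
#' @return 1-based genomic position
#' @export
cds_to_genomic <- function(gm, cds0) {
  if (cds0 < 0L || cds0 >= gm$cds_length)
    crcs_stop("CDS offset out of range", "crcs_coordinate_error")
  f0 <- if (gm$strand == "+") cds0 else gm$cds_length - 1L - cds0
  lens <- gm$cds_ends - gm$cds_starts
  cum <- cumsum(lens)
  exon <- which(f0 < cum)[1L]
  before <- if (exon > 1L) cum[exon - 1L] else 0L
  as.integer(gm$cds_starts[exon] + (f0 - before) + 1L)
}
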