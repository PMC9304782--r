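#' Group variant scores by (cancer type, gene)
#'
#' @param scored data.frame with columns `gene`, `score` and optionally
#'   `cancer_type`
#' @param min_group_size groups with fewer scores are dropped (default 5,
#'   i.e. groups of >= 5 scores are retained)
#' @return list of groups, each `list(cancer_type, gene, scores)`
#' @export
group_scores <- function(scored, min_group_size = 5L) {
  stopifnot(min_group_size >= 1L)
  if (nrow(scored) == 0L) return(list())
  ct <- if (is.null(scored$cancer_type)) rep(NA_character_, nrow(scored))
        else scored$cancer_type
  key <- paste(ct, scored$gene, sep = "\r")
  split_scores <- split(scored$score, key)
  out <- list()
  for (k in names(split_scores)) {
    if (length(split_scores[[k]]) < min_group_size) next
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <- list(
      cancer_type = if (parts[1] == "NA") NA_character_ else parts[1],
      gene = parts[2], scores = split_scores[[k]])
  }
  out
}

#' Per-gene significance of cancer versus control score elevation
#'
#' For every (cancer type, gene) group present with at least
#' `min_group_size` scores on both the cancer and the control side, computes
#' the one-sided Mann-Whitney p-value for the alternative "cancer scores
#' larger". Genes missing from either side are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param cancer_scored data.frame with `cancer_type`, `gene`, `score`
#' @param control_scored data.frame with `gene`, `score` (grouped on genes
#'   alone)
#' @param min_group_size group-size cutoff (default 5)
#' @return data.frame (cancer_type, gene, n_cancer, n_control, p)
#' @export
gene_significance <- function(cancer_scored, control_scored,
                              min_group_size = 5L) {
  cg <- group_scores(cancer_scored, min_group_size)
  ctrl <- group_scores(
    data.frame(gene = control_scored$gene, score = control_scored$score),
    min_group_size)
  ctrl_map <- stats::setNames(lapply(ctrl, `[[`, "scores"),
                              vapply(ctrl, `[[`, "", "gene"))
  rows <- list()
  skipped <- 0L
  for (g in cg) {
    ref <- ctrl_map[[g$gene]]
    if (is.null(ref)) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cancer_type = g$cancer_type, gene = g$gene,
      n_cancer = length(g$scores), n_control = length(ref),
      p = compare_distributions(g$scores, ref), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(cancer_type = character(0), gene = character(0),
                         n_cancer = integer(0), n_control = integer(0),
                         p = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Sorting the m raw p-values ascending, adj_(i) = max_(j<=i)
#' \[1 - (1 - p_(j))^(m - j + 1)\], clipped to 1 and returned in the input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same order as the input
#' @export
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p)))
    crcs_stop("p-values must lie in [0, 1]", "crcs_validation_error")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- cummax(1 - (1 - ps)^(m - seq_len(m) + 1))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Build a gene significance table with per-cancer-type correction
#'
#' Applies [holm_sidak()] within each cancer type (p-values of all genes of
#' a type are collected and corrected together) and flags rows with adjusted
#' p below `alpha`.
#'
#' @param sig data.frame from [gene_significance()]
#' @param alpha significance level on the adjusted p (default 0.05)
#' @return the table with `adjusted_p` and `significant` columns added
#' @export
adjust_gene_significance <- function(sig, alpha = 0.05) {
  if (nrow(sig) == 0L) {
    sig$adjusted_p <- numeric(0)
    sig$significant <- logical(0)
    return(sig)
  }
  sig$adjusted_p <- NA_real_
  for (ct in unique(sig$cancer_type)) {
    rows <- which(sig$cancer_type == ct |
                    (is.na(sig$cancer_type) & is.na(ct)))
    sig$adjusted_p[rows] <- holm_sidak(sig$p[rows])
  }
  sig$significant <- sig$adjusted_p < alpha
  sig
}

#' Recurrence selection of candidate driver genes
#'
#' Keeps genes flagged significant in at least `min_cancer_types` cancer
#' types, then drops cancer types retaining fewer than `min_genes_per_type`
#' of the selected genes (default 6, i.e. types with <= 5 genes are
#' removed).
#'
#' @param table adjusted table from [adjust_gene_significance()]
#' @param min_cancer_types recurrence threshold (default 10)
#' @param min_genes_per_type minimum selected genes for a type to survive
#' @return list with `genes` and `cancer_types`
#' @export
recurrent_gene_selection <- function(table, min_cancer_types = 10L,
                                     min_genes_per_type = 6L) {
  sig <- table[table$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig) == 0L) return(list(genes = character(0),
                                   cancer_types = character(0)))
  per_gene <- tapply(sig$cancer_type, sig$gene,
                     function(x) length(unique(x)))
  genes <- names(per_gene)[per_gene >= min_cancer_types]
  sub <- sig[sig$gene %in% genes, , drop = FALSE]
  per_type <- tapply(sub$gene, sub$cancer_type,
                     function(x) length(unique(x)))
  types <- names(per_type)[per_type >= min_genes_per_type]
  list(genes = sort(genes), cancer_types = sort(types))
}

#' Driver-set enrichment by one-sided Kolmogorov-Smirnov test
#'
#' Tests whether the -log10 adjusted p-values of known driver genes are
#' stochastically larger (more significant) than those of the gene
#' population. Zero adjusted p-values are floored before the transform; the
#' number floored is recorded in the `n_floored` attribute.
#'
#' @param driver_adj_p adjusted p-values of the known driver genes
#' @param all_adj_p adjusted p-values of all genes
#' @param p_floor replacement for zero p (default: smallest positive normal
#'   double)
#' @return one-sided KS p-value
#' @export
driver_enrichment_ks <- function(driver_adj_p, all_adj_p,
                                 p_floor = .Machine$double.xmin) {
  if (length(driver_adj_p) == 0L || length(all_adj_p) == 0L)
    crcs_stop("both p-value sets must be nonempty", "crcs_empty_input")
  n_floored <- sum(driver_adj_p <= 0) + sum(all_adj_p <= 0)
  x <- -log10(pmax(driver_adj_p, p_floor))
  y <- -log10(pmax(all_adj_p, p_floor))
  # alternative "less": the CDF of x lies below that of y, i.e. the driver
  # transforms are stochastically larger
  p <- suppressWarnings(stats::ks.test(x, y, alternative = "less")$p.value)
  structure(p, n_floored = n_floored)
}
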