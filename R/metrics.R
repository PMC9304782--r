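#' Average precision (area under the precision-recall curve)
#'
#' Computed as the step-wise sum over distinct score thresholds in
#' descending order: AP = sum_k (R_k - R_(k-1)) P_k. For untied scores this
#' equals the mean of precision at the rank of each positive; a single tie
#' group collapses to one PR point, giving the positive prevalence.
#'
#' @param scores numeric vector
#' @param labels binary vector (1 = positive)
#' @return AP in \[0, 1\]
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L)
    crcs_stop("average precision undefined without positives",
              "crcs_undefined_metric")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y == 1)
  fp <- cumsum(y != 1)
  last <- which(c(s[-1] != s[-length(s)], TRUE))  # last row of each tie group
  tp_k <- tp[last]; fp_k <- fp[last]
  prec <- tp_k / (tp_k + fp_k)
  rec <- tp_k / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-matrix metrics at a score threshold
#'
#' Predictions are positive where score >= threshold.
#' @param scores,labels as in [average_precision()]
#' @param threshold decision threshold (default 0.9)
#' @return named vector (sensitivity, specificity, f1)
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.9) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fn <- sum(!pred & labels == 1)
  fp <- sum(pred & labels != 1)
  tn <- sum(!pred & labels != 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  c(sensitivity = sens, specificity = spec, f1 = f1)
}

mwu_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' One-sided Mann-Whitney U test (first group stochastically larger)
#'
#' Exact p by enumeration of all group assignments of the pooled values when
#' n_a + n_b <= `exact_max_n` (ties handled exactly by the permutation), and
#' the normal approximation with tie correction (and continuity correction)
#' otherwise.
#'
#' @param a,b numeric samples
#' @param exact_max_n pooled-size cutoff for the exact branch (default 12)
#' @return one-sided p-value for the alternative a > b
#' @export
compare_distributions <- function(a, b, exact_max_n = 12L) {
  if (length(a) == 0L || length(b) == 0L)
    crcs_stop("both groups must be nonempty", "crcs_empty_input")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  u_obs <- mwu_statistic(a, b)
  if (N <= exact_max_n) {
    pool <- c(a, b)
    combos <- utils::combn(N, n1)
    u_all <- apply(combos, 2, function(ix)
      mwu_statistic(pool[ix], pool[-ix]))
    return(mean(u_all >= u_obs - 1e-9))
  }
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  mu <- n1 * n2 / 2
  z <- (u_obs - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}
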