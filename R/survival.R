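#' Cumulative per-patient BLACs score
#'
#' Mean over a patient's mutations of 2^(k * score) - 1: mutations with high
#' cancer-likeness probabilities receive exponentially higher weight. The
#' value lies in \[0, 2^k - 1\] and is invariant to score order.
#'
#' @param scores per-mutation BLAC probabilities in \[0, 1\]
#' @param k scaling factor (default 4)
#' @return nonnegative scalar
#' @export
blacs_score <- function(scores, k = 4) {
  if (length(scores) == 0L)
    crcs_stop("patient has no mutation scores", "crcs_empty_input")
  if (any(scores < 0 | scores > 1))
    crcs_stop("scores must lie in [0, 1]", "crcs_validation_error")
  mean(2^(k * scores) - 1)
}

#' Patient profile constructor
#'
#' @param patient_id,cancer_type identifiers
#' @param mutation_scores per-mutation BLAC scores in \[0, 1\]
#' @param survival_time nonnegative overall-survival time
#' @param event 1 = death observed, 0 = censored
#' @return list of class `patient_profile`
#' @export
patient_profile <- function(patient_id, cancer_type, mutation_scores,
                            survival_time, event) {
  if (any(mutation_scores < 0 | mutation_scores > 1))
    crcs_stop("mutation scores must lie in [0, 1]", "crcs_validation_error")
  if (survival_time < 0)
    crcs_stop("negative survival time", "crcs_validation_error")
  structure(list(patient_id = patient_id, cancer_type = cancer_type,
                 mutation_scores = mutation_scores,
                 survival_time = survival_time, event = as.integer(event)),
            class = "patient_profile")
}

#' Cohort filters for survival analysis
#'
#' Removes patients with fewer than `min_mutations` scored mutations, then
#' drops cancer types left with fewer than `min_patients` patients. Removal
#' counts are recorded in the `counts` attribute.
#'
#' @param patients list of `patient_profile`
#' @param min_mutations per-patient mutation floor (default 5)
#' @param min_patients per-cancer-type patient floor (default 100)
#' @return filtered list, grouped implicitly by `cancer_type`
#' @export
cohort_filters <- function(patients, min_mutations = 5L,
                           min_patients = 100L) {
  n0 <- length(patients)
  keep <- vapply(patients, function(p)
    length(p$mutation_scores) >= min_mutations, logical(1))
  patients <- patients[keep]
  n_after_mut <- length(patients)
  types <- vapply(patients, function(p) p$cancer_type, character(1))
  tab <- table(types)
  ok_types <- names(tab)[tab >= min_patients]
  patients <- patients[types %in% ok_types]
  attr(patients, "counts") <- data.frame(
    stage = c("min_mutations", "min_patients"),
    n_in = c(n0, n_after_mut),
    n_out = c(n_after_mut, length(patients)))
  patients
}

#' Log-rank (Mantel-Haenszel) test for two survival groups
#'
#' Accumulates observed-minus-expected events in group A over the distinct
#' event times of the pooled sample, with the hypergeometric variance;
#' events at a time are counted before censorings at the same time. The
#' statistic is chi-square with 1 df.
#'
#' @param times_a,events_a survival times and event indicators of group A
#' @param times_b,events_b same for group B
#' @return list with `chi2` and `p`
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    crcs_stop("both survival groups must be nonempty", "crcs_empty_input")
  if (any(c(times_a, times_b) < 0))
    crcs_stop("negative survival times", "crcs_validation_error")
  ev_times <- sort(unique(c(times_a[events_a == 1], times_b[events_b == 1])))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    n1 <- sum(times_a >= t)
    n2 <- sum(times_b >= t)
    d1 <- sum(times_a == t & events_a == 1)
    d2 <- sum(times_b == t & events_b == 1)
    n <- n1 + n2
    d <- d1 + d2
    if (n < 2 || d == 0) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Chi-square-optimal dichotomizing threshold
#'
#' Scans candidate cutpoints (midpoints of consecutive distinct scores,
#' subject to minimum group-size constraints) and returns the one maximizing
#' the log-rank chi-square of the induced two-group split. Ties break to the
#' lowest threshold.
#'
#' @param scores per-patient BLACs scores
#' @param times,events survival data aligned with `scores`
#' @param min_group_frac minimum fraction of patients on each side of the
#'   cut (default 0.1)
#' @param min_group_n minimum patients on each side (default 5)
#' @return the selected threshold; the scanned candidates and their
#'   chi-square values are attached as attribute `scan`
#' @export
optimal_threshold <- function(scores, times, events, min_group_frac = 0.1,
                              min_group_n = 5L) {
  s <- sort(unique(scores))
  if (length(s) < 2L)
    crcs_stop("no admissible cutpoint: fewer than 2 distinct scores",
              "crcs_no_cutpoint")
  cand <- (s[-1] + s[-length(s)]) / 2
  n <- length(scores)
  need <- max(min_group_n, ceiling(min_group_frac * n))
  chi2 <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    hi <- scores >= cand[i]
    if (sum(hi) < need || sum(!hi) < need) next
    chi2[i] <- logrank_test(times[hi], events[hi],
                            times[!hi], events[!hi])$chi2
  }
  if (all(is.na(chi2)))
    crcs_stop("no admissible cutpoint under the group-size constraints",
              "crcs_no_cutpoint")
  best <- which(chi2 >= max(chi2, na.rm = TRUE) - 1e-12)[1]
  structure(cand[best], scan = data.frame(threshold = cand, chi2 = chi2))
}

#' Kaplan-Meier curve table
#' @keywords internal
km_table <- function(times, events, group) {
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  st <- summary(fit)
  strata <- if (is.null(st$strata)) rep(levels(factor(group))[1],
                                        length(st$time))
            else sub("^group=", "", as.character(st$strata))
  data.frame(group = strata, time = st$time, survival = st$surv,
             n_risk = st$n.risk, n_event = st$n.event)
}

#' Stratify patients by BLACs score and test survival separation
#'
#' Per cancer type: computes the BLACs score of every patient, finds the
#' chi-square-optimal threshold, assigns patients with score >= threshold to
#' the high-risk group, and tests the two groups with the log-rank test.
#' Kaplan-Meier survival estimates for both groups are returned alongside.
#'
#' @param patients list of `patient_profile` (apply [cohort_filters()]
#'   first)
#' @param k BLACs scaling factor (default 4)
#' @param min_group_frac,min_group_n threshold-search constraints (see
#'   [optimal_threshold()])
#' @return named list (one entry per cancer type) of class
#'   `stratified_cohort` elements: patient table (id, blacs, group),
#'   threshold, chi2, p, and the KM curve table
#' @export
stratify_and_test <- function(patients, k = 4, min_group_frac = 0.1,
                              min_group_n = 5L) {
  types <- vapply(patients, function(p) p$cancer_type, character(1))
  out <- list()
  for (ct in unique(types)) {
    sub <- patients[types == ct]
    blacs <- vapply(sub, function(p) blacs_score(p$mutation_scores, k),
                    numeric(1))
    times <- vapply(sub, function(p) p$survival_time, numeric(1))
    events <- vapply(sub, function(p) p$event, numeric(1))
    thr <- optimal_threshold(blacs, times, events,
                             min_group_frac = min_group_frac,
                             min_group_n = min_group_n)
    hi <- blacs >= thr
    lr <- logrank_test(times[hi], events[hi], times[!hi], events[!hi])
    grp <- ifelse(hi, "high", "low")
    out[[ct]] <- structure(list(
      cancer_type = ct,
      patients = data.frame(
        patient_id = vapply(sub, function(p) p$patient_id, character(1)),
        blacs = blacs, group = grp, time = times, event = events,
        stringsAsFactors = FALSE),
      threshold = as.numeric(thr),
      chi2 = lr$chi2, p = lr$p,
      km = km_table(times, events, grp)), class = "stratified_cohort")
  }
  out
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat(sprintf(
    "<stratified_cohort %s: n=%d (high %d / low %d), thr=%.3f, chi2=%.3f, p=%.4g>\n",
    x$cancer_type, nrow(x$patients), sum(x$patients$group == "high"),
    sum(x$patients$group == "low"), x$threshold, x$chi2, x$p))
  invisible(x)
}
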