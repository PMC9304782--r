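test_that("BLACs score matches its closed forms and bounds", {
  expect_equal(blacs_score(rep(0, 5), k = 4), 0)
  expect_equal(blacs_score(rep(1, 3), k = 4), 15)
  expect_equal(blacs_score(c(0.5, 1.0), k = 4), 9)
  expect_equal(blacs_score(c(1.0, 0.5), k = 4), 9)   # order invariance
  set.seed(41)
  s <- runif(20)
  expect_gte(blacs_score(s, k = 4), 0)
  expect_lte(blacs_score(s, k = 4), 15)
  # strictly increasing in any single mutation score
  s2 <- s; s2[7] <- s2[7] + 0.01
  expect_gt(blacs_score(s2, k = 4), blacs_score(s, k = 4))
  expect_error(blacs_score(numeric(0)), class = "crcs_empty_input")
  expect_error(blacs_score(c(0.5, 1.4)), class = "crcs_validation_error")
})

test_that("cohort filters drop sparse patients then thin cancer types", {
  p_ok <- make_patients(100, "KEEP", n_mut = 6)
  p_few <- make_patients(3, "KEEP", n_mut = 4)       # < 5 mutations
  p_thin <- make_patients(99, "THIN", n_mut = 6)     # 99 < 100 patients
  out <- cohort_filters(c(p_ok, p_few, p_thin))
  types <- vapply(out, function(p) p$cancer_type, "")
  expect_equal(sum(types == "KEEP"), 100L)
  expect_false("THIN" %in% types)
  counts <- attr(out, "counts")
  expect_equal(counts$n_in, c(202L, 199L))
  expect_equal(counts$n_out, c(199L, 100L))
  expect_length(cohort_filters(list()), 0L)
})

test_that("log-rank test matches the survival package and symmetry", {
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p, 1)

  check_vs_survdiff <- function(ta, ea, tb, eb) {
    ours <- logrank_test(ta, ea, tb, eb)
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~
        rep(c("a", "b"), c(length(ta), length(tb))))
    expect_equal(ours$chi2, unname(sd$chisq), tolerance = 1e-10)
  }
  # hand case: all A events precede all B events
  check_vs_survdiff(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  # random instances with censoring and ties
  set.seed(42)
  for (rep in 1:25) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    ta <- sample(1:6, na, replace = TRUE)
    tb <- sample(1:6, nb, replace = TRUE)
    ea <- rbinom(na, 1, 0.7); eb <- rbinom(nb, 1, 0.7)
    if (sum(ea) + sum(eb) == 0) ea[1] <- 1
    check_vs_survdiff(ta, ea, tb, eb)
  }
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1),
               class = "crcs_empty_input")
})

test_that("log-rank agrees with a permutation reference", {
  set.seed(43)
  ta <- rexp(10, 0.5); tb <- rexp(10, 1.5)
  ea <- rep(1, 10); eb <- rep(1, 10)
  obs <- logrank_test(ta, ea, tb, eb)
  pool_t <- c(ta, tb); pool_e <- c(ea, eb)
  n_perm <- 2000
  stat <- replicate(n_perm, {
    ix <- sample(20, 10)
    logrank_test(pool_t[ix], pool_e[ix], pool_t[-ix], pool_e[-ix])$chi2
  })
  p_perm <- mean(stat >= obs$chi2 - 1e-12)
  expect_lt(abs(obs$p - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / n_perm) +
              0.02)
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  times <- c(1, 2, 2, 3, 5, 8)
  km <- crcs:::km_table(times, rep(1, 6), rep("g", 6))
  emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$survival, emp)
})

test_that("optimal threshold maximizes the log-rank chi-square", {
  scores <- c(1, 2, 3, 4)
  times <- c(10, 9, 1, 1.5)
  events <- rep(1, 4)
  thr <- optimal_threshold(scores, times, events, min_group_frac = 0,
                           min_group_n = 1)
  expect_gt(as.numeric(thr), 2)
  expect_lt(as.numeric(thr), 3)
  scan <- attr(thr, "scan")
  best <- scan$chi2[scan$threshold == as.numeric(thr)]
  expect_true(all(scan$chi2 <= best + 1e-12, na.rm = TRUE))
  # permutation of patients changes nothing
  o <- c(3, 1, 4, 2)
  thr2 <- optimal_threshold(scores[o], times[o], events[o],
                            min_group_frac = 0, min_group_n = 1)
  expect_equal(as.numeric(thr2), as.numeric(thr))
  expect_error(optimal_threshold(rep(2, 5), 1:5, rep(1, 5)),
               class = "crcs_no_cutpoint")
})

test_that("stratification recovers a planted hazard link", {
  pats <- simulate_patient_profiles(150, "T1", gamma = 0.35,
                                    censoring_rate = 0.15, seed = 44)
  res <- stratify_and_test(pats, k = 4)
  expect_length(res, 1L)
  sc <- res[["T1"]]
  expect_lt(sc$p, 0.1)
  hi <- sc$patients$group == "high"
  med <- function(t, e) summary(survival::survfit(
    survival::Surv(t, e) ~ 1))$table["median"]
  expect_lt(med(sc$patients$time[hi], sc$patients$event[hi]),
            med(sc$patients$time[!hi], sc$patients$event[!hi]))
  expect_true(all(sc$patients$blacs[hi] >= sc$threshold))
  expect_true(all(sc$patients$blacs[!hi] < sc$threshold))
  # two cancer types in, two stratified cohorts out
  pats2 <- c(pats, simulate_patient_profiles(120, "T2", gamma = 0,
                                             seed = 45))
  expect_length(stratify_and_test(pats2), 2L)
})
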