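test_that("threshold follows the baseline-referenced formula", {
  b <- structure(list(mean = 453.41, sd = 29.42), class = "baseline_stats")
  expect_equal(compute_threshold(b, 1.85), 453.41 - 1.85 * 29.42)
  expect_equal(round(compute_threshold(b, 1.85), 2), 398.98)
  expect_equal(compute_threshold(b, 0), 453.41)
  b0 <- structure(list(mean = 450, sd = 0), class = "baseline_stats")
  expect_equal(compute_threshold(b0, 1.85), 450)
  expect_error(compute_threshold(b, -1), "non-negative")
})

test_that("classification agrees with a brute-force scan on random patterns", {
  set.seed(21)
  base <- list(mean = 450, sd = 30)
  model2 <- threshold_model(1.85, "two_consecutive")
  model1 <- threshold_model(1.85, "first_occurrence")
  thr <- 450 - 1.85 * 30
  for (i in 1:200) {
    n <- sample(5:60, 1)
    # upper bounds scattered around the threshold so both labels occur
    ub <- thr + rnorm(n, sd = 25)
    sm <- make_summaries(ub, baseline = base)
    q <- ub < thr
    for (model in list(model1, model2)) {
      want <- oracle_onset(q, model$rule)
      got <- classify_subject(sm, model)
      if (is.na(want)) {
        expect_equal(got$label, "NOEXP")
        # block of interest is the argmin-z block
        expect_equal(got$block_of_interest, which.min(sm$z_mean))
      } else {
        expect_equal(got$label, "EXP")
        expect_equal(got$onset_repetition, want)
        expect_equal(got$onset_block, sm$block[want])
        expect_equal(got$block_of_interest, got$onset_block)
      }
    }
  }
})

test_that("the two rules differ on an isolated qualifying repetition", {
  base <- list(mean = 450, sd = 30)
  thr <- 450 - 1.85 * 30
  ub <- c(450, thr - 10, 450, thr - 10, thr - 10, 450)
  sm <- make_summaries(ub, baseline = base)
  two <- classify_subject(sm, threshold_model(1.85, "two_consecutive"))
  one <- classify_subject(sm, threshold_model(1.85, "first_occurrence"))
  expect_equal(one$onset_repetition, 2L)
  expect_equal(two$onset_repetition, 5L)
  expect_equal(two$first_of_pair, 4L)
  # a tie with the threshold does not qualify
  tie <- make_summaries(c(450, thr, thr, 450), baseline = base)
  expect_equal(classify_subject(tie, threshold_model(1.85))$label, "NOEXP")
})

test_that("a flat subject is NOEXP with an argmin-z block of interest", {
  base <- list(mean = 450, sd = 30)
  sm <- make_summaries(rep(450, 20), blocks = 2 + (0:19) %/% 5,
                       baseline = base)
  sm$z_mean <- sm$z_mean + c(rep(0, 11), -0.2, rep(0, 8))
  r <- classify_subject(sm, threshold_model())
  expect_equal(r$label, "NOEXP")
  expect_equal(r$block_of_interest, sm$block[12])
  expect_true(is.na(r$onset_repetition))
})

test_that("confusion statistics reproduce the worked group counts", {
  cc <- confusion_counts(tp = 9, fn = 2, tn = 10, fp = 0)
  expect_equal(round(100 * cc$sensitivity, 1), 81.8)
  expect_equal(cc$specificity, 1)
  cc2 <- confusion_counts(tp = 8, fn = 0, tn = 21, fp = 0)
  expect_equal(cc2$sensitivity, 1)
  expect_equal(cc2$specificity, 1)
  cc3 <- confusion_counts(tp = 0, fn = 5, tn = 0, fp = 0)
  expect_equal(cc3$sensitivity, 0)
  expect_true(is.na(cc3$specificity))  # undefined denominator
})

test_that("cohort scoring matches labels against recall truth", {
  labels <- c("EXP", "EXP", "NOEXP", "NOEXP", "EXP")
  recall <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  cc <- score_cohort(labels, recall, subject_ids = paste0("S", 1:5))
  expect_equal(cc$tp, 2L)
  expect_equal(cc$fp, 1L)
  expect_equal(cc$fn, 1L)
  expect_equal(cc$tn, 1L)
  expect_equal(cc$fn_subjects, "S3")
  expect_error(score_cohort(labels, recall[-1]), "lengths differ")
  expect_error(score_cohort(labels, c(recall[-1], NA)), "missing truth")
})

test_that("sweep grid is inclusive with 201 default values", {
  sm <- list(make_summaries(rep(450, 10)), make_summaries(rep(300, 10)))
  sw <- sweep_z(sm, c(FALSE, TRUE))
  expect_equal(length(unique(sw$z)), 201L)
  expect_equal(min(sw$z), 0.5)
  expect_equal(max(sw$z), 2.5)
  expect_equal(nrow(sw), 402L)
  # clean separation: perfect classification across the whole grid
  expect_true(all(sw$sensitivity == 1))
  expect_true(all(sw$specificity == 1))
  expect_error(sweep_z(sm, c(FALSE, TRUE), step = 0), "positive")
})

test_that("sweep classifications match per-z classify_subject calls", {
  lay <- default_layout()
  coh <- simulate_cohort(cohort_config(n_exp = 4, n_noexp = 4,
                                       rng_seed = 17), lay)
  res <- classify_cohort(coh, lay)
  tr <- cohort_truth(coh)
  sw <- sweep_z(res$summaries, tr$truth_recall)
  for (z in c(0.5, 1.23, 1.85, 2.5)) {
    for (rule in c("first_occurrence", "two_consecutive")) {
      labels <- vapply(res$summaries, function(s)
        classify_subject(s, threshold_model(z, rule))$label, character(1))
      cc <- score_cohort(labels, tr$truth_recall)
      row <- sw[abs(sw$z - z) < 1e-9 & sw$rule == rule, ]
      expect_equal(row$tp, cc$tp)
      expect_equal(row$fn, cc$fn)
      expect_equal(row$tn, cc$tn)
      expect_equal(row$fp, cc$fp)
    }
  }
})

test_that("the classifier never consults ground truth", {
  # classification is a pure function of summaries + model: permuting the
  # truth labels cannot change the labels produced
  lay <- default_layout()
  coh <- simulate_cohort(cohort_config(n_exp = 2, n_noexp = 2,
                                       rng_seed = 19), lay)
  res <- classify_cohort(coh, lay)
  labels1 <- vapply(res$classifications, `[[`, character(1), "label")
  res2 <- classify_cohort(coh, lay)
  expect_identical(labels1,
                   vapply(res2$classifications, `[[`, character(1), "label"))
  expect_false("truth_label" %in% names(formals(classify_subject)))
})
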