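test_that("spearman recovers perfect monotone association", {
  expect_equal(spearman_cor(1:9, 1:9)$rho, 1)
  expect_equal(spearman_cor(1:9, 9:1)$rho, -1)
  expect_equal(spearman_cor(1:9, exp(1:9))$rho, 1)  # monotone transform
  expect_error(spearman_cor(rep(3, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("small-sample rho and p match full permutation enumeration", {
  cases <- list(
    list(x = c(4, 9, 12, 15, 20, 23), y = c(5, 7, 7, 14, 19, 25)),  # tie
    list(x = c(1, 2, 3, 4, 5, 6), y = c(2, 1, 4, 3, 6, 5)),
    list(x = c(3, 10, 5, 24, 13, 8), y = c(22, 8, 14, 3, 3, 17)))  # ties
  for (cs in cases) {
    got <- spearman_cor(cs$x, cs$y)
    expect_equal(got$method, "exact")
    expect_equal(got$rho, oracle_rho(cs$x, cs$y))
    expect_equal(got$p_value, oracle_spearman_p(cs$x, cs$y))
  }
})

test_that("large-sample p uses the t-approximation", {
  set.seed(41)
  x <- rnorm(12)
  y <- x + rnorm(12)
  got <- spearman_cor(x, y)
  expect_equal(got$method, "t-approximation")
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(43)
  for (i in 1:20) {
    x <- sample(1:27, 9)
    y <- sample(1:27, 9)
    a <- spearman_cor(x, y)
    b <- spearman_cor(2 * x + 3, y^3)
    expect_equal(a$rho, b$rho)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("neurobehavioral correlation excludes false negatives", {
  beh <- data.frame(subject_id = sprintf("S%02d", 1:12),
                    label = rep(c("EXP", "NOEXP"), each = 6),
                    block_of_interest = c(4, 7, 10, 14, 18, 22,
                                          5, 9, 12, 16, 20, 24))
  # S07 actually recalled the sequence: a false negative
  recall <- setNames(c(rep(TRUE, 6), TRUE, rep(FALSE, 5)),
                     beh$subject_id)
  peaks <- data.frame(subject_id = rep(beh$subject_id, 2),
                      component = rep(c("P3", "P2"), each = 12),
                      peak_block = c(beh$block_of_interest,
                                     rev(beh$block_of_interest)))
  rep_ <- neurobehavioral_correlation(beh, peaks, recall)
  expect_identical(attr(rep_, "excluded"), "S07")
  expect_true(all(rep_$n[rep_$group == "NOEXP"] == 5))
  expect_true(all(rep_$n[rep_$group == "EXP"] == 6))
  expect_equal(rep_$rho[rep_$group == "EXP" & rep_$component == "P3"], 1)
  # Holm-adjusted p never drops below the raw p and keeps its ordering
  expect_true(all(rep_$p_holm >= rep_$p_value - 1e-12))
  for (grp in c("EXP", "NOEXP")) {
    g <- rep_[rep_$group == grp, ]
    expect_true(all(diff(g$p_holm[order(g$p_value)]) >= -1e-12))
  }
})

test_that("group smaller than three subjects is refused", {
  beh <- data.frame(subject_id = c("S1", "S2", "S3", "S4"),
                    label = c("EXP", "EXP", "NOEXP", "NOEXP"),
                    block_of_interest = c(4, 8, 12, 16))
  peaks <- data.frame(subject_id = beh$subject_id, component = "P3",
                      peak_block = c(5, 9, 13, 17))
  expect_error(neurobehavioral_correlation(beh, peaks), "fewer than 3")
})

test_that("P3-latency association flags degenerate subjects", {
  lat <- data.frame(subject_id = "S01", block = 1:10,
                    mean_latency = seq(450, 360, by = -10))
  p3 <- data.frame(subject_id = "S01", block = 1:10,
                   amplitude = 0.5 * seq(450, 360, by = -10))
  out <- p3_latency_association(p3, lat, c(S01 = "EXP"))
  expect_equal(out$per_subject$r, 1)
  expect_equal(out$per_subject$slope, 0.5)
  # constant amplitude: correlation undefined, reported as NA
  p3c <- transform(p3, amplitude = 7)
  outc <- p3_latency_association(p3c, lat, c(S01 = "EXP"))
  expect_true(is.na(outc$per_subject$r))
  # too few blocks: skipped with a warning
  expect_warning(
    res <- p3_latency_association(p3[1:3, ], lat, c(S01 = "EXP")),
    "fewer than")
  expect_null(res$per_subject)
})

test_that("uncorrelated amplitude gives near-zero mean r", {
  set.seed(47)
  rs <- replicate(200, {
    lat <- data.frame(subject_id = "S01", block = 1:20,
                      mean_latency = rnorm(20, 400, 30))
    p3 <- data.frame(subject_id = "S01", block = 1:20,
                     amplitude = rnorm(20, 100, 10))
    p3_latency_association(p3, lat, c(S01 = "EXP"))$per_subject$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("peak ordering uses the canonical tie-break", {
  peaks <- data.frame(subject_id = "S01",
                      component = c("earlyN1", "P2", "lateN1", "P3"),
                      peak_block = c(9, 9, 9, 9))
  po <- peak_order_summary(peaks, c(S01 = "EXP"))
  expect_equal(po$per_subject$order, "P3 -> lateN1 -> P2 -> earlyN1")
  expect_error(peak_order_summary(peaks[-1, ], c(S01 = "EXP")),
               "earlyN1")
})

test_that("lagged coupled peaks order along the expected progression", {
  lay <- default_layout()
  cfg <- cohort_config(n_exp = 5, n_noexp = 0, onset_early_range = 3:15,
                       onset_late_range = 16:20, rng_seed = 51)
  coh <- simulate_cohort(cfg, lay)
  erp <- simulate_erp(coh, erp_sim_config(coupling = 1, noise_sd = 0,
                                          global_p3_decline = 0))
  pk <- peak_block_table(erp)
  po <- peak_order_summary(pk, setNames(rep("EXP", 5),
                                        sprintf("S%02d", 1:5)))
  expect_true(all(startsWith(po$per_subject$order, "P3 -> lateN1")))
  # group means recomputed directly
  for (cm in c("P3", "lateN1", "P2", "earlyN1")) {
    expect_equal(
      po$group_means$peak_block[po$group_means$component == cm],
      mean(pk$peak_block[pk$component == cm]))
  }
})
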