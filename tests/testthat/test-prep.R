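test_that("exp1 cleaning drops unrecorded/out-of-window trials and reports", {
  tr <- make_trials(rep(400, 100))
  tr$recorded[1:15] <- FALSE
  tr$latency[1:15] <- NA
  cl <- clean_trials(tr, mode = "exp1")
  expect_equal(cl$report$n_retained, 85L)
  expect_equal(cl$report$removal_fraction, 0.15)
  # out-of-window recorded responses also removed in exp1
  tr2 <- make_trials(c(-50, 400, 800, 750, 0.5))
  cl2 <- clean_trials(tr2, mode = "exp1")
  expect_equal(cl2$trials$latency, c(400, 750, 0.5))
})

test_that("exp2 cleaning retains anticipatory negative latencies", {
  tr <- make_trials(c(-120, 300, 400))
  cl <- clean_trials(tr, mode = "exp2")
  expect_equal(cl$trials$latency, c(-120, 300, 400))
  expect_equal(cl$report$removal_fraction, 0)
  # full pass-through when everything is recorded and correct
  tr3 <- make_trials(rep(500, 10))
  expect_equal(clean_trials(tr3, "exp2")$trials$latency, tr3$latency)
  expect_error(clean_trials(tr3[0, ], "exp2"), "empty")
})

test_that("baseline statistics follow the mode conventions", {
  # exp1: first 45 presses
  tr <- make_trials(c(rep(400, 45), rep(300, 55)))
  b <- compute_baseline(tr, mode = "exp1")
  expect_equal(b$mean, 400)
  expect_equal(b$sd, 0)
  expect_equal(b$n, 45L)
  # sample statistics verified against the direct formulas
  tr2 <- make_trials(as.numeric(1:45))
  b2 <- compute_baseline(tr2, mode = "exp1")
  expect_equal(b2$mean, 23)
  expect_equal(b2$sd, sqrt(sum((1:45 - 23)^2) / 44))
  # insufficient baseline is a hard error
  expect_error(compute_baseline(make_trials(rep(400, 30)), mode = "exp1"),
               "insufficient baseline")
  # exp1 baseline counts accurate presses only (configurable)
  tr3 <- make_trials(c(rep(999, 5), rep(400, 45)))
  tr3$correct[1:5] <- FALSE
  expect_equal(compute_baseline(tr3, mode = "exp1")$mean, 400)
  expect_equal(compute_baseline(tr3, mode = "exp1",
                                accurate_only = FALSE)$n, 45L)
})

test_that("exp2 baseline uses accurate responses of the random block", {
  lat <- c(rep(380, 30), rep(800, 5))
  tr <- make_trials(lat, block = 1L, phase = "baseline")
  tr$correct[31:35] <- FALSE
  b <- compute_baseline(tr, mode = "exp2")
  expect_equal(b$n, 30L)
  expect_equal(b$mean, 380)
  tr$correct[] <- FALSE
  expect_error(compute_baseline(tr, mode = "exp2"),
               "insufficient baseline")
})

test_that("repetition summaries partition, bound and z-score correctly", {
  base <- structure(list(mean = 450, sd = 30, n = 45, mode = "exp1"),
                    class = "baseline_stats")
  tr <- make_trials(rep(400, 7))
  s <- summarize_repetitions(tr, 7L, baseline = base)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mean_latency, 400)
  expect_equal(s$upper_ci, 400)  # zero-variance repetition
  expect_equal(s$z_mean, -5 / 3)
  # one-sided 95% Student-t bound against the direct formula
  lat <- c(400, 410, 390, 405, 395, 400, 400)
  s2 <- summarize_repetitions(make_trials(lat), 7L, baseline = base)
  expect_equal(s2$upper_ci,
               mean(lat) + qt(0.95, 6) * sd(lat) / sqrt(7))
  expect_gt(s2$upper_ci, s2$mean_latency)
  # degenerate baseline refuses to z-score
  bad <- base; bad$sd <- 0
  expect_error(summarize_repetitions(make_trials(lat), 7L, baseline = bad),
               "degenerate baseline")
})

test_that("a silent repetition inherits the previous mean and is flagged", {
  lat <- c(rep(420, 7), rep(NA, 7), rep(380, 7))
  tr <- make_trials(lat)
  tr$recorded[8:14] <- FALSE
  s <- summarize_repetitions(tr, 7L)
  expect_equal(s$mean_latency, c(420, 420, 380))
  expect_identical(s$imputed, c(FALSE, TRUE, FALSE))
  expect_equal(s$n_responses, c(7L, 0L, 7L))
  expect_equal(s$upper_ci[2], 420)  # bound collapses to the carried mean
})

test_that("partition is complete and z-transform inverts", {
  lay <- default_layout()
  coh <- simulate_cohort(cohort_config(n_exp = 1, n_noexp = 1,
                                       rng_seed = 5), lay)
  for (s in coh) {
    cl <- clean_trials(s$trials, "exp2")
    b <- compute_baseline(cl, "exp2")
    sm <- summarize_repetitions(cl, 7L, baseline = b, layout = lay)
    expect_equal(nrow(sm), 130L)
    # every cleaned sequence trial lands in exactly one repetition
    n_seq <- sum(cl$trials$phase == "sequence" & cl$trials$correct)
    expect_equal(sum(sm$n_responses), n_seq)
    # z inverts back to the latency scale
    expect_equal(sm$z_mean * b$sd + b$mean, sm$mean_latency,
                 tolerance = 1e-9)
    expect_equal(sm$z_upper_ci * b$sd + b$mean, sm$upper_ci,
                 tolerance = 1e-9)
  }
})

test_that("upper bound shrinks toward the mean as n grows", {
  ub <- vapply(c(2, 5, 10, 30, 100), function(n)
    srttaware:::upper_conf_bound(400, 30, n), numeric(1))
  expect_true(all(diff(ub) < 0))
  expect_true(all(ub > 400))
})

test_that("repetitions map onto blocks per design", {
  lay <- default_layout()
  expect_equal(map_repetition_to_block(1, lay), 2L)
  expect_equal(map_repetition_to_block(5, lay), 2L)
  expect_equal(map_repetition_to_block(6, lay), 3L)
  expect_equal(map_repetition_to_block(130, lay), 27L)
  expect_error(map_repetition_to_block(131, lay), "out of range")
  lay1 <- build_block_layout("exp1", c(3, 4, 2, 1, 3, 2, 4))
  expect_equal(map_repetition_to_block(1, lay1), 1L)
  expect_equal(map_repetition_to_block(26, lay1), 1L)
  expect_equal(map_repetition_to_block(27, lay1), 2L)
  expect_equal(map_repetition_to_block(130, lay1), 5L)
})

test_that("trial tables round-trip through CSV", {
  lay <- default_layout()
  coh <- simulate_cohort(cohort_config(n_exp = 1, n_noexp = 0,
                                       rng_seed = 3), lay)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(coh[[1]]$trials, path)
  back <- read_trials(path)
  expect_equal(back$latency, coh[[1]]$trials$latency)
  expect_identical(back$recorded, coh[[1]]$trials$recorded)
  expect_error(read_trials(file.path(tempdir(), "nope.csv")), "not found")
})
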