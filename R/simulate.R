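#' Cohort simulation configuration
#'
#' Defaults emulate the EEG-design cohort: 9 subjects who develop explicit
#' awareness (EXP) and 10 who do not (NOEXP).  Per-subject baseline means
#' are drawn around 455 ms (between-subject SD 35 ms) with per-subject
#' trial SDs around 40 ms, matching the baseline latency scale of the
#' behavioral cohorts (~440-470 ms means, ~30-50 ms SDs).  All subjects
#' drift gradually toward a final z of `implicit_slope` (-1.1, implicit
#' learning); EXP subjects additionally shift abruptly after their
#' awareness-onset block so their final z reaches `explicit_drop` (-4.0).
#' Onset blocks are drawn from an early/late mixture split at block 20
#' (5:4 odds early), spanning blocks 2-27.  Accuracy is ~97% and responses
#' are essentially always recorded in the EEG design (the exp1 emulation
#' uses ~15% unrecorded).
#'
#' @param n_exp,n_noexp Group sizes.
#' @param n_fn Number of "false-negative archetype" subjects: full recall
#'   (`truth_recall = TRUE`) but a drop (`fn_drop`) too shallow to cross a
#'   typical threshold.
#' @param baseline_mean_dist,baseline_sd_dist Mean and SD (across subjects)
#'   of the per-subject baseline mean latency and trial SD, in ms.
#' @param implicit_slope Final z reached by gradual implicit drift
#'   (negative; applies to all subjects).
#' @param explicit_drop Final z reached by EXP subjects (negative; the
#'   post-onset shift ramps the profile from the implicit trend to this
#'   value).
#' @param fn_drop Final z for false-negative archetype subjects.
#' @param onset_early_prob Probability that an EXP onset falls before block
#'   20 ("Early Learner"); onsets are uniform within `onset_early_range`
#'   (blocks 2-19) or `onset_late_range` (blocks 20-27).
#' @param onset_early_range,onset_late_range Candidate onset blocks for
#'   early and late learners.
#' @param ramp_blocks Width of the post-onset linear ramp, in blocks
#'   (default 2: abrupt but not instantaneous; 0 gives a pure step).
#' @param step_fraction Fraction of the explicit shift applied immediately
#'   at onset (default 0.5); the remainder accrues over the ramp.  The
#'   transition is thus a step plus a finite-width ramp.
#' @param accuracy_rate,unrecorded_rate Per-trial probabilities.
#' @param trial_noise_sd Trial noise SD in ms; `NULL` (default) uses each
#'   subject's own drawn baseline SD.
#' @param rng_seed Optional integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_exp = 9L, n_noexp = 10L, n_fn = 0L,
                          baseline_mean_dist = c(455, 35),
                          baseline_sd_dist = c(40, 8),
                          implicit_slope = -1.1,
                          explicit_drop = -4.0,
                          fn_drop = -1.3,
                          onset_early_prob = 5 / 9,
                          onset_early_range = 2:19,
                          onset_late_range = 20:27,
                          ramp_blocks = 2L,
                          step_fraction = 0.5,
                          accuracy_rate = 0.97,
                          unrecorded_rate = 0,
                          trial_noise_sd = NULL,
                          rng_seed = NULL) {
  stopifnot(n_exp >= 0L, n_noexp >= 0L, n_fn >= 0L,
            accuracy_rate >= 0, accuracy_rate <= 1,
            unrecorded_rate >= 0, unrecorded_rate <= 1,
            onset_early_prob >= 0, onset_early_prob <= 1,
            ramp_blocks >= 0L)
  if (explicit_drop >= 0) {
    stop("explicit_drop must be negative: awareness speeds responses")
  }
  if (implicit_slope > 0) stop("implicit_slope must be <= 0")
  structure(as.list(environment()), class = "cohort_config")
}

# sample(x, 1) with the surprise single-integer behaviour disabled
resample <- function(x) x[sample.int(length(x), 1L)]

# z profile over sequence repetitions for one subject: gradual implicit
# drift plus, after awareness onset, an immediate partial step followed by
# a linear ramp to the full explicit drop ("step plus ramp")
z_profile <- function(n_reps, reps_per_block, first_seq_block,
                      implicit_slope, final_z, onset_block, ramp_blocks,
                      step_fraction = 0.5) {
  t <- seq_len(n_reps) / n_reps
  z <- implicit_slope * t
  if (!is.na(onset_block)) {
    onset_rep <- (onset_block - first_seq_block) * reps_per_block + 1L
    post <- seq_len(n_reps) >= onset_rep
    ramp_reps <- ramp_blocks * reps_per_block
    ramp <- if (ramp_reps > 0) {
      pmin(pmax((seq_len(n_reps) - onset_rep + 1L) / ramp_reps, 0), 1)
    } else {
      as.numeric(post)  # instantaneous step
    }
    frac <- post * step_fraction + (1 - step_fraction) * ramp
    z <- z + frac * (final_z - implicit_slope)
  }
  z
}

#' Simulate a cohort of SRTT subjects
#'
#' Draws per-subject baseline parameters and generates a full trial stream
#' over the supplied layout: latency = baseline mean + z-profile x baseline
#' SD + Gaussian trial noise, with the z profile combining the gradual
#' implicit drift (all subjects) and the abrupt post-onset shift (EXP
#' subjects; a step reached through a linear ramp over `ramp_blocks`
#' blocks).  Accuracy and recorded flags are drawn per trial.  Ground truth
#' (label, recall, onset block) is carried on each subject but written to a
#' separate sidecar by the pipeline, never read by the classifier.
#'
#' @param config A [cohort_config()].
#' @param layout A [build_block_layout()] result (exp2-style by default).
#' @return A `srtt_cohort` list of subjects, each with fields `subject_id`,
#'   `trials` (data frame), `truth_label`, `truth_recall`,
#'   `truth_onset_block`, `baseline_mean`, `baseline_sd`.
#' @examples
#' lay <- build_block_layout("exp2", generate_sequence(7, rng_seed = 1),
#'                           rng_seed = 1)
#' coh <- simulate_cohort(cohort_config(rng_seed = 1), lay)
#' @export
simulate_cohort <- function(config, layout) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  if (!is.null(config$rng_seed)) set.seed(as.integer(config$rng_seed))
  stream <- layout$stream
  n_total <- config$n_exp + config$n_fn + config$n_noexp
  if (n_total == 0L) stop("empty cohort")
  first_seq_block <- if (layout$design == "exp2") 2L else 1L
  subjects <- vector("list", n_total)
  labels <- c(rep("EXP", config$n_exp), rep("FN", config$n_fn),
              rep("NOEXP", config$n_noexp))
  for (i in seq_len(n_total)) {
    mean_i <- stats::rnorm(1, config$baseline_mean_dist[1],
                           config$baseline_mean_dist[2])
    sd_i <- max(5, stats::rnorm(1, config$baseline_sd_dist[1],
                                config$baseline_sd_dist[2]))
    noise_sd <- if (is.null(config$trial_noise_sd)) sd_i else
      config$trial_noise_sd
    kind <- labels[i]
    if (kind == "NOEXP") {
      onset <- NA_integer_
      final_z <- NA_real_
    } else {
      early <- stats::runif(1) < config$onset_early_prob
      onset <- if (early) {
        resample(config$onset_early_range)
      } else {
        resample(config$onset_late_range)
      }
      if (layout$design == "exp1") {
        onset <- min(onset, layout$n_blocks)
      }
      final_z <- if (kind == "EXP") config$explicit_drop else config$fn_drop
    }
    zp <- z_profile(layout$n_repetitions, layout$repetitions_per_block,
                    first_seq_block, config$implicit_slope, final_z,
                    onset, config$ramp_blocks, config$step_fraction)
    z_trial <- rep(0, nrow(stream))
    is_seq <- stream$phase == "sequence"
    z_trial[is_seq] <- zp[stream$repetition[is_seq]]
    lat <- mean_i + z_trial * sd_i + stats::rnorm(nrow(stream), 0, noise_sd)
    correct <- stats::runif(nrow(stream)) < config$accuracy_rate
    recorded <- stats::runif(nrow(stream)) >= config$unrecorded_rate
    if (layout$design == "exp1") {
      # exp1 presentation cannot record presses outside the 750 ms window
      recorded <- recorded & lat > 0 & lat <= 750
    }
    response_key <- ifelse(correct, stream$target_key,
                           ((stream$target_key +
                               sample.int(3L, nrow(stream), replace = TRUE)
                             - 1L) %% 4L) + 1L)
    response_key[!recorded] <- NA_integer_
    trials <- data.frame(
      subject_id = sprintf("S%02d", i),
      block = stream$block,
      stim_index = stream$stim_index,
      phase = stream$phase,
      repetition = stream$repetition,
      target_key = stream$target_key,
      response_key = response_key,
      latency = ifelse(recorded, lat, NA_real_),
      recorded = recorded,
      correct = correct & recorded)
    subjects[[i]] <- list(subject_id = sprintf("S%02d", i),
                          trials = trials,
                          truth_label = if (kind == "NOEXP") "NOEXP" else "EXP",
                          truth_recall = kind != "NOEXP",
                          truth_onset_block = onset,
                          fn_archetype = kind == "FN",
                          baseline_mean = mean_i,
                          baseline_sd = sd_i)
  }
  structure(subjects, layout = layout, config = config,
            class = "srtt_cohort")
}

#' @export
print.srtt_cohort <- function(x, ...) {
  lab <- vapply(x, `[[`, character(1), "truth_label")
  cat(sprintf("Simulated SRTT cohort: %d subjects (%d EXP, %d NOEXP)\n",
              length(x), sum(lab == "EXP"), sum(lab == "NOEXP")))
  invisible(x)
}

#' Ground-truth table of a simulated cohort
#'
#' @param cohort A `srtt_cohort`.
#' @return Data frame with `subject_id`, `truth_label`, `truth_recall`,
#'   `truth_onset_block`, `fn_archetype`.
#' @export
cohort_truth <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    truth_label = vapply(cohort, `[[`, character(1), "truth_label"),
    truth_recall = vapply(cohort, `[[`, logical(1), "truth_recall"),
    truth_onset_block = vapply(cohort, function(s)
      as.integer(s$truth_onset_block), integer(1)),
    fn_archetype = vapply(cohort, `[[`, logical(1), "fn_archetype"))
}

#' ERP simulation configuration
#'
#' Per-block component amplitude series are modelled as a baseline level
#' plus a Gaussian bump around a peak block plus noise.  For EXP subjects
#' the peak block tracks the behavioral awareness onset (plus a
#' component-specific lag emulating the P3 -> late N1 -> P2/early N1
#' progression) with strength `coupling`; for NOEXP subjects peak blocks
#' are uniform over the analysis range.  All subjects also receive a P3
#' trend proportional to per-block mean latency, emulating the global P3
#' decline that follows the general speed-up.
#'
#' @param components Data frame with `name`, `region`, `baseline_amp`
#'   (uV.ms), `peak_gain` (uV.ms), `peak_width` (blocks), `lag` (blocks
#'   after behavioral onset).
#' @param coupling In `[0, 1]`: 1 ties EXP peak blocks exactly to onset +
#'   lag; 0 makes them uniform like NOEXP.
#' @param global_p3_decline Slope of the P3 amplitude trend per ms of
#'   block mean latency (uV.ms per ms).
#' @param noise_sd Amplitude noise SD (uV.ms).
#' @param block_range Blocks eligible to hold a peak (default 3:27).
#' @param rng_seed Optional integer seed.
#' @return An `erp_sim_config` list.
#' @export
erp_sim_config <- function(components = default_erp_components(),
                           coupling = 0.9,
                           global_p3_decline = 0.2,
                           noise_sd = 5,
                           block_range = 3:27,
                           rng_seed = NULL) {
  stopifnot(coupling >= 0, coupling <= 1, all(components$peak_width >= 1))
  structure(list(components = components, coupling = coupling,
                 global_p3_decline = global_p3_decline,
                 noise_sd = noise_sd, block_range = block_range,
                 rng_seed = rng_seed),
            class = "erp_sim_config")
}

#' @rdname erp_sim_config
#' @export
default_erp_components <- function() {
  data.frame(
    name = c("P3", "lateN1", "P2", "earlyN1"),
    region = c("centroparietal", "parietal", "left frontocentral", "frontal"),
    baseline_amp = c(120, 80, 70, 60),
    peak_gain = c(60, 50, 45, 40),
    peak_width = c(2, 2, 2, 2),
    lag = c(0, 2, 4, 4))
}

#' Simulate per-block ERP component amplitude series
#'
#' @param cohort A `srtt_cohort` with block-resolved behavior.
#' @param config An [erp_sim_config()].
#' @param n_blocks Number of blocks in the series (default from the
#'   cohort layout).
#' @return Data frame with columns `subject_id`, `component`, `block`,
#'   `amplitude` (uV.ms), one row per subject x component x block.
#' @export
simulate_erp <- function(cohort, config = erp_sim_config(),
                         n_blocks = NULL) {
  if (!is.null(config$rng_seed)) set.seed(as.integer(config$rng_seed))
  layout <- attr(cohort, "layout")
  if (is.null(n_blocks)) {
    n_blocks <- if (is.null(layout)) 27L else layout$n_blocks
  }
  rng <- config$block_range[config$block_range <= n_blocks]
  comps <- config$components
  out <- vector("list", length(cohort) * nrow(comps))
  k <- 0L
  for (s in cohort) {
    blat <- block_latency_summary(s$trials)
    lat_of_block <- stats::approxfun(blat$block, blat$mean_latency,
                                     rule = 2)
    for (j in seq_len(nrow(comps))) {
      cm <- comps[j, ]
      if (s$truth_label == "EXP" && !is.na(s$truth_onset_block)) {
        target <- s$truth_onset_block + cm$lag
        u <- stats::runif(1, min(rng), max(rng))
        peak <- round(config$coupling * target + (1 - config$coupling) * u)
      } else {
        peak <- round(stats::runif(1, min(rng), max(rng)))
      }
      peak <- min(max(peak, min(rng)), max(rng))
      blocks <- seq_len(n_blocks)
      amp <- cm$baseline_amp +
        cm$peak_gain * exp(-(blocks - peak)^2 / (2 * cm$peak_width^2))
      if (cm$name == "P3" && config$global_p3_decline != 0) {
        # amplitude tracks per-block mean latency: slower blocks, larger P3
        amp <- amp + config$global_p3_decline *
          (lat_of_block(blocks) - lat_of_block(1))
      }
      amp <- amp + stats::rnorm(n_blocks, 0, config$noise_sd)
      k <- k + 1L
      out[[k]] <- data.frame(subject_id = s$subject_id,
                             component = cm$name,
                             block = blocks,
                             amplitude = amp)
    }
  }
  do.call(rbind, out)
}
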