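#' Individualized latency threshold
#'
#' The threshold against which sequence-repetition performance is compared:
#' `baseline$mean - z_magnitude * baseline$sd`.  `z_magnitude` is stored as
#' a non-negative magnitude and applied subtractively; in z-score space the
#' threshold sits at `-z_magnitude` (reports print the negative z, e.g.
#' -1.85).
#'
#' @param baseline A `baseline_stats` object (or list with `mean`, `sd`).
#' @param z_magnitude Non-negative threshold magnitude in baseline SD units
#'   (default 1.85).
#' @return Threshold latency in ms.
#' @examples
#' b <- structure(list(mean = 453.41, sd = 29.42), class = "baseline_stats")
#' compute_threshold(b, 1.85)  # 398.98 ms
#' @export
compute_threshold <- function(baseline, z_magnitude = 1.85) {
  if (z_magnitude < 0) stop("z_magnitude must be non-negative")
  baseline$mean - z_magnitude * baseline$sd
}

#' Threshold model specification
#'
#' @inheritParams compute_threshold
#' @param rule Qualification rule: `"two_consecutive"` (default; awareness
#'   requires two successive qualifying repetitions) or
#'   `"first_occurrence"`.
#' @return A `threshold_model` list.
#' @export
threshold_model <- function(z_magnitude = 1.85,
                            rule = c("two_consecutive", "first_occurrence")) {
  rule <- match.arg(rule)
  if (z_magnitude < 0) stop("z_magnitude must be non-negative")
  structure(list(z_magnitude = z_magnitude, rule = rule),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("Threshold model: z = -%.2f, rule = %s\n",
              x$z_magnitude, x$rule))
  invisible(x)
}

#' Classify a subject as explicitly aware or not
#'
#' A repetition qualifies when the upper confidence bound of its mean
#' latency drops strictly below the individualized threshold.  Under
#' `"first_occurrence"` the subject is EXP at the first qualifying
#' repetition; under `"two_consecutive"` at the second repetition of the
#' first consecutive qualifying pair.  Subjects that never satisfy the rule
#' are NOEXP, with the block of lowest z-score performance retained as
#' their block of interest for neural correlation.
#'
#' @param summaries A `repetition_summary` (must carry a baseline, or pass
#'   `baseline`).
#' @param model A `threshold_model`.
#' @param baseline Baseline overriding the one attached to `summaries`.
#' @return A `classification_result` list: `label` (`"EXP"`/`"NOEXP"`),
#'   `onset_repetition`, `onset_block`, `block_of_interest`,
#'   `first_of_pair` (first repetition of the qualifying pair, for
#'   transparency), `threshold_latency`, `z_magnitude`, `rule`.
#' @export
classify_subject <- function(summaries, model = threshold_model(),
                             baseline = NULL) {
  if (is.null(baseline)) baseline <- attr(summaries, "baseline")
  if (is.null(baseline)) stop("no baseline attached or supplied")
  if (nrow(summaries) == 0L) stop("empty repetition summaries")
  thr <- compute_threshold(baseline, model$z_magnitude)
  q <- summaries$upper_ci < thr  # strict: ties do not qualify
  q[is.na(q)] <- FALSE
  onset <- NA_integer_
  first_of_pair <- NA_integer_
  if (model$rule == "first_occurrence") {
    if (any(q)) onset <- which(q)[1L]
  } else {
    pair <- which(q[-length(q)] & q[-1L])
    if (length(q) >= 2L && length(pair)) {
      first_of_pair <- pair[1L]
      onset <- pair[1L] + 1L
    }
  }
  if (!is.na(onset)) {
    label <- "EXP"
    onset_rep <- summaries$repetition_index[onset]
    onset_block <- summaries$block[onset]
    boi <- onset_block
  } else {
    label <- "NOEXP"
    onset_rep <- NA_integer_
    onset_block <- NA_integer_
    z <- summaries$z_mean
    if (all(is.na(z))) z <- summaries$mean_latency
    boi <- summaries$block[which.min(z)]
  }
  structure(list(label = label,
                 onset_repetition = onset_rep,
                 onset_block = onset_block,
                 first_of_pair = if (is.na(first_of_pair)) NA_integer_ else
                   summaries$repetition_index[first_of_pair],
                 block_of_interest = boi,
                 threshold_latency = thr,
                 z_magnitude = model$z_magnitude,
                 rule = model$rule),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Classification: %s (z = -%.2f, %s)\n", x$label,
              x$z_magnitude, x$rule))
  if (x$label == "EXP") {
    cat(sprintf("  awareness onset: repetition %d (block %d)\n",
                x$onset_repetition, x$onset_block))
  }
  cat(sprintf("  block of interest: %d\n", x$block_of_interest))
  invisible(x)
}

#' Confusion counts and sensitivity/specificity
#'
#' Scores classifier output against the recall ground truth: a true
#' positive is a subject with full recall classified EXP; a false negative
#' a recalling subject classified NOEXP (flagged for exclusion from neural
#' analyses); and so on.  Sensitivity (true positive rate) is
#' `TP / (TP + FN)`; specificity (true negative rate) `TN / (TN + FP)`.
#' An undefined rate (zero denominator) is reported as `NA`.
#'
#' @param results List of `classification_result` (or character vector of
#'   labels).
#' @param truth_recall Logical vector: does the subject have full sequence
#'   recall?
#' @param subject_ids Optional ids used to name the flagged false
#'   negatives.
#' @return A `confusion_counts` list: `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`, `fn_subjects`.
#' @export
score_cohort <- function(results, truth_recall, subject_ids = NULL) {
  labels <- if (is.character(results)) results else
    vapply(results, `[[`, character(1), "label")
  if (length(labels) != length(truth_recall)) {
    stop("results and truth_recall lengths differ")
  }
  if (anyNA(truth_recall)) stop("missing truth recall label")
  truth_recall <- as.logical(truth_recall)
  pred_exp <- labels == "EXP"
  counts <- confusion_counts(tp = sum(truth_recall & pred_exp),
                             fn = sum(truth_recall & !pred_exp),
                             tn = sum(!truth_recall & !pred_exp),
                             fp = sum(!truth_recall & pred_exp))
  if (is.null(subject_ids)) subject_ids <- seq_along(labels)
  counts$fn_subjects <- subject_ids[truth_recall & !pred_exp]
  counts
}

#' @rdname score_cohort
#' @param tp,fn,tn,fp Confusion counts.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 fn_subjects = integer(0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion: TP %d  FN %d  TN %d  FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Sensitivity/specificity sweep over the z grid
#'
#' Classifies every subject at each z magnitude on an inclusive grid
#' (default 0.50 to 2.50 in steps of 0.01, 201 values) under one or both
#' qualification rules, and scores each against the recall truth.
#'
#' @param summaries_list List of per-subject `repetition_summary` objects
#'   (each with its baseline attached).
#' @param truth_recall Logical recall truth per subject.
#' @param z_min,z_max,step Grid limits and step.
#' @param rules Character vector of rules to sweep.
#' @return Data frame of class `sweep_result` with columns `z`, `rule`,
#'   `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`.
#' @export
sweep_z <- function(summaries_list, truth_recall,
                    z_min = 0.5, z_max = 2.5, step = 0.01,
                    rules = c("first_occurrence", "two_consecutive")) {
  if (step <= 0) stop("step must be positive")
  grid <- z_min + step * seq.int(0L, round((z_max - z_min) / step))
  # Classification at z reduces to comparing z against each subject's
  # critical magnitude: a repetition qualifies iff -z_upper_ci > z, so the
  # subject is EXP iff z < max(-z_upper_ci) (first occurrence) or
  # z < max over consecutive pairs of pmin (two consecutive).
  crit <- vapply(summaries_list, function(s) {
    b <- attr(s, "baseline")
    zu <- if (!all(is.na(s$z_upper_ci))) s$z_upper_ci else
      (s$upper_ci - b$mean) / b$sd
    zu <- zu[!is.na(zu)]
    c(first_occurrence = if (length(zu)) max(-zu) else -Inf,
      two_consecutive = if (length(zu) >= 2L)
        max(pmin(-zu[-length(zu)], -zu[-1L])) else -Inf)
  }, numeric(2))
  out <- do.call(rbind, lapply(rules, function(rule) {
    cc <- t(vapply(grid, function(z) {
      pred_exp <- crit[rule, ] > z  # strict inequality, as in classify_subject
      c(tp = sum(truth_recall & pred_exp),
        fn = sum(truth_recall & !pred_exp),
        tn = sum(!truth_recall & !pred_exp),
        fp = sum(!truth_recall & pred_exp))
    }, numeric(4)))
    data.frame(z = grid, rule = rule, cc)
  }))
  out$sensitivity <- ifelse(out$tp + out$fn > 0,
                            out$tp / (out$tp + out$fn), NA_real_)
  out$specificity <- ifelse(out$tn + out$fp > 0,
                            out$tn / (out$tn + out$fp), NA_real_)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}
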