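#' Clean a trial stream
#'
#' Applies the response-window conventions of the two designs.  In `"exp1"`
#' mode, responses must land in the 750 ms stimulus window: unrecorded
#' trials and recorded responses outside (0, 750] ms are dropped and the
#' removed fraction reported.  In `"exp2"` mode the presentation software
#' records every response, including anticipatory presses with negative
#' latency, so only unrecorded trials are dropped and negative latencies
#' are retained.  Inaccurate responses are retained in the stream in both
#' modes but flagged, so latency summaries can restrict to accurate
#' responses while the stimulus partition stays intact.
#'
#' @param trials Data frame with at least `stim_index`, `latency`,
#'   `recorded`, `correct` (see [read_trials()] for the full column set).
#' @param mode `"exp1"` or `"exp2"`.
#' @param window Response window in ms for exp1 mode, half-open at zero
#'   (default `c(0, 750)`).
#' @return List of class `cleaned_trials`: `trials` (retained rows) and
#'   `report` (counts and the removed fraction).
#' @export
clean_trials <- function(trials, mode = c("exp2", "exp1"),
                         window = c(0, 750)) {
  mode <- match.arg(mode)
  if (is.null(trials) || nrow(trials) == 0L) stop("empty trial stream")
  if (is.unsorted(trials$stim_index)) {
    trials <- trials[order(trials$stim_index), , drop = FALSE]
  }
  recorded <- as.logical(trials$recorded)
  keep <- recorded
  if (mode == "exp1") {
    in_window <- !is.na(trials$latency) &
      trials$latency > window[1] & trials$latency <= window[2]
    keep <- keep & in_window
  }
  report <- list(mode = mode,
                 n_input = nrow(trials),
                 n_retained = sum(keep),
                 n_removed = sum(!keep),
                 removal_fraction = mean(!keep))
  structure(list(trials = trials[keep, , drop = FALSE], report = report),
            class = "cleaned_trials")
}

#' @export
print.cleaned_trials <- function(x, ...) {
  r <- x$report
  cat(sprintf("Cleaned trials (%s): %d of %d retained (%.1f%% removed)\n",
              r$mode, r$n_retained, r$n_input, 100 * r$removal_fraction))
  invisible(x)
}

trials_of <- function(x) {
  if (inherits(x, "cleaned_trials")) x$trials else x
}

#' Per-subject baseline latency statistics
#'
#' The baseline anchors the individualized threshold.  Under the `"exp1"`
#' convention it is the first 45 key presses of the cleaned stream; under
#' `"exp2"` it is the dedicated 35-key random block (block 1), using
#' accurate recorded responses only.  Latency statistics are the sample
#' mean and sample standard deviation.
#'
#' @param trials Cleaned trials (a `cleaned_trials` object or data frame).
#' @param mode `"exp1"` or `"exp2"`.
#' @param accurate_only Restrict to accurate responses (default `TRUE`;
#'   the exp1 convention for which presses count is configurable here).
#' @param min_n Minimum acceptable number of baseline presses in exp2 mode
#'   (default 10; exp1 requires the full 45).
#' @return A `baseline_stats` list: `mean`, `sd`, `n`, `mode`.
#' @export
compute_baseline <- function(trials, mode = c("exp2", "exp1"),
                             accurate_only = TRUE, min_n = 10L) {
  mode <- match.arg(mode)
  tr <- trials_of(trials)
  if (mode == "exp1") {
    if (accurate_only) tr <- tr[as.logical(tr$correct), , drop = FALSE]
    if (nrow(tr) < 45L) {
      stop("insufficient baseline: need 45 key presses, have ", nrow(tr))
    }
    lat <- tr$latency[seq_len(45L)]
  } else {
    base <- tr[!is.na(tr$block) & tr$block == 1L, , drop = FALSE]
    if ("phase" %in% names(base)) {
      base <- base[base$phase == "baseline", , drop = FALSE]
    }
    if (accurate_only) base <- base[as.logical(base$correct), , drop = FALSE]
    if (nrow(base) < min_n) {
      stop("insufficient baseline: need at least ", min_n,
           " accurate recorded baseline presses, have ", nrow(base))
    }
    lat <- base$latency
  }
  structure(list(mean = mean(lat), sd = stats::sd(lat), n = length(lat),
                 mode = mode),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("Baseline (%s): mean %.2f ms, SD %.2f ms, n = %d\n",
              x$mode, x$mean, x$sd, x$n))
  invisible(x)
}

# One-sided 95% Student-t upper bound of the mean; collapses to the mean
# for n <= 1 or zero spread.
upper_conf_bound <- function(mean, sd, n, level = 0.95) {
  out <- mean
  ok <- !is.na(sd) & n > 1L & sd > 0
  out[ok] <- mean[ok] +
    stats::qt(level, n[ok] - 1L) * sd[ok] / sqrt(n[ok])
  out
}

#' Summarize behavior per sequence repetition
#'
#' Partitions the sequence-phase stimulus stream into consecutive groups of
#' `sequence_length` stimuli (one group per pass through the embedded
#' sequence) and summarizes the latency of accurate recorded responses in
#' each: mean, SD, one-sided 95% Student-t upper confidence bound of the
#' mean, and z-scores of the mean and bound against the subject baseline.
#' A repetition in which no response was recorded inherits the previous
#' repetition's mean (flagged via `imputed`), mirroring the handling of
#' response-pad dropouts.
#'
#' @param trials Cleaned trials (`cleaned_trials` or data frame).  If a
#'   `phase` column is present only `"sequence"` rows are summarized;
#'   otherwise all rows are treated as sequence trials and the repetition
#'   index is derived from `stim_index`.
#' @param sequence_length Number of key presses per sequence repetition.
#' @param baseline A `baseline_stats` object (requires `sd > 0`), or `NULL`
#'   to skip the z conversion.
#' @param layout Optional `block_layout` used to map repetitions to blocks;
#'   when absent and the trials carry a `block` column, the modal block of
#'   each repetition is used.
#' @param conf_level One-sided confidence level of the upper bound
#'   (default 0.95).
#' @param z_scores Compute z-score columns (default `TRUE`).  A zero-SD
#'   baseline is a hard error when z-scores are requested; noise-free
#'   fixtures should use `z_scores = FALSE` and classify on the raw
#'   latency scale.
#' @param max_repetitions Optional truncation, e.g. 70 to equate exposure
#'   across sequence-length conditions.
#' @return Data frame of class `repetition_summary` with columns
#'   `repetition_index`, `block`, `mean_latency`, `sd_latency`,
#'   `n_responses`, `upper_ci`, `z_mean`, `z_upper_ci`, `imputed`.
#' @export
summarize_repetitions <- function(trials, sequence_length, baseline = NULL,
                                  layout = NULL, conf_level = 0.95,
                                  max_repetitions = NULL, z_scores = TRUE) {
  tr <- trials_of(trials)
  if (nrow(tr) == 0L) stop("empty trial stream")
  if (z_scores && !is.null(baseline) && baseline$sd <= 0) {
    stop("degenerate baseline: SD is zero, z-scores are undefined")
  }
  if ("phase" %in% names(tr)) {
    tr <- tr[tr$phase == "sequence", , drop = FALSE]
  }
  if ("repetition" %in% names(tr) && !anyNA(tr$repetition)) {
    rep_idx <- tr$repetition
  } else {
    # consecutive groups of sequence_length stimuli, by position in the
    # sequence-phase stream
    offset <- min(tr$stim_index) - 1L
    rep_idx <- (tr$stim_index - offset - 1L) %/% sequence_length + 1L
  }
  n_reps <- max(rep_idx)
  if (!is.null(max_repetitions)) n_reps <- min(n_reps, max_repetitions)
  keep <- rep_idx <= n_reps
  tr <- tr[keep, , drop = FALSE]
  rep_idx <- rep_idx[keep]

  use <- as.logical(tr$correct) & as.logical(tr$recorded)
  f <- factor(rep_idx, levels = seq_len(n_reps))
  lat <- tr$latency
  lat[!use] <- NA_real_
  m <- as.numeric(tapply(lat, f, mean, na.rm = TRUE))
  s <- as.numeric(tapply(lat, f, stats::sd, na.rm = TRUE))
  n <- as.integer(tapply(!is.na(lat), f, sum))
  n[is.na(n)] <- 0L
  m[n == 0L] <- NA_real_
  s[n <= 1L] <- NA_real_

  imputed <- n == 0L
  for (i in which(imputed)) {
    if (i == 1L) stop("first repetition has no recorded responses")
    m[i] <- m[i - 1L]
  }
  ub <- upper_conf_bound(m, s, n, conf_level)

  if (!is.null(layout)) {
    block <- vapply(seq_len(n_reps), map_repetition_to_block,
                    integer(1), layout = layout)
  } else if ("block" %in% names(tr)) {
    block <- as.integer(tapply(tr$block, f, function(b)
      as.integer(names(which.max(table(b))))))
  } else {
    block <- NA_integer_
  }

  out <- data.frame(repetition_index = seq_len(n_reps),
                    block = block,
                    mean_latency = m,
                    sd_latency = s,
                    n_responses = n,
                    upper_ci = ub,
                    imputed = imputed)
  if (z_scores && !is.null(baseline)) {
    out$z_mean <- (out$mean_latency - baseline$mean) / baseline$sd
    out$z_upper_ci <- (out$upper_ci - baseline$mean) / baseline$sd
  } else {
    out$z_mean <- NA_real_
    out$z_upper_ci <- NA_real_
  }
  class(out) <- c("repetition_summary", "data.frame")
  attr(out, "baseline") <- baseline
  out
}

#' Map a sequence repetition to its block
#'
#' Under the exp2 layout, block 1 is the random baseline and repetitions
#' run five per block from block 2, so repetition r maps to block
#' `1 + ceiling(r / 5)`.  Under exp1 the sequence starts at block 1 and
#' repetition r maps to `ceiling(r / repetitions_per_block)`.
#'
#' @param repetition_index 1-based repetition index.
#' @param layout A `block_layout`.
#' @return Integer block index.
#' @export
map_repetition_to_block <- function(repetition_index, layout) {
  r <- as.integer(repetition_index)
  if (any(r < 1L) || any(r > layout$n_repetitions)) {
    stop("repetition index out of range 1..", layout$n_repetitions)
  }
  if (layout$design == "exp2") {
    1L + as.integer(ceiling(r / layout$repetitions_per_block))
  } else {
    as.integer(ceiling(r / layout$repetitions_per_block))
  }
}

#' Per-block mean latency of accurate recorded responses
#'
#' Descriptive per-block behavior, used for the P3-amplitude association.
#'
#' @inheritParams summarize_repetitions
#' @return Data frame with `block`, `mean_latency`, `n_responses`.
#' @export
block_latency_summary <- function(trials) {
  tr <- trials_of(trials)
  use <- as.logical(tr$correct) & as.logical(tr$recorded)
  tr <- tr[use, , drop = FALSE]
  blocks <- sort(unique(tr$block))
  f <- factor(tr$block, levels = blocks)
  data.frame(block = blocks,
             mean_latency = as.numeric(tapply(tr$latency, f, mean)),
             n_responses = as.integer(tapply(tr$latency, f, length)))
}

#' Read / write trial streams
#'
#' Trial CSVs use the columns `subject_id`, `block`, `stim_index`,
#' `target_key`, `response_key`, `latency_ms`, `recorded`, `correct` (and
#' optionally `phase`, `repetition`).  Internally `latency_ms` is exposed
#' as `latency`.
#'
#' @param path CSV file path.
#' @return `read_trials()`: a data frame of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trials file not found: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("latency_ms" %in% names(tr) && !"latency" %in% names(tr)) {
    names(tr)[names(tr) == "latency_ms"] <- "latency"
  }
  tr$recorded <- as.logical(tr$recorded)
  tr$correct <- as.logical(tr$correct)
  tr
}

#' @rdname read_trials
#' @param trials Data frame of trials.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  if ("latency" %in% names(out)) {
    names(out)[names(out) == "latency"] <- "latency_ms"
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
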