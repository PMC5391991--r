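# Independent brute-force oracles, deliberately implemented differently
# from the package code paths they check.

# Loop-based cyclic constraint check: adjacency + three-finger monotone
# runs, one window at a time.
oracle_valid_sequence <- function(x, n_keys = 4L) {
  n <- length(x)
  if (any(x < 1L | x > n_keys)) return(FALSE)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (x[i] == x[j]) return(FALSE)
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    k <- if (j == n) 1L else j + 1L
    d1 <- x[j] - x[i]
    d2 <- x[k] - x[j]
    if ((d1 == 1L && d2 == 1L) || (d1 == -1L && d2 == -1L)) return(FALSE)
  }
  TRUE
}

# all key-index tuples of a given length (columns of expand.grid)
all_candidate_sequences <- function(length, n_keys = 4L) {
  as.matrix(expand.grid(rep(list(seq_len(n_keys)), length)))
}

# Brute-force scan classifier over a logical qualification vector.
oracle_onset <- function(qualifies, rule) {
  n <- length(qualifies)
  if (rule == "first_occurrence") {
    for (i in seq_len(n)) if (qualifies[i]) return(i)
  } else {
    for (i in seq_len(n - 1L)) {
      if (qualifies[i] && qualifies[i + 1L]) return(i + 1L)
    }
  }
  NA_integer_
}

# Insertion-based permutation enumeration (different algorithm from the
# package's prefix recursion).
oracle_permutations <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (m in 2L:n) {
    out <- do.call(rbind, lapply(seq_len(m), function(pos) {
      cbind(out[, seq_len(pos - 1L), drop = FALSE], m,
            out[, seq(pos, m - 1L)[seq_len(m - pos)], drop = FALSE])
    }))
  }
  out
}

# Spearman rho from the explicit sum formula on mid-ranks.
oracle_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sided permutation p for Spearman rho.
oracle_spearman_p <- function(x, y) {
  obs <- abs(oracle_rho(x, y))
  perms <- oracle_permutations(length(x))
  hits <- 0L
  for (i in seq_len(nrow(perms))) {
    if (abs(oracle_rho(x, y[perms[i, ]])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / nrow(perms)
}

# Repetition summaries built directly from a vector of per-repetition
# latency sets (list of numeric vectors), for constructing classifier
# inputs without the prep pipeline.
make_summaries <- function(upper_ci, z_mean = NULL, blocks = NULL,
                           baseline = list(mean = 450, sd = 30)) {
  n <- length(upper_ci)
  if (is.null(blocks)) blocks <- seq_len(n)
  if (is.null(z_mean)) z_mean <- (upper_ci - baseline$mean) / baseline$sd
  out <- data.frame(repetition_index = seq_len(n), block = blocks,
                    mean_latency = upper_ci, sd_latency = 0,
                    n_responses = 7L, upper_ci = upper_ci,
                    imputed = FALSE, z_mean = z_mean,
                    z_upper_ci = (upper_ci - baseline$mean) / baseline$sd)
  class(out) <- c("repetition_summary", "data.frame")
  attr(out, "baseline") <- structure(baseline, class = "baseline_stats")
  out
}

# Minimal trial table for prep tests.
make_trials <- function(latency, block = 1L, correct = TRUE,
                        recorded = TRUE, phase = "sequence",
                        subject_id = "S01") {
  n <- length(latency)
  data.frame(subject_id = subject_id,
             block = rep_len(block, n),
             stim_index = seq_len(n),
             target_key = rep_len(1:4, n),
             response_key = rep_len(1:4, n),
             latency = latency,
             phase = rep_len(phase, n),
             recorded = rep_len(recorded, n),
             correct = rep_len(correct, n))
}

default_layout <- function(seed = 1) {
  build_block_layout("exp2", c(3, 4, 2, 1, 3, 2, 4), rng_seed = seed)
}
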