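#' Validate an SRTT stimulus sequence
#'
#' Checks the constraints used when building pseudorandom SRTT sequences:
#' no two adjacent elements may be equal, and no three-element window may
#' run across three adjacent fingers in strictly ascending or descending
#' order (e.g. 2-3-4 or 4-3-2).  Because the sequence is presented tiled
#' seamlessly (ISI 0, no inter-sequence marker), both constraints are by
#' default enforced cyclically, i.e. including the windows that wrap from
#' the last element back to the first.
#'
#' @param elements Integer vector of key indices in `1:n_keys`.
#' @param n_keys Number of response keys (default 4).
#' @param cyclic Enforce the constraints across the wrap-around as well
#'   (default `TRUE`).
#' @param monotone_run Forbidden run rule: `"monotone"` (default) forbids
#'   three-element windows whose indices are strictly monotone with step
#'   +/-1; `"any_adjacent"` is the stricter reading forbidding any window
#'   that is a permutation of three adjacent fingers.
#' @return A logical scalar; when invalid, attribute `"reason"` names the
#'   first violated rule.
#' @seealso [generate_sequence()]
#' @export
validate_sequence <- function(elements, n_keys = 4L, cyclic = TRUE,
                              monotone_run = c("monotone", "any_adjacent")) {
  monotone_run <- match.arg(monotone_run)
  x <- as.integer(elements)
  n <- length(x)
  if (n < 3L) stop("sequence must have at least 3 elements")
  if (anyNA(x) || any(x < 1L | x > n_keys)) {
    return(structure(FALSE, reason = "element out of key range"))
  }
  nxt <- if (cyclic) c(x[-1L], x[1L]) else x[-1L]
  cur <- if (cyclic) x else x[-n]
  if (any(cur == nxt)) {
    return(structure(FALSE, reason = "adjacent repeat"))
  }
  # three-element windows; wrap windows included when cyclic
  idx <- if (cyclic) seq_len(n) else seq_len(n - 2L)
  a <- x[idx]
  b <- x[(idx) %% n + 1L]
  c <- x[(idx + 1L) %% n + 1L]
  if (!cyclic) {
    a <- x[seq_len(n - 2L)]; b <- x[2:(n - 1L)]; c <- x[3:n]
  }
  bad <- switch(monotone_run,
    monotone = (b - a == 1L & c - b == 1L) | (b - a == -1L & c - b == -1L),
    any_adjacent = {
      lo <- pmin(a, b, c)
      hi <- pmax(a, b, c)
      hi - lo == 2L & (a != b & b != c & a != c)
    })
  if (any(bad)) {
    return(structure(FALSE, reason = "three-finger run"))
  }
  TRUE
}

#' Generate a pseudorandom SRTT sequence
#'
#' Rejection sampling over uniform candidate sequences until one satisfies
#' [validate_sequence()].  Valid sequences are dense at the task's usual
#' lengths (7, 10, 13 on 4 keys) so rejection converges quickly; generation
#' fails explicitly when the cap is reached, signalling infeasible
#' parameters.
#'
#' @inheritParams validate_sequence
#' @param length Sequence length (>= 3).
#' @param rng_seed Optional integer seed; when supplied the same seed always
#'   yields the same sequence.
#' @param max_attempts Rejection cap (default 10000).
#' @return An integer vector of class `srtt_sequence` with attribute
#'   `n_keys`.
#' @examples
#' generate_sequence(7, rng_seed = 1)
#' @export
generate_sequence <- function(length, n_keys = 4L, rng_seed = NULL,
                              cyclic = TRUE,
                              monotone_run = "monotone",
                              max_attempts = 10000L) {
  if (length < 3L) stop("length must be >= 3")
  if (n_keys < 3L) stop("n_keys must be >= 3")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  for (i in seq_len(max_attempts)) {
    cand <- sample.int(n_keys, length, replace = TRUE)
    if (isTRUE(validate_sequence(cand, n_keys, cyclic, monotone_run))) {
      return(structure(cand, n_keys = as.integer(n_keys),
                       class = "srtt_sequence"))
    }
  }
  stop("no valid sequence found after ", max_attempts,
       " attempts; parameters are likely infeasible")
}

#' @export
print.srtt_sequence <- function(x, ...) {
  cat("SRTT sequence (", length(x), " elements, ",
      attr(x, "n_keys"), " keys): ", paste(unclass(x), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' Generate a random baseline key stream
#'
#' Non-repeating (no two equal adjacent keys) random stream used as the
#' random-baseline block of the EEG design.  Linear, not cyclic: the stream
#' is presented once.
#'
#' @param n Number of keys (default 35).
#' @param n_keys Number of response keys.
#' @return Integer vector of length `n`.
#' @export
random_baseline_keys <- function(n = 35L, n_keys = 4L) {
  out <- integer(n)
  out[1L] <- sample.int(n_keys, 1L)
  for (i in seq_len(n - 1L) + 1L) {
    out[i] <- sample(setdiff(seq_len(n_keys), out[i - 1L]), 1L)
  }
  out
}

#' Assemble a block layout and full stimulus stream
#'
#' Two designs are supported.  `"exp1"`: 5 blocks of seamlessly tiled
#' sequence, with the per-block stimulus count chosen as the largest
#' multiple of the sequence length not exceeding 182 (182 stimuli for 7- and
#' 13-element sequences, 180 for 10-element), and the subject's baseline
#' taken as the first 45 key presses.  `"exp2"`: one random-baseline block
#' of 35 keys followed by 26 blocks of 5 sequence repetitions each (7-element
#' sequence; 945 stimuli in total, 130 sequence repetitions).
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param sequence Integer sequence from [generate_sequence()] (or any
#'   vector passing [validate_sequence()]).
#' @param rng_seed Optional seed for the random baseline keys (exp2).
#' @return A `block_layout` list with fields `design`, `sequence`,
#'   `stimuli_per_block`, `n_blocks`, `repetitions_per_block`,
#'   `baseline_keys`, `sequence_length`, `n_repetitions`, and `stream`, a
#'   data frame with columns `stim_index`, `block`, `phase`
#'   (`"baseline"`/`"sequence"`), `repetition` (NA in the exp2 baseline
#'   block) and `target_key`.
#' @examples
#' lay <- build_block_layout("exp2", c(3, 4, 2, 1, 3, 2, 4), rng_seed = 1)
#' nrow(lay$stream)  # 945
#' @export
build_block_layout <- function(design = c("exp2", "exp1"), sequence,
                               rng_seed = NULL) {
  design <- match.arg(design)
  seq_len_ <- length(sequence)
  ok <- validate_sequence(sequence, n_keys = max(4L, max(sequence)))
  if (!isTRUE(ok)) {
    stop("invalid sequence: ", attr(ok, "reason"))
  }
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  if (design == "exp1") {
    per_block <- (182L %/% seq_len_) * seq_len_
    if (per_block < seq_len_) stop("sequence too long for exp1 blocks")
    n_blocks <- 5L
    reps_per_block <- per_block %/% seq_len_
    n_reps <- reps_per_block * n_blocks
    keys <- rep_len(sequence, per_block * n_blocks)
    stream <- data.frame(
      stim_index = seq_along(keys),
      block = rep(seq_len(n_blocks), each = per_block),
      phase = "sequence",
      repetition = (seq_along(keys) - 1L) %/% seq_len_ + 1L,
      target_key = as.integer(keys))
    baseline_keys <- 45L
  } else {
    reps_per_block <- 5L
    n_seq_blocks <- 26L
    per_block <- reps_per_block * seq_len_
    base <- random_baseline_keys(35L, n_keys = 4L)
    keys <- c(base, rep_len(sequence, per_block * n_seq_blocks))
    n_reps <- reps_per_block * n_seq_blocks
    n_blocks <- n_seq_blocks + 1L
    seq_pos <- seq_len(per_block * n_seq_blocks)
    stream <- data.frame(
      stim_index = seq_along(keys),
      block = c(rep(1L, 35L), 2L + (seq_pos - 1L) %/% per_block),
      phase = c(rep("baseline", 35L), rep("sequence", length(seq_pos))),
      repetition = c(rep(NA_integer_, 35L), (seq_pos - 1L) %/% seq_len_ + 1L),
      target_key = as.integer(keys))
    baseline_keys <- 35L
  }
  structure(list(design = design,
                 sequence = as.integer(sequence),
                 sequence_length = seq_len_,
                 stimuli_per_block = per_block,
                 n_blocks = n_blocks,
                 repetitions_per_block = reps_per_block,
                 n_repetitions = n_reps,
                 baseline_keys = baseline_keys,
                 stream = stream),
            class = "block_layout")
}

#' @export
print.block_layout <- function(x, ...) {
  cat("SRTT block layout (", x$design, ")\n", sep = "")
  cat("  sequence:", paste(x$sequence, collapse = "-"), "\n")
  cat("  blocks:", x$n_blocks, " stimuli/block:", x$stimuli_per_block,
      " total stimuli:", nrow(x$stream), "\n")
  cat("  sequence repetitions:", x$n_repetitions, "\n")
  invisible(x)
}
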