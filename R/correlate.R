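#' Spearman rank correlation with exact small-sample p-values
#'
#' Spearman's rho on mid-ranks (average ranks for ties).  For small samples
#' (`n <= exact_cutoff`, default 8) the two-sided p-value is computed by
#' exact enumeration of all n! permutations of one margin — the
#' t-approximation is poor at the group sizes typical of awareness cohorts
#' (~9 subjects).  Larger samples use the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 (typically block
#'   indices).
#' @param exact_cutoff Largest n for which the permutation-exact p is used.
#' @return List with `rho`, `p_value`, `n`, `method`
#'   (`"exact"`/`"t-approximation"`).
#' @examples
#' spearman_cor(1:9, 9:1)  # rho -1
#' @export
spearman_cor <- function(x, y, exact_cutoff = 8L) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("undefined correlation: constant input")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_cutoff) {
    perms <- permutations_of(n)
    # distribution of rho over all re-pairings of the y ranks; rho equals
    # the Pearson correlation of the (standardized) mid-ranks
    rx_s <- (rx - mean(rx)) / stats::sd(rx)
    ry_s <- (ry - mean(ry)) / stats::sd(ry)
    rhos <- as.numeric(matrix(ry_s[perms], nrow(perms)) %*% rx_s) / (n - 1)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# all permutations of 1..n as an n! x n matrix (n <= 9 intended),
# memoized because the exact test is called repeatedly in sweeps
.perm_cache <- new.env(parent = emptyenv())
permutations_of <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- permutations_of(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, sub + (sub >= k))
    }))
  }
  .perm_cache[[key]] <- out
  out
}

#' Neurobehavioral correlation per component and awareness group
#'
#' Correlates the behavioral block of interest (awareness-onset block for
#' EXP, block of lowest z for NOEXP) with the block of peak component
#' amplitude, per group and component, with Holm adjustment across the
#' component family within each group.  False-negative subjects (full
#' recall but classified NOEXP) are excluded from both groups.
#'
#' @param classifications Named list of `classification_result` per
#'   subject (names = subject ids), or a data frame with `subject_id`,
#'   `label`, `block_of_interest`.
#' @param peaks Data frame from [peak_block_table()] (`subject_id`,
#'   `component`, `peak_block`).
#' @param truth_recall Optional named logical vector of recall truth used
#'   to identify false negatives for exclusion.
#' @param exact_cutoff Passed to [spearman_cor()].
#' @return Data frame with `group`, `component`, `rho`, `p_value`,
#'   `p_holm`, `n`, `method`; attribute `"excluded"` lists FN subject ids.
#' @export
neurobehavioral_correlation <- function(classifications, peaks,
                                        truth_recall = NULL,
                                        exact_cutoff = 8L) {
  beh <- classification_table(classifications)
  excluded <- character(0)
  if (!is.null(truth_recall)) {
    fn <- beh$subject_id[beh$label == "NOEXP" &
                           truth_recall[beh$subject_id]]
    excluded <- fn[!is.na(fn)]
    beh <- beh[!beh$subject_id %in% excluded, , drop = FALSE]
  }
  merged <- merge(beh, peaks, by = "subject_id")
  out <- list()
  for (grp in c("EXP", "NOEXP")) {
    g <- merged[merged$label == grp, , drop = FALSE]
    comps <- unique(g$component)
    if (length(comps) == 0L) next
    if (length(unique(g$subject_id)) < 3L) {
      stop("group ", grp, " has fewer than 3 subjects")
    }
    rows <- do.call(rbind, lapply(comps, function(cm) {
      d <- g[g$component == cm, , drop = FALSE]
      sc <- spearman_cor(d$block_of_interest, d$peak_block, exact_cutoff)
      data.frame(group = grp, component = cm, rho = sc$rho,
                 p_value = sc$p_value, n = sc$n, method = sc$method)
    }))
    rows$p_holm <- stats::p.adjust(rows$p_value, method = "holm")
    out[[grp]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

# normalize classification input to a data frame
classification_table <- function(classifications) {
  if (is.data.frame(classifications)) return(classifications)
  ids <- names(classifications)
  if (is.null(ids)) ids <- as.character(seq_along(classifications))
  data.frame(
    subject_id = ids,
    label = vapply(classifications, `[[`, character(1), "label"),
    block_of_interest = vapply(classifications, function(x)
      as.integer(x$block_of_interest), integer(1)),
    onset_block = vapply(classifications, function(x)
      as.integer(x$onset_block), integer(1)))
}

#' Per-subject P3 amplitude vs response latency association
#'
#' Descriptive per-subject least-squares association between per-block P3
#' amplitude and per-block mean response latency, summarized by awareness
#' group.  This is a deliberately simplified stand-in for a mixed-model
#' analysis: each subject contributes an independent slope, intercept and
#' Pearson r, and groups are compared descriptively.
#'
#' @param p3 Data frame with `subject_id`, `block`, `amplitude` (P3 rows
#'   only).
#' @param latency Data frame with `subject_id`, `block`, `mean_latency`.
#' @param labels Named character vector of awareness labels per subject.
#' @param min_blocks Minimum blocks required per subject (default 5;
#'   subjects below it are skipped with a warning).
#' @return List with `per_subject` (data frame: `subject_id`, `label`,
#'   `slope`, `intercept`, `r`, `n_blocks`) and `by_group` (means and SDs
#'   per label).
#' @export
p3_latency_association <- function(p3, latency, labels,
                                   min_blocks = 5L) {
  ids <- unique(p3$subject_id)
  rows <- lapply(ids, function(id) {
    d <- merge(p3[p3$subject_id == id, c("block", "amplitude")],
               latency[latency$subject_id == id,
                       c("block", "mean_latency")],
               by = "block")
    if (nrow(d) < min_blocks) {
      warning("subject ", id, " has fewer than ", min_blocks,
              " blocks; skipped")
      return(NULL)
    }
    fit <- stats::lm(amplitude ~ mean_latency, data = d)
    r <- if (stats::sd(d$amplitude) == 0 || stats::sd(d$mean_latency) == 0)
      NA_real_ else stats::cor(d$amplitude, d$mean_latency)
    data.frame(subject_id = id, label = unname(labels[id]),
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r = r, n_blocks = nrow(d))
  })
  per_subject <- do.call(rbind, rows)
  if (is.null(per_subject)) {
    return(list(per_subject = NULL, by_group = NULL))
  }
  by_group <- do.call(rbind, lapply(split(per_subject, per_subject$label),
                                    function(g) {
    data.frame(label = g$label[1L], n = nrow(g),
               mean_slope = mean(g$slope, na.rm = TRUE),
               sd_slope = stats::sd(g$slope),
               mean_intercept = mean(g$intercept, na.rm = TRUE),
               sd_intercept = stats::sd(g$intercept),
               mean_r = mean(g$r, na.rm = TRUE))
  }))
  rownames(by_group) <- NULL
  list(per_subject = per_subject, by_group = by_group)
}

#' Peak-timing order of ERP components
#'
#' Orders each subject's components by peak block (canonical tie-break:
#' P3, lateN1, P2, earlyN1 — the progression expected during awareness
#' development) and summarizes group-level mean peak blocks and pairwise
#' block differences.
#'
#' @param peaks Data frame from [peak_block_table()].
#' @param labels Named character vector of awareness labels per subject.
#' @param components Components to include, in canonical order (default
#'   `c("P3", "lateN1", "P2", "earlyN1")`).
#' @return List with `per_subject` (ordered component sequences),
#'   `group_means` (mean peak block per group and component) and
#'   `pairwise` (mean block differences between component pairs per
#'   group).
#' @export
peak_order_summary <- function(peaks, labels,
                               components = c("P3", "lateN1", "P2",
                                              "earlyN1")) {
  missing <- setdiff(components, unique(peaks$component))
  if (length(missing)) {
    stop("missing component series: ", paste(missing, collapse = ", "))
  }
  peaks <- peaks[peaks$component %in% components, , drop = FALSE]
  per_subject <- lapply(split(peaks, peaks$subject_id), function(d) {
    ord <- order(d$peak_block, match(d$component, components))
    data.frame(subject_id = d$subject_id[1L],
               order = paste(d$component[ord], collapse = " -> "),
               stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, per_subject)
  rownames(per_subject) <- NULL
  peaks$label <- labels[peaks$subject_id]
  agg <- stats::aggregate(peak_block ~ label + component, data = peaks,
                          FUN = mean)
  agg$component <- factor(agg$component, levels = components)
  agg <- agg[order(agg$label, agg$component), ]
  rownames(agg) <- NULL
  pairs <- utils::combn(components, 2L)
  pairwise <- do.call(rbind, lapply(unique(peaks$label), function(lb) {
    g <- agg[agg$label == lb, ]
    data.frame(label = lb,
               pair = paste(pairs[2L, ], "-", pairs[1L, ]),
               mean_diff = vapply(seq_len(ncol(pairs)), function(k) {
                 g$peak_block[g$component == pairs[2L, k]] -
                   g$peak_block[g$component == pairs[1L, k]]
               }, numeric(1)))
  }))
  rownames(pairwise) <- NULL
  list(per_subject = per_subject, group_means = agg, pairwise = pairwise)
}
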