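#' ERP component windows and electrode groups
#'
#' Default component definitions: early N1 100-140 ms over frontal
#' electrodes (F1, FZ, F2), late N1 140-170 ms over parietal electrodes
#' (P1, P3, P2, P4), P2 180-210 ms over left frontocentral electrodes
#' (C1A, CZA, C1, CZ) and P3 275-375 ms over centroparietal electrodes
#' (C1, CZ, C2, C1P, CPZ, C2P).  N1 components are negative-going, P2/P3
#' positive-going.
#'
#' @return Named list of `component_window` lists with fields `name`,
#'   `t_start`, `t_end` (ms post-stimulus), `electrode_group`, `polarity`.
#' @export
component_windows <- function() {
  w <- function(name, t_start, t_end, electrodes, polarity) {
    structure(list(name = name, t_start = t_start, t_end = t_end,
                   electrode_group = electrodes, polarity = polarity),
              class = "component_window")
  }
  list(
    earlyN1 = w("earlyN1", 100, 140, c("F1", "FZ", "F2"), "negative"),
    lateN1 = w("lateN1", 140, 170, c("P1", "P3", "P2", "P4"), "negative"),
    P2 = w("P2", 180, 210, c("C1A", "CZA", "C1", "CZ"), "positive"),
    P3 = w("P3", 275, 375, c("C1", "CZ", "C2", "C1P", "CPZ", "C2P"),
           "positive"))
}

#' Construct an epoched ERP average
#'
#' Container for one per-block stimulus-locked average: a uniform time
#' axis (ms, canonically -100 to 500 at 1 kHz) and an amplitude matrix
#' (time x channel, uV).  Baseline correction subtracts each channel's
#' mean over the pre-stimulus window.
#'
#' @param time Numeric time axis in ms, strictly increasing, uniform.
#' @param amplitudes Matrix `length(time)` x channels, or a named list of
#'   per-channel numeric vectors.
#' @param channels Channel labels (defaults to matrix column names).
#' @param baseline_window Pre-stimulus window for correction (default
#'   `c(-100, 0)`); `NULL` skips correction.
#' @return An `erp_epoch` list: `time`, `amplitudes` (matrix with channel
#'   column names), `baseline_corrected`.
#' @export
erp_epoch <- function(time, amplitudes, channels = NULL,
                      baseline_window = c(-100, 0)) {
  if (is.list(amplitudes) && !is.matrix(amplitudes)) {
    channels <- names(amplitudes)
    amplitudes <- do.call(cbind, amplitudes)
  }
  amplitudes <- as.matrix(amplitudes)
  if (!is.null(channels)) colnames(amplitudes) <- channels
  if (is.null(colnames(amplitudes))) {
    stop("channel labels are required")
  }
  if (nrow(amplitudes) != length(time)) {
    stop("time axis and amplitude rows differ")
  }
  if (length(time) >= 2L) {
    dt <- diff(time)
    if (any(abs(dt - dt[1]) > 1e-6)) stop("time axis must be uniform")
    if (dt[1] <= 0) stop("time axis must be increasing")
  }
  corrected <- FALSE
  if (!is.null(baseline_window)) {
    sel <- time >= baseline_window[1] & time <= baseline_window[2]
    if (any(sel)) {
      amplitudes <- sweep(amplitudes, 2L, colMeans(amplitudes[sel, ,
                                                              drop = FALSE]))
      corrected <- TRUE
    }
  }
  structure(list(time = time, amplitudes = amplitudes,
                 baseline_corrected = corrected),
            class = "erp_epoch")
}

#' Signed-area amplitude of an ERP component
#'
#' Averages the window's electrode group sample-wise, then integrates the
#' waveform over `[t_start, t_end]` keeping only the portion whose sign
#' matches the component polarity (`method = "rectified"`, the default:
#' opposite-sign samples contribute zero) or the net integral
#' (`method = "net"`).  Trapezoidal integration on the uniform grid; the
#' magnitude is returned as a positive number in uV.ms with the polarity
#' recorded in an attribute.
#'
#' @param epoch An [erp_epoch()] (must be baseline corrected).
#' @param window A `component_window` (see [component_windows()]).
#' @param method `"rectified"` (default) or `"net"`.
#' @return Amplitude in uV.ms with attribute `polarity`.  `"rectified"` is
#'   always non-negative; `"net"` is the polarity-aligned net integral and
#'   may be negative when the opposite-sign portion dominates.
#' @export
signed_area_amplitude <- function(epoch, window,
                                  method = c("rectified", "net")) {
  method <- match.arg(method)
  if (!inherits(epoch, "erp_epoch")) stop("epoch must be an erp_epoch")
  if (!isTRUE(epoch$baseline_corrected)) {
    stop("epoch must be baseline corrected")
  }
  missing <- setdiff(window$electrode_group, colnames(epoch$amplitudes))
  if (length(missing)) {
    stop("missing channels: ", paste(missing, collapse = ", "))
  }
  sel <- epoch$time >= window$t_start & epoch$time <= window$t_end
  if (!any(sel)) stop("window outside epoch time axis")
  t <- epoch$time[sel]
  y <- rowMeans(epoch$amplitudes[sel, window$electrode_group, drop = FALSE])
  sign_fac <- if (window$polarity == "negative") -1 else 1
  y <- y * sign_fac  # polarity-aligned: component deflection is positive
  if (method == "rectified") y <- pmax(y, 0)
  area <- trapz_area(t, y)
  structure(area, polarity = window$polarity)
}

# trapezoid rule on a (possibly length-1) grid
trapz_area <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

#' Section a per-block series into block groups
#'
#' Collapses a per-block amplitude (or any) series into consecutive
#' sections, e.g. 27 blocks into 9 sections of 3 blocks each; section k is
#' the mean of blocks `3k-2 .. 3k`.
#'
#' @param x Numeric per-block values, in block order.
#' @param section_size Blocks per section (default 3).
#' @return Numeric vector of section means.
#' @export
section_blocks <- function(x, section_size = 3L) {
  n <- length(x)
  if (n %% section_size != 0L) {
    stop("block count ", n, " not divisible by section size ", section_size)
  }
  as.numeric(colMeans(matrix(x, nrow = section_size)))
}

#' Peak-amplitude block of a component series
#'
#' The block at which a component's amplitude series is maximal, restricted
#' to an analysis range (default blocks 3-27, excluding the initial
#' pacing-adaptation peak).  Ties resolve to the earliest block.
#'
#' @param amplitude Numeric amplitudes, one per block.
#' @param blocks Block indices matching `amplitude` (default
#'   `seq_along(amplitude)`).
#' @param analysis_range Blocks eligible for the peak (default `3:27`).
#' @return Integer peak block.
#' @export
find_peak_block <- function(amplitude, blocks = seq_along(amplitude),
                            analysis_range = 3:27) {
  keep <- blocks %in% analysis_range
  if (!any(keep)) stop("analysis range is empty within the series")
  b <- blocks[keep]
  a <- amplitude[keep]
  ord <- order(b)  # earliest-block tie-break regardless of input order
  b <- b[ord]; a <- a[ord]
  b[which.max(a)]
}

#' Per-block component amplitude series with peak identification
#'
#' Wraps a long-format amplitude table (as produced by [simulate_erp()] or
#' read from CSV) into per-subject, per-component series and annotates the
#' peak block.
#'
#' @param amplitudes Data frame with `subject_id`, `component`, `block`,
#'   `amplitude`.
#' @param analysis_range Blocks eligible for the peak (default `3:27`).
#' @return Data frame with one row per subject x component: `subject_id`,
#'   `component`, `peak_block`, `peak_amplitude`.
#' @export
peak_block_table <- function(amplitudes, analysis_range = 3:27) {
  sp <- split(amplitudes,
              list(amplitudes$subject_id, amplitudes$component),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    pk <- find_peak_block(d$amplitude, d$block, analysis_range)
    data.frame(subject_id = d$subject_id[1L],
               component = d$component[1L],
               peak_block = pk,
               peak_amplitude = d$amplitude[d$block == pk][1L])
  }))
  rownames(out) <- NULL
  out
}

#' Expand a per-block amplitude series into synthetic epoch averages
#'
#' Integration helper: builds, for each block, a baseline-corrected epoch
#' whose component window contains a half-sine deflection of the
#' component's polarity with rectified area equal to the series value, on
#' the window's electrode group (zeros elsewhere).  Useful for exercising
#' the signed-area path end-to-end against known areas.
#'
#' @param series Data frame with `block`, `amplitude` for one subject and
#'   component.
#' @param window A `component_window`.
#' @param time Time axis (default -100:500 ms at 1 kHz).
#' @return Named list of [erp_epoch()] objects, one per block.
#' @export
series_to_epochs <- function(series, window, time = seq(-100, 500)) {
  chans <- window$electrode_group
  sign_fac <- if (window$polarity == "negative") -1 else 1
  lapply(stats::setNames(seq_len(nrow(series)), series$block), function(i) {
    amp <- matrix(0, length(time), length(chans),
                  dimnames = list(NULL, chans))
    sel <- time >= window$t_start & time < window$t_end
    tt <- time[sel]
    dur <- window$t_end - window$t_start
    # half sine of area A over [t_start, t_end): peak = A * pi / (2 * dur)
    peak <- series$amplitude[i] * pi / (2 * dur)
    amp[sel, ] <- sign_fac * peak *
      sin(pi * (tt - window$t_start) / dur)
    ep <- erp_epoch(time, amp, baseline_window = NULL)
    ep$baseline_corrected <- TRUE  # zero baseline by construction
    ep
  })
}
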