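#' Neuropil correction
#'
#' Subtracts the scaled neuropil signal from each cell's raw fluorescence:
#' `corrected = F - coefficient * Fneu`.
#'
#' @param f cells x frames raw fluorescence matrix (or a single trace)
#' @param fneu matching neuropil matrix
#' @param coefficient neuropil contamination coefficient (default 0.7)
#' @return corrected matrix with a provenance tag
#' @export
neuropil_correct <- function(f, fneu, coefficient = 0.7) {
  if (!all(dim(as.matrix(f)) == dim(as.matrix(fneu))))
    stop("F and Fneu shapes differ", call. = FALSE)
  if (has_step(f, "conditioned"))
    stop("neuropil correction must precede trace conditioning", call. = FALSE)
  out <- f - coefficient * fneu
  add_provenance(out, "neuropil_corrected")
}

# Causal IIR filtering of the columns of a matrix (zero initial state),
# direct-form `y = filter(b, a, x)` with a[1] = 1.
filter_cols <- function(b, a, x) {
  nb <- length(b)
  if (nb > 1) {
    padded <- rbind(matrix(0, nb - 1, ncol(x)), x)
    v <- stats::filter(padded, b, method = "convolution", sides = 1)
    v <- v[nb:nrow(padded), , drop = FALSE]
  } else {
    v <- b * x
  }
  if (length(a) > 1) {
    v <- stats::filter(v, -a[-1], method = "recursive")
  }
  matrix(as.numeric(v), nrow(x), ncol(x))
}

# Zero-phase (forward-backward) filtering of every row of m. Each row is
# extended at both ends by odd reflection about its endpoints before the
# forward and backward passes, so steady-state signals (e.g. a constant)
# pass through without edge transients.
filtfilt_rows <- function(bf, m) {
  b <- bf$b
  a <- bf$a
  n <- ncol(m)
  npad <- min(3 * max(length(a), length(b)), n - 1)
  # remove each row's mean first: the DC component passes a unit-gain
  # low-pass exactly, and the zero-state transient acts only on the
  # mean-free residual
  mu <- rowMeans(m)
  m <- m - mu
  x <- t(m)
  head_ref <- 2 * rep(x[1, ], each = npad) -
    x[(npad + 1):2, , drop = FALSE]
  tail_ref <- 2 * rep(x[n, ], each = npad) -
    x[(n - 1):(n - npad), , drop = FALSE]
  x <- rbind(matrix(head_ref, npad), x, matrix(tail_ref, npad))
  y <- filter_cols(b, a, x)
  y <- filter_cols(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  t(y[(npad + 1):(npad + n), , drop = FALSE]) + mu
}

#' Detrend and low-pass filter calcium traces
#'
#' Removes the per-cell least-squares linear trend, then applies a
#' zero-phase (forward-backward) Butterworth low-pass filter at `cutoff_hz`
#' (order 4 by default). Length is preserved. The 5 Hz low-pass is used for
#' the population-vector, co-activity-network and decoder analyses;
#' `cutoff_hz = NA` skips filtering and detrends only (appropriate for
#' responsiveness classification, where low-passed noise would be strongly
#' autocorrelated within short windows).
#'
#' @param x cells x frames matrix or a single numeric trace
#' @param frame_rate_hz sampling rate (must exceed twice the cutoff)
#' @param cutoff_hz low-pass cutoff (default 5 Hz); `NA` to detrend only
#' @param order Butterworth filter order
#' @return conditioned traces, same shape, with a provenance tag
#' @export
condition_trace <- function(x, frame_rate_hz, cutoff_hz = 5, order = 4L) {
  if (!is.na(cutoff_hz) && cutoff_hz >= frame_rate_hz / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  n <- ncol(m)
  t_idx <- seq_len(n)
  detr <- t(stats::lm.fit(cbind(1, t_idx), t(m))$residuals)
  out <- if (is.na(cutoff_hz)) {
    detr
  } else {
    bf <- signal::butter(order, cutoff_hz / (frame_rate_hz / 2),
                         type = "low")
    filtfilt_rows(bf, detr)
  }
  if (vec) out <- as.numeric(out)
  out <- add_provenance(out, "conditioned")
  attr(out, "frame_rate") <- frame_rate_hz
  out
}

#' Down-sample traces by anti-aliased frame averaging
#'
#' Low-pass filters at the target Nyquist frequency, then averages
#' consecutive frames into bins of `frame_rate_hz / target_hz` frames.
#' Used at 5 Hz for behaviour-activity correlations and at 3 Hz for
#' decoder features.
#'
#' @param x cells x frames matrix or a single trace
#' @param frame_rate_hz input rate
#' @param target_hz output rate; `frame_rate_hz / target_hz` must be a
#'   whole number of frames
#' @return down-sampled traces (`floor(n / factor)` samples)
#' @export
downsample_trace <- function(x, frame_rate_hz, target_hz) {
  if (target_hz <= 0) stop("target rate must be positive", call. = FALSE)
  if (target_hz >= frame_rate_hz)
    stop("target rate must be below the input rate", call. = FALSE)
  factor <- frame_rate_hz / target_hz
  if (abs(factor - round(factor)) > 1e-6)
    stop("frame_rate_hz must be an integer multiple of target_hz",
         call. = FALSE)
  factor <- as.integer(round(factor))
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  bf <- signal::butter(4L, (target_hz / 2) / (frame_rate_hz / 2),
                       type = "low")
  filt <- filtfilt_rows(bf, m)
  n_out <- floor(ncol(m) / factor)
  idx <- matrix(seq_len(n_out * factor), nrow = factor)
  out <- t(apply(filt, 1, function(row) colMeans(matrix(row[seq_len(n_out * factor)],
                                                        nrow = factor))))
  if (vec) out <- as.numeric(out)
  attr(out, "frame_rate") <- target_hz
  out
}

#' Z-score traces per cell over the whole session
#'
#' @param x cells x frames conditioned matrix
#' @return z-scored matrix; cells with zero variance are dropped and their
#'   row indices recorded in attribute `excluded`
#' @export
zscore_cells <- function(x) {
  m <- as.matrix(x)
  mu <- rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    message(sum(!keep), " zero-variance cell(s) excluded from z-scoring")
  out <- (m[keep, , drop = FALSE] - mu[keep]) / sds[keep]
  attr(out, "provenance") <- c(attr(x, "provenance"), "zscored")
  attr(out, "excluded") <- unname(which(!keep))
  attr(out, "frame_rate") <- attr(x, "frame_rate")
  out
}

baseline_conventions <- function() {
  c("pre-stim-0.5s", "pre-stim-1s", "pre-stim-2s", "pre-delay-150ms", "none")
}

#' Cut trial-aligned epoch tensors with a baseline convention
#'
#' Extracts a half-open per-trial window (in frames,
#' `round(duration * frame_rate)`) relative to each stimulus onset, and
#' subtracts a per-trial, per-cell baseline mean according to the stated
#' convention: 0.5 s, 1 s or 2 s before stimulus onset, 150 ms before the
#' delay onset, or none. The tensor is tagged with the convention so that
#' downstream analyses can enforce the one they assume.
#'
#' @param x cells x frames trace matrix
#' @param onsets 0-based stimulus-onset frames
#' @param window one of `"stimulus"`, `"delay"`, `"response"`, or a numeric
#'   `c(offset_s, duration_s)` relative to stimulus onset
#' @param frame_rate_hz sampling rate
#' @param baseline baseline convention (see [baseline_conventions()])
#' @param stimulus_s,delay_s,response_s epoch durations (s)
#' @return a `trial_tensor`: array `[trials, cells, frames]` with
#'   attributes `window`, `baseline`, `frame_rate`
#' @export
epoch_and_baseline <- function(x, onsets, window = "stimulus",
                               frame_rate_hz,
                               baseline = "pre-stim-0.5s",
                               stimulus_s = 2, delay_s = 2,
                               response_s = 1.5) {
  baseline <- match.arg(baseline, baseline_conventions())
  m <- as.matrix(x)
  fr <- frame_rate_hz
  n_stim <- win_frames(stimulus_s, fr)
  n_delay <- win_frames(delay_s, fr)
  if (is.character(window)) {
    window <- match.arg(window, c("stimulus", "delay", "response"))
    off <- switch(window, stimulus = 0L, delay = n_stim,
                  response = n_stim + n_delay)
    len <- switch(window, stimulus = n_stim, delay = n_delay,
                  response = win_frames(response_s, fr))
    wlabel <- window
  } else {
    off <- win_frames(window[1], fr)
    len <- win_frames(window[2], fr)
    wlabel <- sprintf("custom[%gs,%gs)", window[1], window[1] + window[2])
  }
  b_off <- switch(baseline,
                  `pre-stim-0.5s` = -win_frames(0.5, fr),
                  `pre-stim-1s` = -win_frames(1, fr),
                  `pre-stim-2s` = -win_frames(2, fr),
                  `pre-delay-150ms` = n_stim - win_frames(0.15, fr),
                  none = NA_integer_)
  b_len <- switch(baseline,
                  `pre-stim-0.5s` = win_frames(0.5, fr),
                  `pre-stim-1s` = win_frames(1, fr),
                  `pre-stim-2s` = win_frames(2, fr),
                  `pre-delay-150ms` = win_frames(0.15, fr),
                  none = 0L)
  lo <- onsets + off
  hi <- onsets + off + len - 1L
  blo <- if (!is.na(b_off)) onsets + b_off else lo
  bad <- which(pmin(lo, blo) < 0 | hi >= ncol(m))
  if (length(bad) > 0)
    stop("window out of range for trial(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  n_trials <- length(onsets)
  out <- array(NA_real_, c(n_trials, nrow(m), len))
  for (t in seq_len(n_trials)) {
    seg <- m[, (lo[t] + 1L):(hi[t] + 1L), drop = FALSE]
    if (baseline != "none") {
      bl <- rowMeans(m[, (blo[t] + 1L):(blo[t] + b_len), drop = FALSE])
      seg <- seg - bl
    }
    out[t, , ] <- seg
  }
  structure(out, class = "trial_tensor", window = wlabel,
            baseline = baseline, frame_rate = fr)
}

#' Assert the baseline convention of a trial tensor
#' @param tensor a `trial_tensor`
#' @param baseline required convention tag
#' @return the tensor, invisibly
#' @export
require_baseline <- function(tensor, baseline) {
  tag <- attr(tensor, "baseline")
  if (is.null(tag) || tag != baseline)
    stop("tensor baseline is '", tag %||% "<untagged>", "' but '", baseline,
         "' is required by this analysis", call. = FALSE)
  invisible(tensor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
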