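#' Classify a trial outcome from its type and lick response
#'
#' Go trials require a lick (Hit) and are otherwise a Miss; Nogo trials
#' require withholding (Correct Rejection, CR) and a lick is a False Alarm
#' (FA); catch trials present no stimulus and are scored catch-CR/catch-FA.
#'
#' @param trial_type one of `"go"`, `"nogo"`, `"catch"`
#' @param licked logical: did the animal respond within the response window
#'   (after the 200 ms grace period, see [response_licked()])
#' @return outcome label: `"Hit"`, `"Miss"`, `"FA"`, `"CR"`, `"catch-FA"`
#'   or `"catch-CR"`
#' @export
classify_outcome <- function(trial_type, licked) {
  trial_type <- match.arg(trial_type, c("go", "nogo", "catch"))
  stopifnot(is.logical(licked), length(licked) == 1L, !is.na(licked))
  switch(trial_type,
         go = if (licked) "Hit" else "Miss",
         nogo = if (licked) "FA" else "CR",
         catch = if (licked) "catch-FA" else "catch-CR")
}

#' Did a trial carry a valid response-window lick?
#'
#' Spout contacts within 200 ms of the response-window onset are treated as
#' accidental (e.g. grooming) and not counted as a response.
#'
#' @param lick_times numeric lick timestamps (s, session clock)
#' @param window_onset_s response-window onset (s)
#' @param window_s response-window duration (s)
#' @param grace_s initial grace period during which contacts are ignored
#' @return logical
#' @export
response_licked <- function(lick_times, window_onset_s, window_s = 1.5,
                            grace_s = 0.2) {
  any(lick_times >= window_onset_s + grace_s &
        lick_times < window_onset_s + window_s)
}

#' Behavioural discriminability index d-prime
#'
#' `d' = Z(hit ratio) - Z(false-alarm ratio)` with `Z` the standard-normal
#' inverse CDF. Nogo and catch trials are pooled into the false-alarm ratio
#' by the caller (see [behavior_summary()]). Ratios of exactly 0 or 1 are
#' adjusted to `1/(2N)` and `1 - 1/(2N)` (N = trials of that class) before
#' the inverse normal, so d-prime is always finite.
#'
#' @param hits,misses number of Hit and Miss trials
#' @param fas,crs number of False Alarm and Correct Rejection trials
#'   (including catch-FA/catch-CR)
#' @return d-prime (numeric scalar)
#' @export
d_prime <- function(hits, misses, fas, crs) {
  n_go <- hits + misses
  n_nogo <- fas + crs
  if (n_go < 1 || n_nogo < 1)
    stop("d_prime needs at least one Go and one Nogo/catch trial",
         call. = FALSE)
  stats::qnorm(adjust_ratio(hits / n_go, n_go)) -
    stats::qnorm(adjust_ratio(fas / n_nogo, n_nogo))
}

#' Log-linear adjustment of extreme hit/false-alarm ratios
#'
#' @param ratio a proportion in `[0, 1]`
#' @param n number of trials the ratio was computed from
#' @return the ratio, with 0 replaced by `1/(2n)` and 1 by `1 - 1/(2n)`
#' @export
adjust_ratio <- function(ratio, n) {
  if (ratio <= 0) return(1 / (2 * n))
  if (ratio >= 1) return(1 - 1 / (2 * n))
  ratio
}

#' Per-session behavioural summary
#'
#' Counts outcomes, computes hit and false-alarm ratios (Nogo and catch
#' trials pooled, since performance develops similarly in both), and d-prime.
#'
#' @param trials a `trial_table` with an `outcome` column
#' @return list with outcome counts, `hit_ratio`, `fa_ratio` and `d_prime`
#' @export
behavior_summary <- function(trials) {
  o <- trials$outcome
  n <- c(hits = sum(o == "Hit"), misses = sum(o == "Miss"),
         fas = sum(o %in% c("FA", "catch-FA")),
         crs = sum(o %in% c("CR", "catch-CR")))
  list(counts = n,
       hit_ratio = n[["hits"]] / (n[["hits"]] + n[["misses"]]),
       fa_ratio = n[["fas"]] / (n[["fas"]] + n[["crs"]]),
       d_prime = d_prime(n[["hits"]], n[["misses"]], n[["fas"]], n[["crs"]]))
}

#' Partition sessions into naive and expert learning phases
#'
#' The expert criterion is d-prime above `threshold` on `n_consecutive`
#' consecutive sessions; the expert-onset session is the one ending the
#' first such run. The naive phase is the first up-to-three sessions that
#' are themselves below threshold (animals that learn very fast contribute
#' only two naive sessions). The expert set used for analysis selection is
#' every session with d-prime above threshold.
#'
#' @param dprime numeric d-prime series, one value per session
#' @param threshold expert criterion (default 1.5)
#' @param n_consecutive run length required for expert status
#' @return list with 1-based `naive` indices, `expert` indices and
#'   `expert_onset` (NA if the criterion is never met)
#' @export
learning_phases <- function(dprime, threshold = 1.5, n_consecutive = 3L) {
  if (length(dprime) < n_consecutive)
    stop("need at least ", n_consecutive, " sessions", call. = FALSE)
  above <- dprime > threshold
  onset <- NA_integer_
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= n_consecutive) { onset <- i; break }
  }
  first3 <- seq_len(min(3L, length(dprime)))
  list(naive = first3[!above[first3]],
       expert = which(above),
       expert_onset = onset)
}

#' Anticipatory licking during the delay period
#'
#' Counts licks whose timestamps fall in the half-open delay window
#' `[delay onset, delay end)` of each trial, and computes the lick
#' probability per time bin across trials (optionally smoothed with a
#' 5-frame moving average, for display only).
#'
#' @param lick_times list of per-trial lick timestamp vectors (s)
#' @param delay_onset_s per-trial delay-period onsets (s)
#' @param delay_s delay duration (s)
#' @param frame_rate_hz bin rate for the lick-probability trace
#' @param smooth smooth the probability trace with a 5-frame moving average
#' @return list with per-trial `counts` and per-bin `probability`
#' @export
anticipatory_licks <- function(lick_times, delay_onset_s, delay_s = 2,
                               frame_rate_hz = 30, smooth = FALSE) {
  stopifnot(length(lick_times) == length(delay_onset_s))
  n_bins <- win_frames(delay_s, frame_rate_hz)
  counts <- integer(length(lick_times))
  hits <- matrix(0, length(lick_times), n_bins)
  for (i in seq_along(lick_times)) {
    rel <- lick_times[[i]] - delay_onset_s[i]
    rel <- rel[rel >= 0 & rel < delay_s]
    counts[i] <- length(rel)
    if (length(rel) > 0) {
      b <- pmin(floor(rel * frame_rate_hz) + 1L, n_bins)
      hits[i, unique(b)] <- 1
    }
  }
  prob <- colMeans(hits)
  if (smooth) prob <- movmean(prob, 5L)
  list(counts = counts, probability = prob)
}

#' Correlate single-cell activity with a behavioural variable
#'
#' Pearson correlation between each cell's calcium trace and a behavioural
#' trace (locomotion or pupil area) over a set of masked samples, both on a
#' shared 5 Hz clock. A cell is flagged as significantly correlated iff
#' `|r| > 0.2` and `p < 0.05` (two-sided t-transform p-value). Constant
#' cells, for which Pearson's r is undefined, are excluded and counted.
#'
#' @param cell_mat cells x samples matrix (down-sampled to 5 Hz)
#' @param behav_trace behavioural samples on the same clock
#' @param mask logical or integer sample selector (e.g. one task epoch);
#'   defaults to all samples
#' @param r_threshold,alpha joint significance criterion
#' @return data frame with per-cell `r`, `p`, `significant`; the flagged
#'   fraction and the number of excluded cells are attached as attributes
#'   `fraction` and `n_excluded`
#' @export
behavior_activity_correlation <- function(cell_mat, behav_trace, mask = NULL,
                                          r_threshold = 0.2, alpha = 0.05) {
  if (is.null(mask)) mask <- seq_len(ncol(cell_mat))
  x <- behav_trace[mask]
  m <- cell_mat[, mask, drop = FALSE]
  if (length(x) < 3) stop("fewer than 3 masked samples", call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  keep <- sds > 0 & !is.na(sds)
  res <- data.frame(cell = which(keep), r = NA_real_, p = NA_real_)
  if (any(keep)) {
    r <- as.numeric(stats::cor(t(m[keep, , drop = FALSE]), x))
    res$r <- r
    res$p <- pearson_p(r, length(x))
  }
  res$significant <- abs(res$r) > r_threshold & res$p < alpha
  attr(res, "fraction") <- mean(res$significant)
  attr(res, "n_excluded") <- sum(!keep)
  res
}
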