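# Internal helpers shared across modules.

#' Number of frames spanned by a duration
#'
#' Windows are half-open `[start, start + n)` in 0-based frames; the length is
#' `round(duration * frame_rate)` so that epoching is exact integer arithmetic.
#'
#' @param duration_s duration in seconds
#' @param frame_rate sampling rate in Hz
#' @return integer number of frames
#' @keywords internal
win_frames <- function(duration_s, frame_rate) {
  as.integer(round(duration_s * frame_rate))
}

# Append a processing step to the provenance attribute of a trace object.
add_provenance <- function(x, step) {
  attr(x, "provenance") <- c(attr(x, "provenance"), step)
  x
}

has_step <- function(x, step) {
  step %in% attr(x, "provenance")
}

# Pearson correlation p-value via the t transform, two-sided.
pearson_p <- function(r, n) {
  if (n < 3) return(NA_real_)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

# Restore the caller's RNG state on exit so seeded helpers do not perturb
# the global stream.
local_seed <- function(seed, envir = parent.frame()) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  do.call(on.exit, list(bquote(assign(".Random.seed", .(old), globalenv())),
                        add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Moving average with window w (centred, shrinking at the edges), as used for
# display smoothing of lick probabilities.
movmean <- function(x, w = 5L) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}
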