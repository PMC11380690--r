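#' Exact two-sided Wilcoxon signed-rank test against zero
#'
#' Zero differences are dropped; tied absolute values receive midranks.
#' For up to `exact_n` retained observations the null distribution of the
#' positive-rank sum is computed exactly by dynamic programming over the
#' doubled (hence integer) midranks, which reproduces full sign-flip
#' enumeration including under ties. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x numeric sample (tested against median zero)
#' @param exact_n largest sample size for the exact distribution
#' @return list with `statistic` (positive-rank sum `W+`), `p`, `n_used`,
#'   and `method`; `p` is `NA` if all values are zero
#' @export
signed_rank_test <- function(x, exact_n = 50L) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0)
    return(list(statistic = NA_real_, p = NA_real_, n_used = 0L,
                method = "degenerate"))
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_n) {
    # doubled midranks are integers; DP over the sign-flip distribution
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)   # counts over W2 = 0..total
    dist[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(total + 1L - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = w, p = p, n_used = n, method = method)
}

#' Two-step stimulus-responsiveness classification of one cell
#'
#' Step 1: a two-sided Wilcoxon signed-rank test asks whether the per-trial
#' mean responses (z units, baselined) differ from zero. Step 2: cells
#' passing step 1 must also exceed a median-response threshold
#' (`|median| > 0.2` z) to be called `excited` (positive median) or
#' `inhibited` (negative median). For auditory stimuli a second, 0.3 s
#' onset window is evaluated the same way to catch fast-adapting cells;
#' the cell is responsive if either window passes.
#'
#' @param responses per-trial mean responses over the full stimulus window
#' @param onset_responses optional per-trial means over the 0.3 s onset
#'   window (auditory trials only)
#' @param alpha signed-rank significance level (per cell, uncorrected)
#' @param threshold median z-score threshold
#' @return a `responsiveness_call`: list with `call` (one of `excited`,
#'   `inhibited`, `nonresponsive`), per-window `p` and `median`, and the
#'   window that drove the call
#' @export
classify_cell <- function(responses, onset_responses = NULL, alpha = 0.05,
                          threshold = 0.2) {
  if (length(responses) < 5)
    stop("classification needs at least 5 trials", call. = FALSE)
  eval_window <- function(x) {
    sr <- signed_rank_test(x)
    med <- stats::median(x)
    call <- "nonresponsive"
    if (!is.na(sr$p) && sr$p < alpha) {
      if (med > threshold) call <- "excited"
      if (med < -threshold) call <- "inhibited"
    }
    list(p = sr$p, median = med, call = call)
  }
  full <- eval_window(responses)
  onset <- if (!is.null(onset_responses)) eval_window(onset_responses)
  res <- full
  window <- "full"
  if (full$call == "nonresponsive" && !is.null(onset) &&
      onset$call != "nonresponsive") {
    res <- onset
    window <- "onset"
  }
  structure(list(call = res$call, p = full$p, median = full$median,
                 onset_p = onset$p %||% NA_real_,
                 onset_median = onset$median %||% NA_real_,
                 window = window),
            class = "responsiveness_call")
}

#' Label cells by the trial type they respond to
#'
#' Combines per-cell Go-window and Nogo-window responsiveness calls into
#' `Go`, `Nogo`, `both` or `none` labels and population proportions.
#'
#' @param go_calls,nogo_calls character vectors (or lists of
#'   `responsiveness_call`) for the same cells
#' @return list with per-cell `label` and named `proportions` summing to 1
#' @export
label_by_trial_type <- function(go_calls, nogo_calls) {
  as_resp <- function(x) {
    if (is.list(x)) x <- vapply(x, function(ci) ci$call, character(1))
    x != "nonresponsive"
  }
  g <- as_resp(go_calls)
  n <- as_resp(nogo_calls)
  stopifnot(length(g) == length(n))
  label <- ifelse(g & n, "both", ifelse(g, "Go", ifelse(n, "Nogo", "none")))
  lv <- c("Go", "Nogo", "both", "none")
  props <- table(factor(label, levels = lv)) / length(label)
  list(label = label, proportions = as.numeric(props) |>
         stats::setNames(lv))
}

#' Chi-square test on responsive-cell proportions across learning phases
#'
#' Pearson chi-square on a 2 x K contingency table of pooled cell counts
#' per category (e.g. Go / Nogo / both / none) in two phases, with K - 1
#' degrees of freedom.
#'
#' @param counts_a,counts_b named category counts in the two phases
#' @return list with `statistic`, `df`, `p`
#' @export
proportion_transition_test <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 2)
    stop("need matching counts over at least 2 categories", call. = FALSE)
  tab <- rbind(a = counts_a, b = counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    warning("expected cell count below 1; chi-square may be unreliable")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Per-trial mean responses for responsiveness testing
#'
#' Convenience wrapper: reduces a trial tensor to per-trial per-cell means,
#' restricted to a trial subset.
#'
#' @param tensor a `trial_tensor` `[trials, cells, frames]`
#' @param trial_idx trials to include (default all)
#' @return trials x cells matrix of window means
#' @export
trial_means <- function(tensor, trial_idx = NULL) {
  if (is.null(trial_idx)) trial_idx <- seq_len(dim(tensor)[1])
  apply(tensor[trial_idx, , , drop = FALSE], c(1, 2), mean)
}
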