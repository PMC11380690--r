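#' Split-half responsiveness for sensory-mapping stimuli
#'
#' For one stimulus type, each trial's 2 s stimulus window is split in
#' half (0-1 s and 1-2 s) and the two half-window means enter the
#' two-step responsiveness classifier as individual data points, doubling
#' the sample (8 trials give 16 points per cell).
#'
#' @param tensor a `trial_tensor` over the 2 s stimulus window (baselined
#'   to 0.5 s pre-stimulus)
#' @param trial_idx trials of the stimulus type under test
#' @param alpha,threshold classifier parameters (see [classify_cell()])
#' @return list of `responsiveness_call`, one per cell
#' @export
split_half_responsiveness <- function(tensor, trial_idx = NULL,
                                      alpha = 0.05, threshold = 0.2) {
  if (is.null(trial_idx)) trial_idx <- seq_len(dim(tensor)[1])
  n_frames <- dim(tensor)[3]
  half <- n_frames %/% 2
  sub <- tensor[trial_idx, , , drop = FALSE]
  first <- apply(sub[, , seq_len(half), drop = FALSE], c(1, 2), mean)
  second <- apply(sub[, , (half + 1):n_frames, drop = FALSE], c(1, 2), mean)
  points <- rbind(first, second)   # (2 * trials) x cells
  lapply(seq_len(ncol(points)), function(cell)
    classify_cell(points[, cell], alpha = alpha, threshold = threshold))
}

#' Tuning-curve feature matrix and correlation-distance k-means
#'
#' Assembles the cells x 20 matrix of mean stimulus-window responses
#' (5 auditory frequencies x uni-/multisensory x pre-/post-learning) in
#' the column order pre-multi f1..f5, post-multi f1..f5, pre-uni f1..f5,
#' post-uni f1..f5, and clusters the rows with correlation-distance
#' k-means (k-means with cosine distance on row-centred features).
#'
#' @param tuning long-format data frame with columns `cell`,
#'   `frequency_khz`, `context` (`uni`/`multi`), `phase` (`pre`/`post`),
#'   `response`
#' @param k number of tuning clusters (default 8)
#' @param seed RNG seed
#' @param cluster set `FALSE` to return only the matrix
#' @return list with `matrix` (cells x 20) and, if clustered,
#'   `assignments` and the underlying `model`
#' @export
tuning_matrix <- function(tuning, k = 8L, seed = 1L, cluster = TRUE) {
  freqs <- c(4, 8, 12, 16, 20)
  blocks <- list(c("pre", "multi"), c("post", "multi"),
                 c("pre", "uni"), c("post", "uni"))
  cells <- sort(unique(tuning$cell))
  m <- matrix(NA_real_, length(cells), 20,
              dimnames = list(cells, NULL))
  col <- 0L
  for (b in blocks) for (f in freqs) {
    col <- col + 1L
    rows <- tuning$phase == b[1] & tuning$context == b[2] &
      tuning$frequency_khz == f
    v <- tuning$response[rows][match(cells, tuning$cell[rows])]
    m[, col] <- v
  }
  complete <- rowSums(is.na(m)) == 0
  if (!all(complete))
    message(sum(!complete), " cell(s) dropped: missing tuning features")
  m <- m[complete, , drop = FALSE]
  out <- list(matrix = m)
  if (cluster) {
    centred <- m - rowMeans(m)
    ok <- apply(centred, 1, function(r) any(r != 0))
    model <- cluster_cells(centred[ok, , drop = FALSE], k = k, seed = seed,
                           n_restarts = 20L, var_explained = 0.999)
    out$assignments <- rep(NA_integer_, nrow(m))
    out$assignments[ok] <- model$assignments
    out$model <- model
  }
  out
}

#' Pre/post tuning-curve stability
#'
#' Pearson correlation between each cell's 5-point pre- and post-learning
#' frequency tuning curves, separately for uni- and multisensory trials;
#' the two stability distributions are compared with a two-sample KS test.
#'
#' @param mat cells x 20 tuning matrix from [tuning_matrix()]
#' @return list with per-cell `r_uni`, `r_multi` (NA where a curve is
#'   constant, with a logged count) and `ks` (the uni-vs-multi test)
#' @export
tuning_stability <- function(mat) {
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  r_multi <- vapply(seq_len(nrow(mat)), function(i)
    safe_cor(mat[i, 1:5], mat[i, 6:10]), numeric(1))
  r_uni <- vapply(seq_len(nrow(mat)), function(i)
    safe_cor(mat[i, 11:15], mat[i, 16:20]), numeric(1))
  n_excl <- sum(is.na(r_uni)) + sum(is.na(r_multi))
  if (n_excl > 0)
    message(n_excl, " constant tuning curve(s) excluded from stability")
  ks <- suppressWarnings(
    stats::ks.test(r_uni[!is.na(r_uni)], r_multi[!is.na(r_multi)]))
  list(r_uni = r_uni, r_multi = r_multi,
       ks = list(statistic = unname(ks$statistic), p = ks$p.value))
}

#' Multisensory integration index
#'
#' `index_f = |AV_f| / |A_f + V|` per cell and auditory frequency, where
#' `A_f` is the mean uni-auditory response, `V` the direction-averaged
#' uni-visual response and `AV_f` the direction-averaged multisensory
#' response. An index of 1 indicates linear integration, above 1
#' supralinear. Exclusions, recorded with a reason: cells non-significant
#' in both the AV and A trials (`both-nonsignificant`), cells whose
#' multisensory response and unisensory sum have opposite signs
#' (`sign-conflict`, `AV * (A + V) < 0`), and zero denominators.
#'
#' @param A,V,AV mean responses (vectors over cell-frequency records)
#' @param sig_A,sig_AV logical responsiveness of the A and AV responses
#' @return data frame with `index` (NA where excluded) and
#'   `exclusion_reason`
#' @export
multisensory_index <- function(A, V, AV, sig_A = TRUE, sig_AV = TRUE) {
  n <- length(A)
  stopifnot(length(V) == n, length(AV) == n)
  sig_A <- rep_len(sig_A, n)
  sig_AV <- rep_len(sig_AV, n)
  reason <- rep("none", n)
  reason[!sig_A & !sig_AV] <- "both-nonsignificant"
  reason[reason == "none" & AV * (A + V) < 0] <- "sign-conflict"
  reason[reason == "none" & A + V == 0] <- "zero-denominator"
  idx <- ifelse(reason == "none", abs(AV) / abs(A + V), NA_real_)
  data.frame(index = idx, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Two-dimensional two-sample Kolmogorov-Smirnov test
#'
#' Fasano-Franceschini variant: the statistic is the largest difference
#' between the two samples' empirical quadrant fractions, maximised over
#' all four quadrants anchored at every observed point; the p-value comes
#' from a permutation null.
#'
#' @param x1,y1 first sample coordinates
#' @param x2,y2 second sample coordinates
#' @param n_perm permutation resamples for the p-value
#' @param seed RNG seed
#' @return list with `statistic` and `p`
#' @export
ks2d_test <- function(x1, y1, x2, y2, n_perm = 200L, seed = 1L) {
  stat <- function(ax, ay, bx, by) {
    px <- c(ax, bx); py <- c(ay, by)
    d <- 0
    for (i in seq_along(px)) {
      for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
        fa <- mean(sx * (ax - px[i]) >= 0 & sy * (ay - py[i]) >= 0)
        fb <- mean(sx * (bx - px[i]) >= 0 & sy * (by - py[i]) >= 0)
        d <- max(d, abs(fa - fb))
      }
    }
    d
  }
  d_obs <- stat(x1, y1, x2, y2)
  local_seed(seed)
  n1 <- length(x1)
  px <- c(x1, x2); py <- c(y1, y2)
  d_null <- vapply(seq_len(n_perm), function(p) {
    idx <- sample.int(length(px), n1)
    stat(px[idx], py[idx], px[-idx], py[-idx])
  }, numeric(1))
  list(statistic = d_obs, p = (1 + sum(d_null >= d_obs)) / (1 + n_perm))
}

#' Single-cell PSTH correlation across mapping sessions
#'
#' Pearson correlation between each cell's stimulus-condition-concatenated
#' response time series before and after learning; constant series are
#' excluded. Reports the per-cell values and their mean with SEM.
#'
#' @param pre,post cells x time matrices on a common time base
#' @return list with per-cell `r`, `mean`, `sem`, `n_excluded`
#' @export
cross_session_psth_correlation <- function(pre, post) {
  if (!all(dim(pre) == dim(post)))
    stop("pre and post PSTH matrices must have equal shape", call. = FALSE)
  r <- vapply(seq_len(nrow(pre)), function(i) {
    if (stats::sd(pre[i, ]) == 0 || stats::sd(post[i, ]) == 0)
      return(NA_real_)
    stats::cor(pre[i, ], post[i, ])
  }, numeric(1))
  ok <- !is.na(r)
  list(r = r, mean = mean(r[ok]),
       sem = stats::sd(r[ok]) / sqrt(sum(ok)),
       n_excluded = sum(!ok))
}
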