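# Independent oracles used across the suite. These deliberately take the
# slow, direct route (enumeration, dense all-pairs recursion) so they share
# no code with the implementation they check.

# All-pairs shortest paths by Floyd-Warshall on an explicit length matrix
# (Inf where no edge).
oracle_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Exact two-sided signed-rank p by full 2^n sign-flip enumeration.
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Direct evaluation of the weighted triad clustering coefficient: explicit
# loop over ordered neighbour pairs.
oracle_clustering_coefficient <- function(w) {
  mx <- max(w)
  wh <- w / mx
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    s <- 0
    for (j in nb) for (l in nb) {
      if (j == l) next
      s <- s + (wh[i, j] * wh[i, l] * wh[j, l])^(1 / 3)
    }
    s / (k * (k - 1))
  }, numeric(1))
}

# Binary clustering coefficient by triangle counting.
oracle_binary_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (j in nb) for (l in nb) if (j < l && adj[j, l] > 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Random positive-regime correlation graph on n nodes: symmetric, unit
# diagonal, a fraction of edges present with weights in (0, 1].
random_pos_graph <- function(n, p_edge = 0.7) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        w[i, j] <- w[j, i] <- stats::runif(1, 0.05, 1)
      }
    }
  }
  r <- w
  diag(r) <- 1
  structure(list(r = r, w = w, regime = "positive",
                 node_ids = seq_len(n), m = n, n_removed_cells = 0L),
            class = "coactivity_graph")
}

# Small fully-preprocessed task session: conditioned + z-scored traces and
# tensors for the requested epochs.
make_session_tensors <- function(cfg, phase, seed, epochs = c("delay"),
                                 baseline = "pre-stim-2s") {
  g <- generate_session(cfg, phase, seed)
  z <- zscore_cells(condition_trace(
    neuropil_correct(g$recording$F, g$recording$Fneu),
    cfg$frame_rate_hz))
  tensors <- lapply(epochs, function(ep)
    epoch_and_baseline(z, g$trials$onset_frame, ep, cfg$frame_rate_hz,
                       baseline = baseline))
  names(tensors) <- epochs
  list(session = g, z = z, tensors = tensors)
}

# Compact config used by most pipeline tests (sizes chosen for runtime).
small_cfg <- function(...) {
  sim_config(n_cells = 30L, n_trials = 20L, iti_range_s = c(3, 5), ...)
}
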