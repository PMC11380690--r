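make_graph_tensor <- function(cell_series) {
  # cell_series: cells x (trials * frames); reshape to trials x cells x frames
  n_trials <- 4L
  frames <- ncol(cell_series) / n_trials
  arr <- array(NA_real_, c(n_trials, nrow(cell_series), frames))
  for (t in seq_len(n_trials)) {
    arr[t, , ] <- cell_series[, ((t - 1) * frames + 1):(t * frames)]
  }
  structure(arr, class = "trial_tensor", window = "delay",
            baseline = "pre-stim-2s", frame_rate = 30)
}

graph_from_w <- function(w, regime = "positive") {
  r <- w
  diag(r) <- 1
  structure(list(r = r, w = w, regime = regime,
                 node_ids = seq_len(nrow(w)), m = nrow(w),
                 n_removed_cells = 0L),
            class = "coactivity_graph")
}

test_that("a shared signal makes all correlations one", {
  base <- sin(seq(0, 20, length.out = 240))
  series <- rbind(base, 2 * base + 1, 0.5 * base - 3)
  g <- build_coactivity_graph(make_graph_tensor(series))
  expect_true(all(abs(g$r - 1) < 1e-10))
})

test_that("independent noise yields small correlations, order-invariantly", {
  set.seed(20)
  series <- matrix(rnorm(50 * 240), 50)
  ten <- make_graph_tensor(series)
  g <- build_coactivity_graph(ten)
  off <- g$r[upper.tri(g$r)]
  expect_lt(mean(abs(off)), 0.08)
  # permuting trial order leaves the adjacency unchanged
  perm <- c(3, 1, 4, 2)
  g2 <- build_coactivity_graph(ten, trial_filter = perm)
  expect_equal(g2$r, g$r, tolerance = 1e-12)
})

test_that("hubness is the mean correlation to the other nodes", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- 0.8
  g <- graph_from_w(w)
  h <- hubness(g)
  expect_equal(h$H[1], 0.35)
  expect_equal(h$H[2], 0.65)
  expect_equal(h$H[3], 0.5)
  # literal printed form includes the unit self-term
  expect_equal(hubness(g, include_self = TRUE)$H[1], (1 + 0.5 + 0.2) / 3)
  # all-ones graph
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  expect_equal(hubness(graph_from_w(ones))$H, rep(1, 4))
  # random graphs match the brute-force row mean
  set.seed(2)
  for (i in 1:20) {
    g <- random_pos_graph(sample(3:8, 1))
    brute <- sapply(seq_len(g$m), function(i) sum(g$w[i, -i]) / (g$m - 1))
    expect_equal(hubness(g)$H, brute, tolerance = 1e-12)
  }
})

test_that("geodesics prefer strong indirect routes over weak direct edges", {
  w <- matrix(0, 3, 3)
  w[1, 3] <- w[3, 1] <- 1      # A-C
  w[3, 2] <- w[2, 3] <- 1      # C-B
  w[1, 2] <- w[2, 1] <- 0.25   # weak direct A-B: length 4
  sp <- shortest_paths_graph(graph_from_w(w))
  expect_equal(sp$L[1, 2], 2)  # via C, not the direct length-4 edge
})

test_that("disconnected components are excluded with the right pair count", {
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.5
  w[4, 5] <- w[5, 4] <- 0.5
  sp <- shortest_paths_graph(graph_from_w(w))
  expect_equal(sp$n_unreachable_pairs, 2 * 3)
  expect_true(is.finite(sp$mean))
})

test_that("Dijkstra equals a Floyd-Warshall oracle on random graphs", {
  set.seed(33)
  for (i in 1:200) {
    g <- random_pos_graph(sample(3:8, 1), p_edge = runif(1, 0.3, 0.9))
    len <- ifelse(g$w > 0, 1 / g$w, Inf)
    expect_equal(shortest_paths_graph(g)$L, oracle_floyd_warshall(len),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("triad clustering coefficient matches direct evaluation", {
  # triangle with weights 0.9, 0.6, 0.3
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.6
  w[2, 3] <- w[3, 2] <- 0.3
  C <- clustering_coefficient(graph_from_w(w))$C
  expect_equal(C, rep(0.605706864277, 3), tolerance = 1e-9)
  # complete graph with uniform weights: all ones
  u <- matrix(0.4, 5, 5); diag(u) <- 0
  expect_equal(clustering_coefficient(graph_from_w(u))$C, rep(1, 5))
  # degree-1 node gets zero
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 0.5
  expect_equal(clustering_coefficient(graph_from_w(chain))$C, rep(0, 3))
  # random graphs match the ordered-pair enumeration oracle
  set.seed(4)
  for (i in 1:30) {
    g <- random_pos_graph(sample(4:8, 1))
    expect_equal(clustering_coefficient(g)$C,
                 oracle_clustering_coefficient(g$w), tolerance = 1e-12)
  }
})

test_that("uniform weights reduce to the binary clustering coefficient", {
  set.seed(5)
  for (i in 1:20) {
    g <- random_pos_graph(sample(4:8, 1))
    g$w[g$w > 0] <- 0.7
    expect_equal(clustering_coefficient(g)$C,
                 oracle_binary_clustering(g$w > 0), tolerance = 1e-12)
  }
})

test_that("bootstrap deltas are zero against self and seed-stable", {
  set.seed(6)
  vals <- c(rnorm(50, 1), rnorm(50, 1.2))
  cond <- rep(c("naive", "expert"), each = 50)
  d1 <- bootstrap_delta(vals, cond, baseline = "naive", n_boot = 500,
                        seed = 3)
  d2 <- bootstrap_delta(vals, cond, baseline = "naive", n_boot = 500,
                        seed = 3)
  expect_identical(d1, d2)
  base_row <- d1[d1$condition == "naive", ]
  expect_equal(base_row$delta, 0)
  eff_row <- d1[d1$condition == "expert", ]
  expect_true(eff_row$ci_lo <= eff_row$delta &
                eff_row$delta <= eff_row$ci_hi)
  expect_warning(bootstrap_delta(vals, cond, "naive", n_boot = 50),
                 "100")
})

test_that("a planted shift gives a CI excluding zero", {
  set.seed(7)
  vals <- c(rnorm(80, 0, 0.1), rnorm(80, 0.2, 0.1))
  cond <- rep(c("base", "up"), each = 80)
  d <- bootstrap_delta(vals, cond, baseline = "base", n_boot = 1000,
                       seed = 1)
  up <- d[d$condition == "up", ]
  expect_gt(up$ci_lo, 0)
})

test_that("removal shuffles bracket random targets and identity holds", {
  set.seed(8)
  series <- matrix(rnorm(30 * 240), 30) +
    rep(sin(seq(0, 20, length.out = 240)), each = 30)
  ten <- make_graph_tensor(series)
  res0 <- removal_shuffle(ten, integer(0), n_shuffles = 3, seed = 1)
  expect_equal(res0$targeted, res0$full, tolerance = 1e-12)
  res <- removal_shuffle(ten, sample.int(30, 6), n_shuffles = 30, seed = 2)
  expect_true(res$targeted[["hubness"]] >= min(res$shuffle$hubness) - 0.05)
  expect_true(res$targeted[["hubness"]] <= max(res$shuffle$hubness) + 0.05)
  expect_error(removal_shuffle(ten, 1:30, n_shuffles = 2), "empty")
})
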