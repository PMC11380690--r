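#' Build a weighted co-activity graph from concatenated epoch time series
#'
#' For each cell, the within-window time series of the filtered trials are
#' concatenated; the adjacency is the cells x cells Pearson correlation
#' matrix of these concatenations. Positive and negative edges are
#' analysed as separate regimes: the positive regime keeps edges with
#' `r > 0`; the negative regime keeps edges with `r < 0`, weighted by
#' `|r|`. Zero-variance cells are removed and counted.
#'
#' @param tensor a `trial_tensor` baselined to `pre-stim-2s`
#' @param trial_filter logical or integer trial selector (default all)
#' @param regime `"positive"` or `"negative"`
#' @return a `coactivity_graph`: list with the raw correlation matrix `r`,
#'   regime weight matrix `w` (zero where no edge), `regime`, `node_ids`
#'   (original cell indices), `m` (node count), `n_removed_cells`
#' @export
build_coactivity_graph <- function(tensor, trial_filter = NULL,
                                   regime = c("positive", "negative")) {
  regime <- match.arg(regime)
  require_baseline(tensor, "pre-stim-2s")
  if (is.null(trial_filter)) trial_filter <- seq_len(dim(tensor)[1])
  if (is.logical(trial_filter)) trial_filter <- which(trial_filter)
  if (length(trial_filter) < 2)
    stop("need at least 2 trials", call. = FALSE)
  sub <- tensor[trial_filter, , , drop = FALSE]
  n_cells <- dim(sub)[2]
  # concatenate trials: cells x (trials * frames)
  conc <- t(apply(sub, 2, function(cell_mat) as.numeric(t(cell_mat))))
  sds <- apply(conc, 1, stats::sd)
  keep <- sds > 0 & !is.na(sds)
  if (sum(keep) < 2)
    stop("fewer than 2 usable cells", call. = FALSE)
  conc <- conc[keep, , drop = FALSE]
  r <- stats::cor(t(conc))
  diag(r) <- 1
  w <- if (regime == "positive") ifelse(r > 0, r, 0) else ifelse(r < 0, -r, 0)
  diag(w) <- 0
  structure(list(r = r, w = w, regime = regime,
                 node_ids = which(keep), m = sum(keep),
                 n_removed_cells = sum(!keep)),
            class = "coactivity_graph")
}

#' Node hubness: mean pairwise activity correlation
#'
#' The hubness of node i is the mean of its edge weights to the other
#' nodes. By default the self-term is excluded (mean over the m - 1 other
#' nodes, matching "correlation of each node to all the others");
#' `include_self = TRUE` gives the literal sum over all m nodes divided by
#' m, which includes `r_ii = 1`.
#'
#' @param graph a `coactivity_graph`
#' @param include_self divide the row sum (plus 1 for the diagonal) by m
#'   instead of excluding the self-term
#' @return list with per-node `H` and the population `mean`
#' @export
hubness <- function(graph, include_self = FALSE) {
  if (graph$m < 2) stop("hubness needs at least 2 nodes", call. = FALSE)
  w <- graph$w
  h <- if (include_self) (rowSums(w) + 1) / graph$m
       else rowSums(w) / (graph$m - 1)
  list(H = h, mean = mean(h))
}

#' Geodesic path lengths on inverse-correlation edge lengths
#'
#' Assigns each edge the length `1 / r_ij` and computes all-pairs shortest
#' paths with Dijkstra's algorithm over the existing edges of the regime.
#' Pairs in different connected components are unreachable and excluded
#' from the mean, with their count reported.
#'
#' @param graph a `coactivity_graph`
#' @return list with the `L` matrix (Inf where unreachable), `mean`
#'   (finite off-diagonal pairs) and `n_unreachable_pairs`
#' @export
shortest_paths_graph <- function(graph) {
  w <- graph$w
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  L <- igraph::distances(g, algorithm = "dijkstra")
  off <- L[upper.tri(L)]
  list(L = L, mean = mean(off[is.finite(off)]),
       n_unreachable_pairs = sum(!is.finite(off)))
}

#' Weighted triad clustering coefficient (max-normalised weights)
#'
#' For each node i with degree `k_i`,
#' `C_i = 1 / (k_i (k_i - 1)) * sum_{j != k} (w'_ij w'_ik w'_jk)^(1/3)`
#' where `w' = w / max(w)` is the adjacency normalised by its maximum
#' weight. The sum runs over ordered neighbour pairs; nodes with degree
#' at most 1 get `C_i = 0`. With uniform weights this reduces to the
#' binary clustering coefficient.
#'
#' @param graph a `coactivity_graph`
#' @return list with per-node `C` and the population `mean`
#' @export
clustering_coefficient <- function(graph) {
  w <- graph$w
  mx <- max(w)
  if (mx == 0) return(list(C = rep(0, graph$m), mean = 0))
  wh <- (w / mx)^(1 / 3)
  diag(wh) <- 0
  triads <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  C <- ifelse(denom > 0, triads / denom, 0)
  list(C = C, mean = mean(C))
}

#' Bootstrap delta of a network metric between conditions
#'
#' Resamples the per-unit metric values (nodes for hubness and clustering
#' coefficient, pairs for path length) with replacement within each
#' condition, and reports each condition's mean difference to the baseline
#' condition with a percentile 95% confidence interval.
#'
#' @param values numeric per-unit metric values, all conditions pooled
#' @param condition condition label per value
#' @param baseline the reference condition
#' @param n_boot bootstrap resamples (default 3000)
#' @param seed RNG seed
#' @param conf confidence level
#' @return data frame with one row per condition: `delta`, `ci_lo`,
#'   `ci_hi`, `n`
#' @export
bootstrap_delta <- function(values, condition, baseline, n_boot = 3000L,
                            seed = 1L, conf = 0.95) {
  if (n_boot < 100) warning("fewer than 100 bootstrap resamples")
  condition <- as.character(condition)
  stopifnot(baseline %in% condition)
  local_seed(seed)
  groups <- split(values, condition)
  boot_means <- lapply(groups, function(v)
    vapply(seq_len(n_boot), function(b)
      mean(sample(v, length(v), replace = TRUE)), numeric(1)))
  alpha <- (1 - conf) / 2
  res <- lapply(names(groups), function(g) {
    point <- mean(groups[[g]]) - mean(groups[[baseline]])
    if (g == baseline) {
      data.frame(condition = g, delta = 0, ci_lo = 0, ci_hi = 0,
                 n = length(groups[[g]]))
    } else {
      d <- boot_means[[g]] - boot_means[[baseline]]
      data.frame(condition = g, delta = point,
                 ci_lo = unname(stats::quantile(d, alpha)),
                 ci_hi = unname(stats::quantile(d, 1 - alpha)),
                 n = length(groups[[g]]))
    }
  })
  do.call(rbind, res)
}

#' Network metrics after targeted and random cell removal
#'
#' Rebuilds the co-activity graph after removing a target cell set, and
#' after `n_shuffles` random removals of the same size, recomputing mean
#' hubness, mean path length and mean clustering coefficient each time.
#'
#' @param tensor a `trial_tensor` baselined to `pre-stim-2s`
#' @param remove_ids cell indices (into the tensor) to remove
#' @param trial_filter trial selector
#' @param n_shuffles random removals (default 30)
#' @param seed RNG seed
#' @return list with `full`, `targeted` (named metric vectors) and
#'   `shuffle` (data frame, one row per shuffle)
#' @export
removal_shuffle <- function(tensor, remove_ids, trial_filter = NULL,
                            n_shuffles = 30L, seed = 1L) {
  n_cells <- dim(tensor)[2]
  remove_ids <- unique(remove_ids)
  if (length(remove_ids) >= n_cells)
    stop("removal would empty the graph", call. = FALSE)
  local_seed(seed)
  metrics_without <- function(ids) {
    keep <- setdiff(seq_len(n_cells), ids)
    sub <- tensor[, keep, , drop = FALSE]
    attributes(sub)[c("class", "window", "baseline", "frame_rate")] <-
      attributes(tensor)[c("class", "window", "baseline", "frame_rate")]
    g <- build_coactivity_graph(sub, trial_filter)
    c(hubness = hubness(g)$mean,
      path_length = shortest_paths_graph(g)$mean,
      clustering = clustering_coefficient(g)$mean)
  }
  full <- metrics_without(integer(0))
  targeted <- metrics_without(remove_ids)
  shuffle <- t(vapply(seq_len(n_shuffles), function(s)
    metrics_without(sample.int(n_cells, length(remove_ids))),
    numeric(3)))
  list(full = full, targeted = targeted,
       shuffle = as.data.frame(shuffle))
}
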