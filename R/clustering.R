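#' Build concatenated trial-averaged feature rows for functional clustering
#'
#' Each cell contributes one row: its trial-averaged stimulus + delay trace
#' in each phase, concatenated in the given phase order (e.g. naive then
#' expert). Initial and reversal learning are treated as independent
#' observations, i.e. stacked as separate rows by the caller.
#'
#' @param phase_traces named list (in concatenation order) of
#'   cells x frames trial-averaged matrices with identical row sets
#' @return cells x (sum of frames) matrix with attribute `segments`
#'   (named per-phase column counts)
#' @export
build_features <- function(phase_traces) {
  stopifnot(is.list(phase_traces), length(phase_traces) >= 1)
  nr <- vapply(phase_traces, nrow, integer(1))
  if (length(unique(nr)) != 1)
    stop("all phases must cover the same matched cells", call. = FALSE)
  drop_rows <- Reduce(`|`, lapply(phase_traces,
                                  function(m) rowSums(!is.finite(m)) > 0))
  if (any(drop_rows))
    message(sum(drop_rows), " cell(s) dropped: missing phase data")
  out <- do.call(cbind, lapply(phase_traces,
                               function(m) m[!drop_rows, , drop = FALSE]))
  attr(out, "segments") <- vapply(phase_traces, ncol, integer(1))
  attr(out, "kept") <- which(!drop_rows)
  out
}

# Spherical (cosine-distance) k-means via Lloyd iterations on unit-norm
# rows; empty clusters are re-seeded from the point farthest from its
# centroid. Returns assignments, unit centroids and total cosine inertia.
spherical_kmeans_once <- function(xn, k, max_iter = 100L) {
  n <- nrow(xn)
  cent <- xn[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    sim <- xn %*% t(cent)
    assign_new <- max.col(sim, ties.method = "first")
    empties <- which(tabulate(assign_new, k) == 0L)
    if (length(empties) > 0) {
      # re-seed each empty cluster from a distinct farthest point
      far <- order(sim[cbind(seq_len(n), assign_new)])
      for (e in seq_along(empties)) assign_new[far[e]] <- empties[e]
    }
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      members <- assign_new == j
      if (!any(members)) next   # keep previous centroid
      mu <- colMeans(xn[members, , drop = FALSE])
      nrm <- sqrt(sum(mu^2))
      if (nrm > 0) cent[j, ] <- mu / nrm
    }
  }
  inertia <- sum(1 - sim[cbind(seq_len(n), assign_old)])
  list(assignments = assign_old, centroids = cent, inertia = inertia)
}

#' PCA + cosine k-means functional clustering
#'
#' Projects feature rows onto the principal components explaining at least
#' `var_explained` of the variance, then runs k-means with cosine distance
#' (spherical k-means) with multiple restarts, keeping the solution with
#' the lowest cosine inertia. Deterministic given `seed`.
#'
#' @param features cells x time feature matrix from [build_features()]
#' @param k number of clusters (default 30)
#' @param seed RNG seed
#' @param n_restarts restarts; the best-inertia run is kept
#' @param var_explained PCA variance fraction to retain
#' @return a `cluster_model`: list with `assignments`, `centroid_traces`
#'   (cluster means in the original feature space), `inertia`, `k`,
#'   `n_pcs`, `features`
#' @export
cluster_cells <- function(features, k = 30L, seed = 1L, n_restarts = 20L,
                          var_explained = 0.90) {
  x <- as.matrix(features)
  if (nrow(x) < k)
    stop("need at least k rows to form k clusters", call. = FALSE)
  local_seed(seed)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pcs <- min(which(cum >= var_explained), nrow(x) - 1L)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  nrm <- sqrt(rowSums(scores^2))
  nrm[nrm == 0] <- 1
  xn <- scores / nrm
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- spherical_kmeans_once(xn, k)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  centroid_traces <- t(vapply(seq_len(k), function(j)
    colMeans(x[best$assignments == j, , drop = FALSE]),
    numeric(ncol(x))))
  structure(list(assignments = best$assignments,
                 centroid_traces = centroid_traces,
                 inertia = best$inertia, k = k, n_pcs = n_pcs,
                 features = x,
                 segments = attr(features, "segments")),
            class = "cluster_model")
}

#' Merge similar clusters and assign semantic labels
#'
#' Automated surrogate for by-eye merging of similar activity patterns:
#' average-linkage agglomeration of cluster centroid traces by Pearson
#' correlation, merging while the maximum inter-group linkage exceeds
#' `threshold`. Merged clusters are then labelled by their best-matching
#' activity template (minimum correlation 0.5, otherwise `other`):
#' delay-period ramps (`ramp_up`, `ramp_down`) and stimulus-window boxcars
#' (`stimulus`).
#'
#' @param model a `cluster_model`
#' @param threshold centroid correlation above which groups merge
#' @param stim_frames,delay_frames frames of the stimulus and delay windows
#'   within each concatenated phase segment; defaults assume each segment
#'   is an equal split of stimulus then delay
#' @return the model with `merged` (per-cell merged-cluster id),
#'   `merged_labels` (semantic label per merged cluster) and
#'   `merged_centroids` added
#' @export
merge_clusters <- function(model, threshold = 0.8, stim_frames = NULL,
                           delay_frames = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  cent <- model$centroid_traces
  occupied <- which(rowSums(!is.nan(cent)) > 0 &
                      apply(cent, 1, function(r) stats::sd(r) > 0))
  groups <- as.list(occupied)
  link <- function(g1, g2) {
    cc <- stats::cor(t(cent[g1, , drop = FALSE]) ,
                     t(cent[g2, , drop = FALSE]))
    mean(cc)
  }
  repeat {
    if (length(groups) < 2) break
    best <- c(NA, NA); best_r <- -Inf
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      r <- link(groups[[a]], groups[[b]])
      if (r > best_r) { best_r <- r; best <- c(a, b) }
    }
    if (best_r <= threshold) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  merged_of_raw <- integer(model$k)
  for (g in seq_along(groups)) merged_of_raw[groups[[g]]] <- g
  merged <- merged_of_raw[model$assignments]
  merged_centroids <- t(vapply(seq_along(groups), function(g)
    colMeans(model$features[merged == g, , drop = FALSE]),
    numeric(ncol(model$features))))

  templates <- cluster_templates(ncol(model$features), model$segments,
                                 stim_frames, delay_frames)
  merged_labels <- vapply(seq_along(groups), function(g) {
    rs <- vapply(templates, function(tp)
      suppressWarnings(stats::cor(merged_centroids[g, ], tp)), numeric(1))
    rs[is.na(rs)] <- -Inf
    if (max(rs) >= 0.5) names(templates)[which.max(rs)] else "other"
  }, character(1))

  model$merged <- merged
  model$merged_labels <- merged_labels
  model$merged_centroids <- merged_centroids
  model
}

# Activity templates on the concatenated feature layout. Each phase segment
# is assumed to be stimulus frames followed by delay frames.
cluster_templates <- function(n_cols, segments, stim_frames = NULL,
                              delay_frames = NULL) {
  if (is.null(segments)) segments <- n_cols
  starts <- cumsum(c(0, segments[-length(segments)]))
  make <- function(seg_fun) {
    tp <- numeric(n_cols)
    for (s in seq_along(segments)) {
      len <- segments[s]
      sf <- if (is.null(stim_frames)) len %/% 2 else stim_frames
      df <- if (is.null(delay_frames)) len - sf else delay_frames
      tp[starts[s] + seq_len(len)] <- seg_fun(sf, df, s, length(segments))
    }
    tp
  }
  list(
    ramp_up = make(function(sf, df, s, np) c(rep(0, sf),
                                             seq(0, 1, length.out = df))),
    ramp_down = make(function(sf, df, s, np) c(rep(0, sf),
                                               seq(1, 0, length.out = df))),
    stimulus = make(function(sf, df, s, np) c(rep(1, sf), rep(0, df))),
    stimulus_enhanced = make(function(sf, df, s, np)
      c(rep(if (s == np) 1 else 0.2, sf), rep(0, df))),
    stimulus_inhibited = make(function(sf, df, s, np)
      c(rep(if (s == 1) 1 else 0.2, sf), rep(0, df)))
  )
}

#' Cells belonging to ramp-labelled merged clusters
#'
#' @param model a merged `cluster_model`
#' @return integer vector of cell row indices in ramp-up or ramp-down
#'   clusters (empty if none)
#' @export
ramp_cell_ids <- function(model) {
  if (is.null(model$merged))
    stop("run merge_clusters() first", call. = FALSE)
  ramp_groups <- which(model$merged_labels %in% c("ramp_up", "ramp_down"))
  which(model$merged %in% ramp_groups)
}
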