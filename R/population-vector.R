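#' Build per-trial population vectors and their correlation matrix
#'
#' Each trial contributes a vector of per-cell mean responses over one
#' epoch (stimulus or delay), computed from a trial tensor baselined to the
#' 2 s pre-stimulus period. The trial-by-trial Pearson correlation matrix
#' (PVC) summarises the coherence of the population representation across
#' trials. Cells with missing epoch data are dropped and counted; trial
#' pairs whose correlation is undefined (a trial vector constant across
#' cells) are excluded from the session mean.
#'
#' @param tensor a `trial_tensor` with baseline tag `pre-stim-2s`
#' @param trial_filter logical or integer trial selector (default all)
#' @return a `population_vector_set`: list with `vectors`
#'   (trials x cells), `pvc` (trials x trials, NA where undefined),
#'   `n_dropped_cells`
#' @export
build_population_vectors <- function(tensor, trial_filter = NULL) {
  require_baseline(tensor, "pre-stim-2s")
  if (is.null(trial_filter)) trial_filter <- seq_len(dim(tensor)[1])
  if (is.logical(trial_filter)) trial_filter <- which(trial_filter)
  if (length(trial_filter) < 2)
    stop("fewer than 2 trials after filtering", call. = FALSE)
  v <- trial_means(tensor, trial_filter)   # trials x cells
  keep <- colSums(is.na(v)) == 0
  v <- v[, keep, drop = FALSE]
  if (ncol(v) < 2)
    stop("fewer than 2 usable cells for population vectors", call. = FALSE)
  pvc <- suppressWarnings(stats::cor(t(v)))
  structure(list(vectors = v, pvc = pvc,
                 n_dropped_cells = sum(!keep),
                 trial_filter = trial_filter),
            class = "population_vector_set")
}

#' Session-level mean population-vector correlation
#'
#' Mean of the strictly-upper-triangle entries of the trial-by-trial PVC
#' matrix (all trial pairs, diagonal excluded).
#'
#' @param set a `population_vector_set` (or a bare correlation matrix)
#' @return numeric scalar
#' @export
session_mean_pvc <- function(set) {
  m <- if (inherits(set, "population_vector_set")) set$pvc else set
  mean(m[upper.tri(m)], na.rm = TRUE)
}

#' Compare session-mean PVC between learning phases with a mixed model
#'
#' Random-intercept linear mixed model, `value ~ phase + (1 | mouse)`,
#' fitted by REML with Satterthwaite degrees of freedom for the phase
#' effect. If the mixed fit fails, falls back to ordinary least squares
#' and flags the result.
#'
#' @param values per-session mean PVC values
#' @param phase factor/character phase per session (e.g. naive/expert);
#'   the effect reported is the second level relative to the first
#' @param mouse mouse id per session
#' @return list with `estimate`, `se`, `p`, `model` (`"lmm"` or `"ols"`)
#' @export
compare_phases_lmm <- function(values, phase, mouse) {
  df <- data.frame(value = values, phase = factor(phase),
                   mouse = factor(mouse))
  if (nlevels(df$phase) != 2)
    stop("exactly two phases required", call. = FALSE)
  if (nlevels(df$mouse) < 2)
    stop("at least two mice required", call. = FALSE)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ phase + (1 | mouse), data = df, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(summary(fit))
    row <- grep("^phase", rownames(co))[1]
    return(list(estimate = co[row, "Estimate"],
                se = co[row, "Std. Error"],
                p = co[row, "Pr(>|t|)"], model = "lmm"))
  }
  ols <- stats::lm(value ~ phase, data = df)
  co <- stats::coef(suppressWarnings(summary(ols)))
  row <- grep("^phase", rownames(co))[1]
  list(estimate = co[row, "Estimate"], se = co[row, "Std. Error"],
       p = co[row, "Pr(>|t|)"], model = "ols")
}

#' Stratify Hit trials by anticipatory licking
#'
#' Splits a session's Hit trials into those with and without anticipatory
#' (delay-period) licks. Sessions contribute only if both strata have more
#' than `min_trials` trials.
#'
#' @param tensor a `trial_tensor` baselined to `pre-stim-2s`
#' @param hit_idx Hit-trial indices into the tensor's trial dimension
#' @param antic_counts anticipatory lick counts for those trials
#' @param min_trials strict minimum per stratum (default 6: more than 6
#'   trials of each kind are required)
#' @return list with `with` and `without` population-vector sets, or
#'   `NULL` (with a message) if the session fails the inclusion rule
#' @export
stratify_by_anticipatory_licking <- function(tensor, hit_idx, antic_counts,
                                             min_trials = 6L) {
  stopifnot(length(hit_idx) == length(antic_counts))
  with_idx <- hit_idx[antic_counts > 0]
  without_idx <- hit_idx[antic_counts == 0]
  if (length(with_idx) <= min_trials || length(without_idx) <= min_trials) {
    message("session excluded: needs more than ", min_trials,
            " trials with and without anticipatory licking")
    return(NULL)
  }
  list(with = build_population_vectors(tensor, with_idx),
       without = build_population_vectors(tensor, without_idx))
}

#' Targeted cell-removal control with random-removal shuffles
#'
#' Recomputes the session-mean PVC after removing a target cell set (e.g.
#' ramp-up and ramp-down cells) and after `n_shuffles` random removals of
#' the same number of cells, giving a null distribution for the targeted
#' effect.
#'
#' @param tensor a `trial_tensor` baselined to `pre-stim-2s`
#' @param remove_ids cell indices to remove (may be empty)
#' @param trial_filter trial selector passed to
#'   [build_population_vectors()]
#' @param n_shuffles number of random same-size removals (default 30)
#' @param seed RNG seed
#' @return list with `full`, `targeted` (mean PVC after targeted removal)
#'   and `shuffle` (vector of mean PVCs under random removal)
#' @export
remove_cells_control <- function(tensor, remove_ids, trial_filter = NULL,
                                 n_shuffles = 30L, seed = 1L) {
  n_cells <- dim(tensor)[2]
  remove_ids <- unique(remove_ids)
  if (length(remove_ids) >= n_cells)
    stop("removal would empty the population", call. = FALSE)
  local_seed(seed)
  mean_without <- function(ids) {
    keep <- setdiff(seq_len(n_cells), ids)
    sub <- tensor[, keep, , drop = FALSE]
    attributes(sub)[c("class", "window", "baseline", "frame_rate")] <-
      attributes(tensor)[c("class", "window", "baseline", "frame_rate")]
    session_mean_pvc(build_population_vectors(sub, trial_filter))
  }
  full <- mean_without(integer(0))
  targeted <- mean_without(remove_ids)
  shuffle <- vapply(seq_len(n_shuffles), function(s)
    mean_without(sample.int(n_cells, length(remove_ids))), numeric(1))
  list(full = full, targeted = targeted, shuffle = shuffle)
}
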