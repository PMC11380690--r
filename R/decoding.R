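#' Build decoder features from the stimulus period
#'
#' Down-samples each trial's stimulus-window time series to 3 Hz by bin
#' averaging (a 2 s window gives 6 bins) and keeps the trials x cells x
#' bins structure needed by the circular-permutation null; the flattened
#' trials x (cells * bins) view is what the decoder consumes.
#'
#' @param tensor a `trial_tensor` over the stimulus window, baselined to
#'   the 1 s pre-stimulus period (`pre-stim-1s`)
#' @param target_hz decoder sampling rate (default 3 Hz, guards against
#'   overfitting)
#' @return a `decoder_features` array `[trials, cells, bins]`
#' @export
build_decoder_features <- function(tensor, target_hz = 3) {
  require_baseline(tensor, "pre-stim-1s")
  fr <- attr(tensor, "frame_rate")
  factor <- fr / target_hz
  if (abs(factor - round(factor)) > 1e-6)
    stop("frame rate must be an integer multiple of target_hz",
         call. = FALSE)
  factor <- as.integer(round(factor))
  n_bins <- dim(tensor)[3] %/% factor
  dims <- dim(tensor)
  out <- array(NA_real_, c(dims[1], dims[2], n_bins))
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1L) * factor + 1L):(b * factor)
    out[, , b] <- apply(tensor[, , idx, drop = FALSE], c(1, 2), mean)
  }
  structure(out, class = "decoder_features", target_hz = target_hz)
}

flatten_features <- function(features) {
  d <- dim(features)
  matrix(features, d[1], d[2] * d[3])
}

#' Balanced train/test split for decoding
#'
#' Modality decoding equalises class sizes to the smallest class before
#' splitting (test size per class = `floor(smallest * (1 - train_frac))`,
#' so the standard mapping session gives a 27-trial test set); frequency
#' decoding uses all frequency-labelled trials with a plain 70/30 split
#' (140 train / 60 test on a standard session).
#'
#' @param labels class label per trial
#' @param task `"modality"` (balanced subsampling) or `"frequency"`
#'   (plain split)
#' @param train_frac training fraction (default 0.7)
#' @param seed RNG seed; omit to draw from the current RNG state
#' @return list with `train` and `test` trial indices
#' @export
balanced_split <- function(labels, task = c("modality", "frequency"),
                           train_frac = 0.7, seed = NULL) {
  task <- match.arg(task)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (min(table(labels)) < 4)
    stop("every class needs at least 4 trials", call. = FALSE)
  if (!is.null(seed)) local_seed(seed)
  if (task == "modality") {
    n_min <- min(table(labels))
    n_test <- floor(n_min * (1 - train_frac))
    n_train <- n_min - n_test
    train <- integer(0); test <- integer(0)
    for (cl in classes) {
      ids <- sample(which(labels == cl), n_min)
      train <- c(train, ids[seq_len(n_train)])
      test <- c(test, ids[(n_train + 1):n_min])
    }
  } else {
    n <- length(labels)
    n_test <- floor(n * (1 - train_frac))
    ids <- sample.int(n)
    test <- ids[seq_len(n_test)]
    train <- ids[(n_test + 1):n]
  }
  list(train = sort(train), test = sort(test))
}

# Standardize on the training fold only, fit a linear SVM (C = 1,
# one-vs-rest handled by e1071's multiclass machinery), return test accuracy.
svm_accuracy <- function(x_train, y_train, x_test, y_test, cost = 1) {
  mu <- colMeans(x_train)
  sds <- apply(x_train, 2, stats::sd)
  sds[sds == 0] <- 1
  x_train <- sweep(sweep(x_train, 2, mu), 2, sds, "/")
  x_test <- sweep(sweep(x_test, 2, mu), 2, sds, "/")
  fit <- e1071::svm(x_train, factor(y_train), kernel = "linear",
                    cost = cost, scale = FALSE, type = "C-classification")
  pred <- stats::predict(fit, x_test)
  mean(as.character(pred) == as.character(y_test))
}

#' Train and evaluate a linear SVM decoder over resampled splits
#'
#' Fits a linear SVM (cost 1, features standardised on the training fold
#' only) on `n_iter` independent balanced splits and averages the simple
#' test accuracy.
#'
#' @param features a `decoder_features` array or a trials x features matrix
#' @param labels class label per trial
#' @param task split scheme, see [balanced_split()]
#' @param n_iter resampled train/test iterations (default 50)
#' @param seed RNG seed
#' @param cost SVM regularisation parameter
#' @return list with `mean_accuracy` and `accuracies` (per iteration)
#' @export
train_eval <- function(features, labels, task = "modality", n_iter = 50L,
                       seed = 1L, cost = 1) {
  x <- if (length(dim(features)) == 3) flatten_features(features)
       else as.matrix(features)
  local_seed(seed)
  acc <- vapply(seq_len(n_iter), function(it) {
    sp <- balanced_split(labels, task)
    svm_accuracy(x[sp$train, , drop = FALSE], labels[sp$train],
                 x[sp$test, , drop = FALSE], labels[sp$test], cost = cost)
  }, numeric(1))
  list(mean_accuracy = mean(acc), accuracies = acc)
}

# Rotate each trial's time bins by a per-trial random offset, coherently
# across cells (preserves within-trial cross-cell structure).
rotate_trials <- function(features, offsets) {
  d <- dim(features)
  out <- features
  for (t in seq_len(d[1])) {
    k <- offsets[t] %% d[3]
    if (k > 0)
      out[t, , ] <- features[t, , c((d[3] - k + 1):d[3], seq_len(d[3] - k))]
  }
  out
}

#' Circular-permutation chance accuracy
#'
#' Estimates the chance level of a decoder by circular permutation of the
#' down-sampled time-series features, retraining the decoder for every
#' permutation within each of `n_iter` train/test iterations.
#'
#' Two permutation units are available. `"trials"` (the default used for
#' chance estimation) circularly shifts the session's trial sequence
#' relative to the labels, which breaks the feature-label correspondence
#' while preserving the session's temporal structure, so the expected
#' accuracy is the class-frequency chance level. `"bins"` rotates each
#' trial's time bins by a random per-trial offset (coherently across
#' cells): this destroys temporal coding within the trial but leaves
#' time-invariant population patterns decodable, so it tests specifically
#' whether information is carried by response timing.
#'
#' @param features a `decoder_features` array (time-bin structure
#'   required)
#' @param labels class label per trial
#' @param task split scheme
#' @param n_shuffle permutations per iteration (default 100)
#' @param n_iter train/test iterations (default 50)
#' @param unit permutation unit, `"trials"` or `"bins"`
#' @param seed RNG seed
#' @param cost SVM regularisation parameter
#' @return list with `mean_accuracy` (the chance estimate) and
#'   `accuracies` (`n_iter` x `n_shuffle`)
#' @export
circular_shuffle_null <- function(features, labels, task = "modality",
                                  n_shuffle = 100L, n_iter = 50L,
                                  unit = c("trials", "bins"),
                                  seed = 1L, cost = 1) {
  stopifnot(length(dim(features)) == 3)
  unit <- match.arg(unit)
  d <- dim(features)
  local_seed(seed)
  acc <- matrix(NA_real_, n_iter, n_shuffle)
  for (it in seq_len(n_iter)) {
    sp <- balanced_split(labels, task)
    for (s in seq_len(n_shuffle)) {
      if (unit == "trials") {
        off <- sample.int(d[1] - 1L, 1L)
        lab_s <- labels[((seq_len(d[1]) - 1L + off) %% d[1]) + 1L]
        x <- flatten_features(features)
      } else {
        lab_s <- labels
        rot <- rotate_trials(features, sample.int(d[3], d[1],
                                                  replace = TRUE))
        x <- flatten_features(rot)
      }
      acc[it, s] <- svm_accuracy(x[sp$train, , drop = FALSE],
                                 lab_s[sp$train],
                                 x[sp$test, , drop = FALSE],
                                 lab_s[sp$test], cost = cost)
    }
  }
  list(mean_accuracy = mean(acc), accuracies = acc)
}

#' Pairwise cross-session decoding matrix
#'
#' Trains a decoder on each session and tests it on every session: entry
#' (a, b) is the accuracy of the session-a decoder on session b's trials
#' (held-out trials when a = b). Feature spaces must already be aligned to
#' the same tracked cells in the same order.
#'
#' @param feature_list list of `decoder_features` arrays, one per session
#' @param label_list matching list of per-trial labels
#' @param task split scheme
#' @param n_iter iterations per matrix entry
#' @param seed RNG seed
#' @param cost SVM regularisation parameter
#' @return sessions x sessions accuracy matrix
#' @export
pairwise_session_matrix <- function(feature_list, label_list,
                                    task = "modality", n_iter = 10L,
                                    seed = 1L, cost = 1) {
  n_s <- length(feature_list)
  stopifnot(length(label_list) == n_s)
  n_feat <- vapply(feature_list, function(f) prod(dim(f)[2:3]), numeric(1))
  if (length(unique(n_feat)) != 1)
    stop("sessions have unaligned feature spaces", call. = FALSE)
  local_seed(seed)
  acc <- matrix(NA_real_, n_s, n_s)
  for (a in seq_len(n_s)) {
    xa <- flatten_features(feature_list[[a]])
    for (it in seq_len(n_iter)) {
      sp <- balanced_split(label_list[[a]], task)
      for (b in seq_len(n_s)) {
        xb <- flatten_features(feature_list[[b]])
        ab <- if (a == b)
          svm_accuracy(xa[sp$train, , drop = FALSE],
                       label_list[[a]][sp$train],
                       xa[sp$test, , drop = FALSE],
                       label_list[[a]][sp$test], cost = cost)
        else
          svm_accuracy(xa[sp$train, , drop = FALSE],
                       label_list[[a]][sp$train],
                       xb, label_list[[b]], cost = cost)
        acc[a, b] <- if (it == 1) ab else acc[a, b] + ab
      }
    }
    acc[a, ] <- acc[a, ] / n_iter
  }
  acc
}
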