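make_decoder_fixture <- function(n_per_class = 20, n_cells = 10,
                                 n_bins = 6, classes = c("a", "b", "c"),
                                 noise = 0.05, signal_bins = seq_len(6),
                                 seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  arr <- array(rnorm(n * n_cells * n_bins, sd = noise),
               c(n, n_cells, n_bins))
  for (k in seq_along(classes)) {
    pattern <- rnorm(n_cells)
    rows <- which(labels == classes[k])
    for (b in signal_bins) {
      arr[rows, , b] <- arr[rows, , b] + rep(pattern, each = length(rows))
    }
  }
  structure(arr, class = "decoder_features", target_hz = 3,
            labels = labels)
}

test_that("decoder features flatten cells by 3 Hz time bins", {
  arr <- array(rnorm(8 * 50 * 60), c(8, 50, 60))
  ten <- structure(arr, class = "trial_tensor", window = "stimulus",
                   baseline = "pre-stim-1s", frame_rate = 30)
  feats <- build_decoder_features(ten)
  expect_equal(dim(feats), c(8, 50, 6))
  expect_equal(dim(thalpop:::flatten_features(feats)), c(8, 300))
  # constant traces give all-equal bins
  ten0 <- structure(array(3, c(4, 2, 60)), class = "trial_tensor",
                    window = "stimulus", baseline = "pre-stim-1s",
                    frame_rate = 30)
  expect_true(all(build_decoder_features(ten0) == 3))
})

test_that("balanced modality split reproduces the 27-trial test set", {
  labels <- rep(c("multisensory", "auditory", "visual"), c(160, 40, 32))
  sp <- balanced_split(labels, "modality", seed = 4)
  expect_length(sp$test, 27)           # 3 classes x floor(32 * 0.3)
  expect_length(sp$train, 69)          # 3 x (32 - 9)
  expect_true(all(table(labels[sp$test]) == 9))
  expect_true(all(table(labels[sp$train]) == 23))
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("frequency split keeps all 200 trials at 70/30", {
  labels <- rep(c(4, 8, 12, 16, 20), each = 40)
  sp <- balanced_split(labels, "frequency", seed = 2)
  expect_length(sp$train, 140)
  expect_length(sp$test, 60)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(balanced_split(rep("x", 10), "modality"), "2 classes")
})

test_that("separable classes decode nearly perfectly, shuffles at chance", {
  feats <- make_decoder_fixture()
  labels <- attr(feats, "labels")
  res <- train_eval(feats, labels, task = "modality", n_iter = 10,
                    seed = 3)
  expect_gte(res$mean_accuracy, 0.95)
  # label shuffling collapses accuracy to chance
  set.seed(5)
  shuffled <- sample(labels)
  res_null <- train_eval(feats, shuffled, task = "modality", n_iter = 10,
                         seed = 3)
  se <- sd(res_null$accuracies) / sqrt(length(res_null$accuracies))
  expect_lt(abs(res_null$mean_accuracy - 1 / 3), 3 * max(se, 0.04))
  # seeded reproducibility
  res2 <- train_eval(feats, labels, task = "modality", n_iter = 10,
                     seed = 3)
  expect_identical(res$accuracies, res2$accuracies)
})

test_that("circular rotation preserves per-trial values; zero offset is identity", {
  feats <- make_decoder_fixture(n_per_class = 5)
  rot0 <- thalpop:::rotate_trials(feats, rep(0L, dim(feats)[1]))
  expect_equal(rot0, feats, ignore_attr = TRUE)
  rot <- thalpop:::rotate_trials(feats, sample.int(6, dim(feats)[1],
                                                   replace = TRUE))
  for (t in 1:3) {
    expect_equal(sort(as.numeric(rot[t, , ])),
                 sort(as.numeric(feats[t, , ])))
  }
})

test_that("temporally coded signals fall to chance under circular rotation", {
  # classes share one population pattern and differ only in its timing
  # (bins 1 / 3 / 5); rotation erases exactly that temporal code
  set.seed(7)
  n_per <- 15; n_cells <- 10; n_bins <- 6
  labels <- rep(c("a", "b", "c"), each = n_per)
  pattern <- rnorm(n_cells)
  arr <- array(rnorm(45 * n_cells * n_bins, sd = 0.2),
               c(45, n_cells, n_bins))
  bin_of <- c(a = 1, b = 3, c = 5)
  for (t in seq_len(45)) {
    arr[t, , bin_of[labels[t]]] <- arr[t, , bin_of[labels[t]]] + pattern
  }
  feats <- structure(arr, class = "decoder_features", target_hz = 3)
  real <- train_eval(feats, labels, task = "modality", n_iter = 8,
                     seed = 1)
  null <- circular_shuffle_null(feats, labels, task = "modality",
                                n_shuffle = 10, n_iter = 4,
                                unit = "bins", seed = 1)
  expect_gte(real$mean_accuracy, 0.95)
  expect_gt(real$mean_accuracy - null$mean_accuracy, 0.2)
  expect_lt(abs(null$mean_accuracy - 1 / 3), 0.15)
})

test_that("trial-sequence permutation estimates class-frequency chance", {
  feats <- make_decoder_fixture(n_per_class = 15, seed = 3)
  labels <- attr(feats, "labels")
  # scramble the block structure so circular shifts decouple labels
  set.seed(11)
  ord <- sample(seq_along(labels))
  feats <- structure(feats[ord, , ], class = "decoder_features",
                     target_hz = 3)
  labels <- labels[ord]
  null <- circular_shuffle_null(feats, labels, task = "modality",
                                n_shuffle = 10, n_iter = 4,
                                unit = "trials", seed = 2)
  expect_lt(abs(null$mean_accuracy - 1 / 3), 0.12)
  real <- train_eval(feats, labels, task = "modality", n_iter = 6, seed = 2)
  expect_gt(real$mean_accuracy - null$mean_accuracy, 0.4)
})

test_that("pairwise session matrices have the right shape and diagonal", {
  sessions <- lapply(1:3, function(s)
    make_decoder_fixture(n_per_class = 15, seed = 100))  # identical tuning
  labels <- lapply(sessions, attr, "labels")
  acc <- pairwise_session_matrix(sessions, labels, task = "modality",
                                 n_iter = 3, seed = 2)
  expect_equal(dim(acc), c(3, 3))
  expect_true(all(acc > 0.9))   # stable tuning decodes across sessions
  bad <- sessions
  bad[[2]] <- bad[[2]][, 1:5, ]
  expect_error(pairwise_session_matrix(bad, labels), "unaligned")
})
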