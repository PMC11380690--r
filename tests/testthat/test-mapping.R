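test_that("the stimulus catalog enumerates 29 types with the right mix", {
  cat <- mapping_catalog()
  expect_equal(nrow(cat), 29)
  expect_equal(sum(cat$modality == "auditory"), 5)
  expect_equal(sum(cat$modality == "visual"), 4)
  expect_equal(sum(cat$modality == "multisensory"), 20)
})

test_that("mapping sessions repeat each stimulus 8 times in random order", {
  cfg <- sim_config(n_cells = 10L)
  s <- generate_mapping_session(cfg, seed = 5)
  tr <- s$trials
  expect_equal(nrow(tr), 232)
  expect_equal(sum(tr$modality == "auditory"), 40)
  expect_equal(sum(tr$modality == "visual"), 32)
  expect_equal(sum(tr$modality == "multisensory"), 160)
  key <- paste(tr$modality, tr$frequency_khz, tr$direction)
  expect_true(all(table(key) == 8))
  # seed reproducibility: identical trial order
  s2 <- generate_mapping_session(cfg, seed = 5)
  expect_identical(s2$trials$modality, tr$modality)
  expect_identical(s2$trials$onset_frame, tr$onset_frame)
})

test_that("split-half responsiveness doubles the data points", {
  # 8 trials, sustained +1 z response -> 16 points at +1 -> excited
  arr <- array(1, c(8, 3, 60))
  arr[, 2, ] <- 0                      # silent cell
  arr[, 3, 1:30] <- 0                  # responds in the second half only
  ten <- structure(arr, class = "trial_tensor", window = "stimulus",
                   baseline = "pre-stim-0.5s", frame_rate = 30)
  calls <- split_half_responsiveness(ten)
  expect_equal(calls[[1]]$call, "excited")
  expect_equal(calls[[2]]$call, "nonresponsive")
  # half the points at +1 still reaches significance at 8 trials
  expect_equal(calls[[3]]$call, "excited")
  # signed-rank enumeration oracle for the constructed point set
  pts <- c(rep(0, 8), rep(1, 8))
  expect_equal(signed_rank_test(pts)$p, oracle_signed_rank_p(pts),
               tolerance = 1e-12)
})

test_that("tuning matrices are laid out pre/post x multi/uni by frequency", {
  freqs <- c(4, 8, 12, 16, 20)
  grid <- expand.grid(cell = 1:6, frequency_khz = freqs,
                      context = c("uni", "multi"), phase = c("pre", "post"),
                      stringsAsFactors = FALSE)
  grid$response <- ifelse(grid$cell <= 3,
                          exp(-(grid$frequency_khz - 8)^2 / 32),
                          exp(-(grid$frequency_khz - 16)^2 / 32)) +
    ifelse(grid$context == "multi", 0.2, 0)
  tm <- tuning_matrix(grid, cluster = FALSE)
  expect_equal(dim(tm$matrix), c(6, 20))
  # block order: pre-multi, post-multi, pre-uni, post-uni
  r1 <- grid$response[grid$cell == 1 & grid$context == "multi" &
                        grid$phase == "pre"]
  expect_equal(unname(tm$matrix[1, 1:5]), r1)
  r1u <- grid$response[grid$cell == 1 & grid$context == "uni" &
                         grid$phase == "post"]
  expect_equal(unname(tm$matrix[1, 16:20]), r1u)
  # stable pre/post tuning gives equal blocks
  expect_equal(tm$matrix[, 1:5], tm$matrix[, 6:10])
})

test_that("two planted tuning motifs are recovered by clustering", {
  set.seed(17)
  freqs <- c(4, 8, 12, 16, 20)
  rows <- list()
  for (cell in 1:40) {
    pref <- if (cell <= 20) 8 else 16
    for (ph in c("pre", "post")) for (ctx in c("uni", "multi")) {
      rows[[length(rows) + 1]] <- data.frame(
        cell = cell, frequency_khz = freqs, context = ctx, phase = ph,
        response = exp(-(freqs - pref)^2 / 20) + rnorm(5, sd = 0.05))
    }
  }
  tm <- tuning_matrix(do.call(rbind, rows), k = 2, seed = 3)
  truth <- rep(1:2, each = 20)
  expect_gte(oracle_ari(tm$assignments, truth), 0.9)
})

test_that("tuning stability is signed correlation of pre/post curves", {
  m <- matrix(0, 2, 20)
  curve <- c(0.1, 0.5, 1, 0.5, 0.1)
  m[1, ] <- c(curve, curve, curve, curve)              # identical
  m[2, ] <- c(curve, -curve + 1.2, curve, rev(curve))  # inverted post
  st <- tuning_stability(m)
  expect_equal(st$r_multi[1], 1)
  expect_equal(st$r_uni[1], 1)
  expect_equal(st$r_multi[2], -1)
  # random 5-point curves give a stability distribution centred on zero
  set.seed(18)
  mm <- matrix(rnorm(1000 * 20), 1000)
  st2 <- tuning_stability(mm)
  expect_lt(abs(mean(st2$r_uni)), 0.05)
  expect_lt(abs(median(st2$r_multi)), 0.07)
})

test_that("multisensory index implements linearity and exclusions", {
  # linear integration
  expect_equal(multisensory_index(1, 1, 2)$index, 1)
  # supralinear
  expect_equal(multisensory_index(1, 1, 3)$index, 1.5)
  # sign conflict
  sc <- multisensory_index(0.6, 0.4, -1)
  expect_true(is.na(sc$index))
  expect_equal(sc$exclusion_reason, "sign-conflict")
  # both nonsignificant
  ns <- multisensory_index(1, 1, 2, sig_A = FALSE, sig_AV = FALSE)
  expect_equal(ns$exclusion_reason, "both-nonsignificant")
  # zero denominator
  zd <- multisensory_index(1, -1, 0)
  expect_equal(zd$exclusion_reason, "zero-denominator")
  # scale invariance
  for (c_scale in c(0.5, 2, 10)) {
    expect_equal(multisensory_index(c_scale * 1, c_scale * 1,
                                    c_scale * 3)$index, 1.5)
  }
})

test_that("planted supralinear gain appears in the noiseless index", {
  cfg <- sim_config(n_cells = 4L, multisensory_gain = 2, noise_sd = 1)
  s <- generate_mapping_session(cfg, seed = 2, keep_signal = TRUE)
  tr <- s$trials
  fr <- cfg$frame_rate_hz
  stim_mean <- function(i, cell) {
    o <- tr$onset_frame[i]
    mean(s$truth$signal[cell, (o + 1):(o + 60)])
  }
  cell <- 1
  pref <- s$truth$tuning$pref_freq_idx[cell]
  f <- c(4, 8, 12, 16, 20)[pref]
  a_tr <- which(tr$modality == "auditory" & tr$frequency_khz == f)
  v_tr <- which(tr$modality == "visual")
  av_tr <- which(tr$modality == "multisensory" & tr$frequency_khz == f)
  A <- mean(sapply(a_tr, stim_mean, cell = cell))
  V <- mean(sapply(v_tr, stim_mean, cell = cell))
  AV <- mean(sapply(av_tr, stim_mean, cell = cell))
  idx <- multisensory_index(A, V, AV)$index
  # tolerance covers the per-transient amplitude jitter averaged over 8 reps
  expect_equal(idx, 2, tolerance = 0.2)
})

test_that("2-D KS test separates shifted clouds but not identical ones", {
  set.seed(9)
  x1 <- rnorm(60); y1 <- rnorm(60)
  same <- ks2d_test(x1, y1, rnorm(60), rnorm(60), n_perm = 99, seed = 2)
  expect_gt(same$p, 0.05)
  shifted <- ks2d_test(x1, y1, rnorm(60) + 2, rnorm(60), n_perm = 99,
                       seed = 2)
  expect_lt(shifted$p, 0.05)
  expect_gt(shifted$statistic, same$statistic)
})

test_that("cross-session PSTH correlation is 1 for identity, ~0 for shuffle", {
  set.seed(10)
  pre <- matrix(rnorm(30 * 100), 30)
  res <- cross_session_psth_correlation(pre, pre)
  expect_true(all(abs(res$r - 1) < 1e-12))
  shuf <- pre[, sample.int(100)]
  res2 <- cross_session_psth_correlation(pre, shuf)
  expect_lt(abs(res2$mean), 0.1)
  # constant PSTHs are excluded
  pre2 <- rbind(pre, 0)
  post2 <- rbind(pre, 0)
  res3 <- cross_session_psth_correlation(pre2, post2)
  expect_equal(res3$n_excluded, 1)
  expect_error(cross_session_psth_correlation(pre, pre[, 1:50]), "shape")
})
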