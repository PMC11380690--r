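#' Sensory-mapping stimulus catalog
#'
#' Five pure-tone frequencies (4, 8, 12, 16, 20 kHz), four drifting-grating
#' directions, and their 20 audio-visual combinations: 29 enumerable
#' stimulus types.
#'
#' @return data frame with columns `modality`, `frequency_khz`, `direction`
#' @export
mapping_catalog <- function() {
  freqs <- c(4, 8, 12, 16, 20)
  dirs <- c("up", "down", "left", "right")
  rbind(
    data.frame(modality = "auditory", frequency_khz = freqs,
               direction = NA_character_),
    data.frame(modality = "visual", frequency_khz = NA_real_,
               direction = dirs),
    expand.grid(frequency_khz = freqs, direction = dirs,
                stringsAsFactors = FALSE) |>
      (\(g) data.frame(modality = "multisensory",
                       frequency_khz = g$frequency_khz,
                       direction = g$direction))()
  )
}

#' Generate one synthetic sensory-mapping session
#'
#' Presents every catalog stimulus `mapping_reps` times in pseudo-random
#' order (default 8 repetitions: 232 trials). Cells carry planted Gaussian
#' frequency tuning, direction tuning, and a configurable multisensory
#' gain: the planted multisensory amplitude is
#' `gain * (auditory + visual)`, so `gain = 1` is linear integration.
#'
#' @param cfg a [sim_config()]
#' @param seed integer seed
#' @param mouse_id,session_id identifiers
#' @param tuning optional planted tuning from a previous call (to simulate
#'   stable tuning across sessions); a list as returned in `truth$tuning`
#' @param tuning_drift SD of tuning-amplitude perturbation applied to a
#'   reused `tuning` (0 = perfectly stable)
#' @param keep_signal attach the noiseless signal matrix to the truth
#' @return list with `recording`, `trials` (mapping trial table), `truth`
#' @export
generate_mapping_session <- function(cfg, seed, mouse_id = "m01",
                                     session_id = "map01", tuning = NULL,
                                     tuning_drift = 0,
                                     keep_signal = FALSE) {
  validate_sim_config(cfg)
  local_seed(seed)
  fr <- cfg$frame_rate_hz
  catalog <- mapping_catalog()
  reps <- cfg$mapping_reps
  order_idx <- sample(rep(seq_len(nrow(catalog)), reps))
  n_trials <- length(order_idx)
  trials <- catalog[order_idx, ]
  rownames(trials) <- NULL
  trials$trial <- seq_len(n_trials)

  n_stim <- win_frames(cfg$stimulus_s, fr)
  itis <- stats::runif(n_trials, cfg$mapping_iti_range_s[1],
                       cfg$mapping_iti_range_s[2])
  iti_frames <- vapply(itis, win_frames, integer(1), frame_rate = fr)
  onsets <- cumsum(iti_frames) +
    c(0L, cumsum(rep(n_stim, n_trials - 1L)))
  n_frames <- onsets[n_trials] + n_stim + win_frames(3, fr)
  trials$onset_frame <- onsets

  freqs <- c(4, 8, 12, 16, 20)
  dirs <- c("up", "down", "left", "right")
  A <- cfg$effect_size
  if (is.null(tuning)) {
    tuning <- list(
      pref_freq_idx = sample.int(5L, cfg$n_cells, replace = TRUE),
      freq_width = stats::runif(cfg$n_cells, 0.6, 1.2),
      aud_amp = A * stats::runif(cfg$n_cells, 0.6, 1.4),
      pref_dir = sample(dirs, cfg$n_cells, replace = TRUE),
      vis_amp = 0.5 * A * stats::runif(cfg$n_cells, 0.4, 1.2),
      ms_gain = rep(cfg$multisensory_gain, cfg$n_cells)
    )
  } else if (tuning_drift > 0) {
    tuning$aud_amp <- pmax(tuning$aud_amp *
                             exp(stats::rnorm(cfg$n_cells, 0, tuning_drift)), 0)
    tuning$pref_freq_idx <- ifelse(stats::runif(cfg$n_cells) < tuning_drift,
                                   sample.int(5L, cfg$n_cells, replace = TRUE),
                                   tuning$pref_freq_idx)
  }

  aud_resp <- function(cell, fidx)
    tuning$aud_amp[cell] *
      exp(-(fidx - tuning$pref_freq_idx[cell])^2 /
            (2 * tuning$freq_width[cell]^2))
  vis_resp <- function(cell, dir)
    tuning$vis_amp[cell] * ifelse(dir == tuning$pref_dir[cell], 1, 0.3)

  kernel <- calcium_kernel(cfg)
  sig <- matrix(0, cfg$n_cells, n_frames)
  for (cell in seq_len(cfg$n_cells)) {
    tr <- numeric(n_frames)
    for (i in seq_len(n_trials)) {
      mo <- trials$modality[i]
      amp <- if (mo == "auditory") {
        aud_resp(cell, match(trials$frequency_khz[i], freqs))
      } else if (mo == "visual") {
        vis_resp(cell, trials$direction[i])
      } else {
        tuning$ms_gain[cell] *
          (aud_resp(cell, match(trials$frequency_khz[i], freqs)) +
             vis_resp(cell, trials$direction[i]))
      }
      if (amp != 0)
        tr <- add_transient(tr, onsets[i], amp * stats::runif(1, 0.85, 1.15),
                            kernel)
    }
    sig[cell, ] <- tr
  }
  noise <- matrix(stats::rnorm(cfg$n_cells * n_frames, sd = cfg$noise_sd),
                  cfg$n_cells, n_frames)
  bg <- 2 + smooth_noise(n_frames)
  fneu <- matrix(bg, cfg$n_cells, n_frames, byrow = TRUE) +
    matrix(stats::rnorm(cfg$n_cells * n_frames, sd = 0.1),
           cfg$n_cells, n_frames)
  drift <- outer(stats::rnorm(cfg$n_cells, sd = cfg$drift_sd),
                 seq(-0.5, 0.5, length.out = n_frames))
  f <- sig + noise + drift + 0.7 * fneu

  rec <- structure(list(F = f, Fneu = fneu, frame_rate = fr,
                        mouse_id = mouse_id, session_id = session_id,
                        phase = "mapping", task_rule = NA_character_),
                   class = "session_recording")
  class(trials) <- c("mapping_trial_table", class(trials))
  truth <- list(tuning = tuning, seed = seed)
  if (keep_signal) truth$signal <- sig
  list(recording = rec, trials = trials, truth = truth)
}
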