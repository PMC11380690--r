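#' GCaMP-like calcium impulse response
#'
#' Difference-of-exponentials kernel `(1 - exp(-t/rise)) * exp(-t/decay)`
#' normalised to unit peak, sampled at the imaging frame rate and truncated
#' at five decay constants.
#'
#' @param cfg a [sim_config()]
#' @return numeric vector, one value per frame
#' @export
calcium_kernel <- function(cfg) {
  fr <- cfg$frame_rate_hz
  t <- seq(0, 5 * cfg$kernel_decay_s, by = 1 / fr)
  k <- (1 - exp(-t / cfg$kernel_rise_s)) * exp(-t / cfg$kernel_decay_s)
  k / max(k)
}

# Add amp * kernel to a trace starting at 0-based frame `at` (in place value
# semantics: returns the modified trace).
add_transient <- function(trace, at, amp, kernel) {
  n <- length(trace)
  i0 <- at + 1L
  if (i0 > n) return(trace)
  len <- min(length(kernel), n - i0 + 1L)
  idx <- i0:(i0 + len - 1L)
  trace[idx] <- trace[idx] + amp * kernel[seq_len(len)]
  trace
}

simulate_cell_classes <- function(cfg) {
  probs <- cfg$class_probs
  n <- cfg$n_cells
  # deterministic allocation: largest-remainder so labels partition all cells
  raw <- probs * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  factor(rep(names(probs), counts), levels = names(probs))
}

# Smooth unit-mean AR(1) process used for locomotion and latent waveforms.
smooth_noise <- function(n, rho = 0.98) {
  x <- stats::filter(stats::rnorm(n), rho, method = "recursive")
  as.numeric(x) / stats::sd(x)
}

#' Generate one synthetic task session
#'
#' Builds a complete Go/Nogo imaging session with known ground truth: a
#' cell-by-frame fluorescence matrix (plus matched neuropil), the per-trial
#' event table, behavioural traces, and the planted cell-class labels.
#'
#' Planted structure, per functional class: stimulus-locked calcium
#' transients for Go- and Nogo-responsive classes (with learning-dependent
#' amplitude for the `learning_enhanced` / `learning_inhibited` classes),
#' monotone delay-period ramps on Hit trials for the `ramp_up` / `ramp_down`
#' classes, and locomotion-coupled activity for `behavior_coupled` cells.
#' In phases with non-zero `delay_coherence`, all cells additionally share a
#' common latent delay-period signal on Hit trials, scaled per cell by a
#' positive loading; this is what the population-vector-correlation and
#' co-activity-network analyses are designed to detect.
#'
#' @param cfg a [sim_config()]
#' @param phase one of `"initial-naive"`, `"initial-expert"`,
#'   `"reversal-naive"`, `"reversal-expert"`
#' @param seed integer seed; identical seeds give bit-identical output
#' @param mouse_id,session_id identifiers stored in the recording
#' @param keep_signal if `TRUE`, attach the noiseless signal matrix and
#'   per-cell transient counts to the ground truth (used by oracles)
#' @return list with elements `recording` (a `session_recording`),
#'   `trials` (a `trial_table` data frame), `behavior`
#'   (a `behavioral_traces` list) and `truth` (ground-truth list)
#' @export
generate_session <- function(cfg, phase, seed, mouse_id = "m01",
                             session_id = "s01", keep_signal = FALSE) {
  validate_sim_config(cfg)
  phase <- match.arg(phase, task_phases())
  local_seed(seed)

  fr <- cfg$frame_rate_hz
  n_stim <- win_frames(cfg$stimulus_s, fr)
  n_delay <- win_frames(cfg$delay_s, fr)
  n_resp <- win_frames(cfg$response_s, fr)

  counts <- trial_counts(cfg)
  types <- sample(rep(c("go", "nogo", "catch"), counts))

  itis <- stats::runif(cfg$n_trials, cfg$iti_range_s[1], cfg$iti_range_s[2])
  iti_frames <- vapply(itis, win_frames, integer(1), frame_rate = fr)
  trial_len <- n_stim + n_delay + n_resp
  onsets <- cumsum(iti_frames) + c(0L, cumsum(rep(trial_len, cfg$n_trials - 1L)))
  n_frames <- onsets[cfg$n_trials] + trial_len + win_frames(2, fr)

  expert <- is_expert_phase(phase)
  pol <- cfg$lick_policy[[if (expert) "expert" else "naive"]]
  p_lick <- c(go = pol$go, nogo = pol$nogo, catch = pol$catch)
  licked <- stats::runif(cfg$n_trials) < p_lick[types]
  outcome <- mapply(classify_outcome, types, licked)

  # lick timestamps (seconds from session start)
  lick_times <- vector("list", cfg$n_trials)
  antic_count <- integer(cfg$n_trials)
  for (i in seq_len(cfg$n_trials)) {
    lt <- numeric(0)
    resp_on_s <- (onsets[i] + n_stim + n_delay) / fr
    if (licked[i]) {
      n_resp_licks <- 1L + stats::rpois(1, 3)
      lt <- resp_on_s + sort(stats::runif(n_resp_licks, 0.25,
                                          cfg$response_s - 0.05))
      if (stats::runif(1) < pol$p_antic) {
        k <- stats::rpois(1, pol$antic_rate_hz * cfg$delay_s)
        if (k > 0) {
          antic <- (onsets[i] + n_stim) / fr +
            sort(stats::runif(k, 0, cfg$delay_s - 1e-6))
          antic_count[i] <- k
          lt <- c(antic, lt)
        }
      }
    }
    lick_times[[i]] <- lt
  }

  go_cue <- if (startsWith(phase, "initial")) "tone-12kHz" else "grating-right"
  nogo_cue <- if (startsWith(phase, "initial")) "grating-right" else "tone-12kHz"
  stimulus <- c(go = go_cue, nogo = nogo_cue, catch = "blank")[types]

  trials <- data.frame(
    trial = seq_len(cfg$n_trials),
    type = types,
    stimulus = stimulus,
    onset_frame = onsets,
    outcome = outcome,
    reward = outcome == "Hit",
    n_antic_licks = antic_count,
    stringsAsFactors = FALSE
  )
  trials$lick_times <- I(lick_times)
  class(trials) <- c("trial_table", class(trials))

  # behavioural traces
  locomotion <- pmax(smooth_noise(n_frames) + 1, 0)
  loco_z <- (locomotion - mean(locomotion)) / stats::sd(locomotion)

  # planted activity -------------------------------------------------------
  cls <- simulate_cell_classes(cfg)
  A <- cfg$effect_size
  kernel <- calcium_kernel(cfg)
  u <- stats::runif(cfg$n_cells, 0.5, 1.5)        # coherence loadings
  coh <- cfg$delay_coherence[[phase]]

  sig <- matrix(0, cfg$n_cells, n_frames)
  n_events <- integer(cfg$n_cells)

  go_amp <- c(stable_go = A,
              learning_enhanced = if (expert) A else 0.2 * A,
              learning_inhibited = if (expert) 0.25 * A else A)

  hit_idx <- which(trials$outcome == "Hit")
  delay_from <- n_stim
  ramp <- seq(0, 1, length.out = n_delay)
  tail_len <- min(length(kernel), n_frames)

  # shared latent delay signal on Hit trials
  if (coh > 0 && length(hit_idx) > 0) {
    lat <- matrix(0, length(hit_idx), n_delay)
    for (h in seq_along(hit_idx)) {
      g <- stats::runif(1, 0.7, 1.3)
      lat[h, ] <- g * (1 + 0.5 * smooth_noise(n_delay, rho = 0.9))
    }
  }

  for (c_i in seq_len(cfg$n_cells)) {
    tr <- numeric(n_frames)
    cc <- as.character(cls[c_i])
    if (cc %in% names(go_amp)) {
      amp <- go_amp[[cc]]
      if (amp > 0) {
        for (i in which(trials$type == "go")) {
          tr <- add_transient(tr, onsets[i], amp * stats::runif(1, 0.8, 1.2),
                              kernel)
          n_events[c_i] <- n_events[c_i] + 1L
        }
      }
    } else if (cc == "nogo_responsive") {
      for (i in which(trials$type == "nogo")) {
        tr <- add_transient(tr, onsets[i], A * stats::runif(1, 0.8, 1.2),
                            kernel)
        n_events[c_i] <- n_events[c_i] + 1L
      }
    } else if (cc %in% c("ramp_up", "ramp_down")) {
      shape <- if (cc == "ramp_up") ramp else rev(ramp)
      for (i in hit_idx) {
        j <- onsets[i] + delay_from
        idx <- (j + 1L):(j + n_delay)
        tr[idx] <- tr[idx] + A * shape
        # exponential tail so the ramp does not end in a step
        tl <- min(length(kernel), n_frames - (j + n_delay))
        if (tl > 0) {
          tidx <- (j + n_delay + 1L):(j + n_delay + tl)
          tr[tidx] <- tr[tidx] + A * shape[n_delay] *
            exp(-(seq_len(tl) / fr) / cfg$kernel_decay_s)
        }
      }
    } else if (cc == "behavior_coupled") {
      tr <- tr + 0.5 * A * loco_z
    }
    if (coh > 0 && length(hit_idx) > 0) {
      for (h in seq_along(hit_idx)) {
        j <- onsets[hit_idx[h]] + delay_from
        idx <- (j + 1L):(j + n_delay)
        tr[idx] <- tr[idx] + coh * u[c_i] * lat[h, ]
      }
    }
    sig[c_i, ] <- tr
  }

  noise <- matrix(stats::rnorm(cfg$n_cells * n_frames, sd = cfg$noise_sd),
                  cfg$n_cells, n_frames)
  drift_amp <- stats::rnorm(cfg$n_cells, sd = cfg$drift_sd)
  drift <- outer(drift_amp, seq(-0.5, 0.5, length.out = n_frames))

  # neuropil: slow shared background plus its own noise; raw F carries the
  # 0.7-scaled contamination so neuropil correction recovers the cell signal
  bg <- 2 + smooth_noise(n_frames)
  fneu <- matrix(bg, cfg$n_cells, n_frames, byrow = TRUE) +
    matrix(stats::rnorm(cfg$n_cells * n_frames, sd = 0.1),
           cfg$n_cells, n_frames)
  f <- sig + noise + drift + 0.7 * fneu

  rec <- structure(list(F = f, Fneu = fneu, frame_rate = fr,
                        mouse_id = mouse_id, session_id = session_id,
                        phase = phase,
                        task_rule = if (startsWith(phase, "initial"))
                          "auditory-go" else "visual-go"),
                   class = "session_recording")

  behavior <- structure(list(locomotion = locomotion,
                             lick_events = sort(unlist(lick_times)),
                             pupil = simulate_pupil_points(n_frames)),
                        class = "behavioral_traces")

  truth <- list(cell_class = cls, delay_coherence = coh,
                effect_size = A, loadings = u, n_events = n_events,
                seed = seed)
  if (keep_signal) truth$signal <- sig

  list(recording = rec, trials = trials, behavior = behavior, truth = truth)
}

# Eight labelled pupil-edge points per frame on a slowly varying circle;
# ~3% of frames are blinks with fewer than 3 visible points.
simulate_pupil_points <- function(n_frames) {
  radius <- 2 + 0.3 * smooth_noise(n_frames)
  radius <- pmax(radius, 0.5)
  ang <- seq(0, 2 * pi, length.out = 9L)[1:8]
  x <- outer(radius, cos(ang)) + stats::rnorm(n_frames * 8, sd = 0.02)
  y <- outer(radius, sin(ang)) + stats::rnorm(n_frames * 8, sd = 0.02)
  blink <- stats::runif(n_frames) < 0.03
  x[blink, 3:8] <- NA_real_
  y[blink, 3:8] <- NA_real_
  list(x = x, y = y, radius = radius)
}
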