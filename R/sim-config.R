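#' Simulation configuration for synthetic Go/Nogo imaging experiments
#'
#' Bundles every tunable of the synthetic-data generator. Defaults reproduce
#' the task design the analyses assume: 140 trials per session split
#' 30% Go / 35% Nogo / 35% catch, a 2 s stimulus, 2 s delay and 1.5 s
#' response window separated by 6-13 s inter-trial intervals, imaging at
#' 30 Hz with GCaMP-like kinetics.
#'
#' @param n_mice number of animals to simulate
#' @param n_cells number of cells per animal
#' @param sessions_per_phase imaging sessions per learning phase
#' @param n_trials trials per task session
#' @param trial_mix named proportions for `go`, `nogo`, `catch`; must sum to 1.
#'   Trial counts are allocated deterministically: `floor` for Go and Nogo,
#'   remainder to catch.
#' @param frame_rate_hz imaging frame rate (Hz)
#' @param stimulus_s,delay_s,response_s epoch durations in seconds
#' @param iti_range_s two-element range of inter-trial intervals (s)
#' @param kernel_rise_s,kernel_decay_s calcium-indicator kernel time constants
#'   (s); the kernel is a difference of exponentials normalised to unit peak
#' @param noise_sd per-frame Gaussian noise SD (z units)
#' @param drift_sd SD of the per-cell linear drift amplitude over a session
#'   (z units across the whole session), exercised by detrending
#' @param effect_size response amplitude of planted responsive cells (z units)
#' @param class_probs named class proportions for planted functional cell
#'   classes; must sum to 1. Classes: `stable_go`, `learning_enhanced`,
#'   `learning_inhibited`, `ramp_up`, `ramp_down`, `nogo_responsive`,
#'   `behavior_coupled`, `nonresponsive`.
#' @param delay_coherence named per-phase strength in `[0, 1]` of the common
#'   latent signal shared across cells during the delay period of rewarded
#'   (Hit) trials
#' @param lick_policy named list of per-phase lick probabilities
#'   (`go`, `nogo`, `catch`) and anticipatory-lick parameters
#'   (`p_antic`: probability a Hit trial carries anticipatory licking;
#'   `antic_rate_hz`: Poisson lick rate during the delay on those trials)
#' @param expert_session session index at which the expected d-prime crosses
#'   1.5 (logistic learning-curve midpoint)
#' @param n_sessions sessions per learning block for learning curves
#' @param dprime_max asymptote of the expected d-prime curve
#' @param learning_width_sessions logistic width of the learning curve
#' @param mapping_reps repetitions of each mapping stimulus type
#' @param mapping_iti_range_s inter-trial interval range in mapping sessions
#' @param multisensory_gain multiplicative gain linking the multisensory
#'   response to the sum of unisensory responses (1 = linear integration)
#'
#' @return an object of class `sim_config` (a validated list)
#' @export
sim_config <- function(n_mice = 8L,
                       n_cells = 100L,
                       sessions_per_phase = 3L,
                       n_trials = 140L,
                       trial_mix = c(go = 0.30, nogo = 0.35, catch = 0.35),
                       frame_rate_hz = 30,
                       stimulus_s = 2,
                       delay_s = 2,
                       response_s = 1.5,
                       iti_range_s = c(6, 13),
                       kernel_rise_s = 0.07,
                       kernel_decay_s = 1.7,
                       noise_sd = 1.0,
                       drift_sd = 1.0,
                       effect_size = 1.5,
                       class_probs = c(stable_go = 0.10,
                                       learning_enhanced = 0.10,
                                       learning_inhibited = 0.05,
                                       ramp_up = 0.07,
                                       ramp_down = 0.05,
                                       nogo_responsive = 0.10,
                                       behavior_coupled = 0.05,
                                       nonresponsive = 0.48),
                       delay_coherence = c(`initial-naive` = 0,
                                           `initial-expert` = 0.4,
                                           `reversal-naive` = 0,
                                           `reversal-expert` = 0.4),
                       lick_policy = NULL,
                       expert_session = 10L,
                       n_sessions = 14L,
                       dprime_max = 3.0,
                       learning_width_sessions = 1.2,
                       mapping_reps = 8L,
                       mapping_iti_range_s = c(6, 9),
                       multisensory_gain = 1.0) {
  if (is.null(lick_policy)) {
    lick_policy <- list(
      naive  = list(go = 0.50, nogo = 0.45, catch = 0.45,
                    p_antic = 0.35, antic_rate_hz = 0.8),
      expert = list(go = 0.95, nogo = 0.10, catch = 0.10,
                    p_antic = 0.50, antic_rate_hz = 1.5)
    )
  }
  cfg <- list(n_mice = as.integer(n_mice), n_cells = as.integer(n_cells),
              sessions_per_phase = as.integer(sessions_per_phase),
              n_trials = as.integer(n_trials), trial_mix = trial_mix,
              frame_rate_hz = frame_rate_hz, stimulus_s = stimulus_s,
              delay_s = delay_s, response_s = response_s,
              iti_range_s = iti_range_s, kernel_rise_s = kernel_rise_s,
              kernel_decay_s = kernel_decay_s, noise_sd = noise_sd,
              drift_sd = drift_sd, effect_size = effect_size,
              class_probs = class_probs, delay_coherence = delay_coherence,
              lick_policy = lick_policy,
              expert_session = as.integer(expert_session),
              n_sessions = as.integer(n_sessions), dprime_max = dprime_max,
              learning_width_sessions = learning_width_sessions,
              mapping_reps = as.integer(mapping_reps),
              mapping_iti_range_s = mapping_iti_range_s,
              multisensory_gain = multisensory_gain)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (abs(sum(cfg$trial_mix) - 1) > 1e-8)
    stop("trial_mix must sum to 1", call. = FALSE)
  if (any(c(cfg$stimulus_s, cfg$delay_s, cfg$response_s) <= 0))
    stop("epoch durations must be positive", call. = FALSE)
  if (cfg$frame_rate_hz <= 2 * 5)
    stop("frame_rate_hz must exceed twice the 5 Hz low-pass cutoff",
         call. = FALSE)
  if (abs(sum(cfg$class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1", call. = FALSE)
  if (any(cfg$delay_coherence < 0 | cfg$delay_coherence > 1))
    stop("delay_coherence values must lie in [0, 1]", call. = FALSE)
  counts <- trial_counts(cfg)
  if (any(counts < 1))
    stop("trial counts below 1 per type; increase n_trials", call. = FALSE)
  invisible(cfg)
}

#' Deterministic trial-type allocation
#'
#' Go and Nogo counts are `floor(prop * n_trials)`; the remainder goes to
#' catch trials. At the default 140-trial session this yields 42 Go, 49 Nogo
#' and 49 catch trials.
#'
#' @param cfg a [sim_config()]
#' @return named integer vector with elements `go`, `nogo`, `catch`
#' @export
trial_counts <- function(cfg) {
  n <- cfg$n_trials
  go <- as.integer(floor(cfg$trial_mix[["go"]] * n))
  nogo <- as.integer(floor(cfg$trial_mix[["nogo"]] * n))
  c(go = go, nogo = nogo, catch = n - go - nogo)
}

task_phases <- function() {
  c("initial-naive", "initial-expert", "reversal-naive", "reversal-expert")
}

is_expert_phase <- function(phase) {
  grepl("expert$", phase)
}
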