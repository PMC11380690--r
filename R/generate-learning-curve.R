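#' Simulate a behavioural learning curve
#'
#' The expected d-prime follows a logistic curve
#' `d'(s) = dprime_max / (1 + exp(-(s - expert_session) / width))`, so the
#' deterministic trajectory crosses `dprime_max / 2` (1.5 at the default
#' asymptote of 3) exactly at the configured expert session. Hit and
#' false-alarm probabilities are derived symmetrically
#' (`p_hit = pnorm(d'/2)`, `p_fa = pnorm(-d'/2)`) and, when `stochastic`,
#' outcome counts are binomial draws at the session's trial allocation,
#' with the observed d-prime recomputed through [d_prime()] (including the
#' extreme-ratio adjustment). A reversal block restarts the curve below
#' threshold with its own midpoint.
#'
#' @param cfg a [sim_config()]
#' @param seed RNG seed
#' @param stochastic draw binomial outcome counts; if `FALSE` the observed
#'   d-prime equals the deterministic curve exactly
#' @param blocks learning blocks to simulate
#' @return data frame with one row per session: `block`, `session`,
#'   `p_hit`, `p_fa`, `hits`, `misses`, `fas`, `crs`, `d_expected`,
#'   `d_prime`
#' @export
generate_learning_curve <- function(cfg, seed = 1L, stochastic = TRUE,
                                    blocks = c("initial", "reversal")) {
  validate_sim_config(cfg)
  if (cfg$n_sessions < 1) stop("need at least one session", call. = FALSE)
  local_seed(seed)
  counts <- trial_counts(cfg)
  n_go <- counts[["go"]]
  n_nogo <- counts[["nogo"]] + counts[["catch"]]
  one_block <- function(block) {
    s <- seq_len(cfg$n_sessions)
    d_exp <- cfg$dprime_max /
      (1 + exp(-(s - cfg$expert_session) / cfg$learning_width_sessions))
    p_hit <- stats::pnorm(d_exp / 2)
    p_fa <- stats::pnorm(-d_exp / 2)
    if (stochastic) {
      hits <- stats::rbinom(length(s), n_go, p_hit)
      fas <- stats::rbinom(length(s), n_nogo, p_fa)
    } else {
      hits <- p_hit * n_go
      fas <- p_fa * n_nogo
    }
    d_obs <- mapply(function(h, f) d_prime(h, n_go - h, f, n_nogo - f),
                    hits, fas)
    data.frame(block = block, session = s, p_hit = p_hit, p_fa = p_fa,
               hits = hits, misses = n_go - hits, fas = fas,
               crs = n_nogo - fas, d_expected = d_exp, d_prime = d_obs)
  }
  do.call(rbind, lapply(blocks, one_block))
}
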