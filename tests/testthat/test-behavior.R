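test_that("trial outcomes follow the Go/Nogo/catch contingency", {
  expect_equal(classify_outcome("go", TRUE), "Hit")
  expect_equal(classify_outcome("go", FALSE), "Miss")
  expect_equal(classify_outcome("nogo", TRUE), "FA")
  expect_equal(classify_outcome("nogo", FALSE), "CR")
  expect_equal(classify_outcome("catch", TRUE), "catch-FA")
  expect_equal(classify_outcome("catch", FALSE), "catch-CR")
  expect_error(classify_outcome("blank", TRUE))
})

test_that("contacts inside the 200 ms grace period are not responses", {
  # lick 0.8 s into the window counts
  expect_true(response_licked(10.8, window_onset_s = 10))
  # touch 0.1 s after window onset is ignored -> Miss on a Go trial
  expect_false(response_licked(10.1, window_onset_s = 10))
  expect_equal(classify_outcome("go", response_licked(10.1, 10)), "Miss")
  # half-open window end
  expect_false(response_licked(11.5, window_onset_s = 10, window_s = 1.5))
})

test_that("d-prime matches an independent inverse-normal oracle", {
  # oracle: Z via pracma::erfinv, evaluated independently of qnorm
  z_oracle <- function(p) sqrt(2) * pracma::erfinv(2 * p - 1)
  expect_equal(d_prime(38, 4, 10, 88),
               z_oracle(38 / 42) - z_oracle(10 / 98), tolerance = 1e-9)
  # equal ratios give zero
  expect_equal(d_prime(21, 21, 49, 49), 0)
  # antisymmetry under swapping hit and false-alarm ratios
  expect_equal(d_prime(38, 4, 10, 88), -d_prime(10, 88, 38, 4))
})

test_that("extreme ratios are adjusted to 1/(2N) before the inverse normal", {
  expect_equal(adjust_ratio(1, 42), 1 - 1 / 84)
  expect_equal(adjust_ratio(0, 42), 1 / 84)
  d <- d_prime(42, 0, 10, 88)
  expect_true(is.finite(d))
  expect_equal(d, qnorm(1 - 1 / 84) - qnorm(10 / 98))
  expect_error(d_prime(0, 0, 10, 88), "at least one")
})

test_that("expert onset is the end of the first qualifying run", {
  ph <- learning_phases(c(0.2, 0.9, 1.6, 1.7, 1.8))
  expect_equal(ph$expert_onset, 5L)          # 0-based index 4
  ph2 <- learning_phases(c(1.6, 1.7, 1.2, 1.6, 1.7, 1.8))
  expect_equal(ph2$expert_onset, 6L)         # 0-based index 5
  expect_equal(learning_phases(c(1, 1.2, 0.8, 1.1))$expert, integer(0))
  expect_true(is.na(learning_phases(c(1, 1.2, 0.8, 1.1))$expert_onset))
})

test_that("learning phase detection agrees with an exhaustive scan oracle", {
  oracle_onset <- function(d, thr = 1.5, k = 3) {
    for (i in k:length(d)) {
      if (all(d[(i - k + 1):i] > thr)) return(i)
    }
    NA_integer_
  }
  set.seed(42)
  for (rep in 1:50) {
    d <- runif(10, 0, 3)
    expect_identical(learning_phases(d)$expert_onset, oracle_onset(d))
  }
})

test_that("anticipatory lick counting uses half-open delay windows", {
  licks <- list(c(12.5, 13.9), c(13.999), numeric(0))
  res <- anticipatory_licks(licks, delay_onset_s = c(12, 12, 12),
                            delay_s = 2)
  expect_equal(res$counts, c(2L, 1L, 0L))
  # a lick exactly at delay end is not counted (half-open window)
  res2 <- anticipatory_licks(list(14.0), delay_onset_s = 12, delay_s = 2)
  expect_equal(res2$counts, 0L)
  # one exactly at delay onset is
  res3 <- anticipatory_licks(list(12.0), delay_onset_s = 12, delay_s = 2)
  expect_equal(res3$counts, 1L)
  # licks only in the response window leave delay counts at zero
  res4 <- anticipatory_licks(list(c(14.3, 14.8)), delay_onset_s = 12,
                             delay_s = 2)
  expect_equal(res4$counts, 0L)
})

test_that("Poisson synthetic licking recovers the planted rate", {
  set.seed(8)
  rate <- 1.5
  n <- 400
  licks <- lapply(seq_len(n), function(i) {
    k <- rpois(1, rate * 2)
    sort(runif(k, 0, 2)) + 100
  })
  res <- anticipatory_licks(licks, delay_onset_s = rep(100, n), delay_s = 2)
  se <- sqrt(rate * 2 / n)
  expect_lt(abs(mean(res$counts) - rate * 2), 3 * se)
})

test_that("behaviour-activity correlation applies the joint criterion", {
  set.seed(3)
  behav <- rnorm(200)
  cells <- rbind(behav,                         # perfectly coupled
                 matrix(rnorm(20 * 200), 20),   # independent
                 rep(1, 200))                   # constant -> excluded
  res <- behavior_activity_correlation(cells, behav)
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  expect_true(res$significant[1])
  expect_equal(attr(res, "n_excluded"), 1L)
  expect_error(behavior_activity_correlation(cells[, 1:2, drop = FALSE],
                                             behav[1:2]), "3 masked")
})

test_that("joint |r| and p criterion keeps null false positives low", {
  set.seed(11)
  flagged <- replicate(10, {
    behav <- rnorm(150)
    cells <- matrix(rnorm(100 * 150), 100)
    attr(behavior_activity_correlation(cells, behav), "fraction")
  })
  expect_lt(mean(flagged), 0.05)
})
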