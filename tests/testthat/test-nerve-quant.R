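test_that("envelope filter: unity DC gain, -3 dB at 25 Hz, monotone response", {
  fs <- 2000
  # all-zero in, all-zero out
  expect_true(all(envelope(numeric(4000), fs = fs) == 0))
  # DC offset passes with unit gain away from the edges
  env <- envelope(rep(-0.5, 4000), fs = fs)
  expect_equal(env[500:3500], rep(0.5, 3001))
  # ripple riding on a positive offset measures the filter gain directly
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  gain_at <- function(f) {
    e <- envelope(1 + 0.1 * sin(2 * pi * f * tt), fs = fs)
    mid <- e[(2 * fs):(8 * fs)]
    (max(mid) - min(mid)) / 2 / 0.1
  }
  expect_equal(gain_at(25), 1 / sqrt(2), tolerance = 1e-3)
  gains <- vapply(c(2, 10, 25, 50, 100), gain_at, numeric(1))
  expect_gt(gains[1], 0.99)
  expect_true(all(diff(gains) < 0))
  expect_error(envelope(numeric(10), fs = 2000), "shorter")
  expect_error(envelope(numeric(100), fs = 50), "100 Hz")
})

test_that("quantification recovers a known analytic alpha-function area", {
  fs <- 2000; onset <- 15
  # |signal| = alpha function with rise 1 s, decay 3 s: integral tau_d - tau_r
  tr <- envelope_trace(function(tt)
    ifelse(tt > onset, exp(-(tt - onset) / 3) - exp(-(tt - onset) / 1), 0),
    fs = fs, onset = onset, offset = 35)
  q <- quantify_response(tr, "stim")
  expect_equal(q$area, 2, tolerance = 0.05)
  expect_equal(q$time_to_peak, 1.5 * log(3), tolerance = 0.5)
  expect_lt(q$decay_fraction, 0.05)
  expect_equal(q$kinetics_class, "fast_transient")
})

test_that("quantified area is invariant to a DC offset of the raw trace", {
  fs <- 2000; onset <- 15
  shape <- function(tt)
    ifelse(tt > onset, exp(-(tt - onset) / 3) - exp(-(tt - onset) / 1), 0)
  q0 <- quantify_response(envelope_trace(shape, fs = fs), "stim")
  q1 <- quantify_response(envelope_trace(function(tt) shape(tt) + 3,
                                         fs = fs), "stim")
  expect_equal(q1$area, q0$area, tolerance = 1e-6)
  expect_equal(q1$baseline, q0$baseline + 3, tolerance = 1e-6)
})

test_that("fast-transient and slow-sustained envelopes separate on both features", {
  fs <- 2000; onset <- 15; offset <- 35
  fast <- envelope_trace(function(tt)
    ifelse(tt > onset, exp(-(tt - onset) / 3) - exp(-(tt - onset) / 1), 0),
    fs = fs)
  slow <- envelope_trace(function(tt) {
    e <- 1 / (1 + exp(-(pmin(tt, offset) - onset - 10) / 5))
    e <- ifelse(tt > offset, e * exp(-(tt - offset) / 60), e)
    ifelse(tt < onset, 0, e)
  }, fs = fs)
  qf <- quantify_response(fast, "stim")
  qs <- quantify_response(slow, "stim")
  expect_lt(qf$time_to_peak, qs$time_to_peak)
  expect_lt(qf$decay_fraction, qs$decay_fraction)
  expect_equal(qf$kinetics_class, "fast_transient")
  expect_equal(qs$kinetics_class, "slow_sustained")
  # a flat trace never clears the noise floor
  q0 <- quantify_response(envelope_trace(function(tt) rep(0, length(tt)),
                                         fs = fs), "stim")
  expect_equal(q0$area, 0)
  expect_equal(q0$kinetics_class, "none")
  expect_error(quantify_response(fast, "no_such_label"), "no stimulus")
})

test_that("threshold estimation follows the blank mean + 3 SD rule", {
  set.seed(2)
  blanks <- rnorm(8, mean = 1, sd = 0.1)
  crit <- mean(blanks) + 3 * sd(blanks)
  doses <- 10^seq(-2, 1, by = 0.5)
  # responses cross the criterion exactly at the 4th dose
  level <- c(1, 1, 1, 5, 8, 9, 9)
  responses <- lapply(level, function(m) rnorm(4, m, 0.05))
  ser <- dose_response_series("aa", "sp", doses, responses, blanks)
  est <- estimate_threshold(ser)
  expect_equal(est$threshold, doses[4])
  expect_equal(unname(est$detected), level > crit)
  expect_equal(est$criterion, crit)
  # all-blank series: nothing detected
  flat <- dose_response_series("aa", "sp", doses,
                               lapply(1:7, function(i) rnorm(4, 1, 0.1)),
                               blanks)
  expect_true(is.na(estimate_threshold(flat)$threshold))
  expect_error(dose_response_series("aa", "sp", rev(doses), responses,
                                    blanks), "ascending")
})

test_that("threshold estimate does not rise when blank noise shrinks", {
  doses <- 10^seq(-2, 1, by = 0.5)
  thr_for <- function(blank_sd, seed) {
    set.seed(seed)
    blanks <- rnorm(6, 1, blank_sd)
    responses <- lapply(c(1, 1.2, 1.5, 2.5, 5, 8, 9),
                        function(m) rnorm(4, m, 0.05))
    t <- estimate_threshold(dose_response_series("aa", "sp", doses,
                                                 responses,
                                                 blanks))$threshold
    if (is.na(t)) Inf else t
  }
  for (seed in 1:10)
    expect_lte(thr_for(0.05, seed), thr_for(0.5, seed))
})

test_that("response heatmap normalizes per leg and averages across legs", {
  one <- data.frame(compound = "ala", leg = "L1", area = 0.7)
  hm <- response_heatmap(one)
  expect_equal(unname(hm$mean), 1)
  expect_equal(dim(hm$matrix), c(1L, 1L))
  # scaling one leg's areas leaves the summary unchanged
  q <- data.frame(compound = rep(c("ala", "bet", "carv"), 2),
                  leg = rep(c("L1", "L2"), each = 3),
                  area = c(1, 0.5, 0.25, 2, 1.1, 0.4))
  hm1 <- response_heatmap(q)
  q2 <- q
  q2$area[q2$leg == "L2"] <- 10 * q2$area[q2$leg == "L2"]
  expect_equal(response_heatmap(q2)$mean, hm1$mean)
  # known relative magnitudes recovered
  expect_equal(unname(hm1$mean["ala"]), 1)
  expect_equal(unname(hm1$mean["bet"]), mean(c(0.5, 1.1 / 2)),
               tolerance = 1e-6)
  expect_true(all(hm1$matrix >= 0 & hm1$matrix <= 1))
  # all-zero legs are dropped with a warning
  qz <- rbind(q, data.frame(compound = c("ala", "bet", "carv"),
                            leg = "L3", area = 0))
  expect_warning(hm3 <- response_heatmap(qz), "L3")
  expect_equal(hm3$mean, hm1$mean)
})
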