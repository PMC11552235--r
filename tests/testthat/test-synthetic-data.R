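test_that("trace generator is seeded-deterministic and blank at zero dose", {
  pr <- digging_profile()
  t1 <- gen_trace(pr, "l_amino_acids", 2, seed = 7)
  t2 <- gen_trace(pr, "l_amino_acids", 2, seed = 7)
  expect_identical(t1$samples, t2$samples)
  expect_false(identical(t1$samples,
                         gen_trace(pr, "l_amino_acids", 2,
                                   seed = 8)$samples))
  # zero dose: area within the blank distribution (3 SD of blank spread)
  blank_areas <- vapply(1:8, function(i)
    quantify_response(gen_trace(pr, "l_amino_acids", 0, fs = 2000,
                                seed = 100 + i), "l_amino_acids")$area,
    numeric(1))
  a0 <- quantify_response(gen_trace(pr, "l_amino_acids", 0, fs = 2000,
                                    seed = 500), "l_amino_acids")$area
  expect_lt(abs(a0 - mean(blank_areas)), 3 * sd(blank_areas) + 1e-12)
  expect_error(gen_trace(pr, "l_amino_acids", -1), "non-negative")
  expect_error(gen_trace(pr, "l_amino_acids", 1, fs = 500), "1000")
  expect_error(gen_trace(pr, "l_amino_acids", 1, duration = 30), "60")
})

test_that("quantified area rises monotonically across the dose range", {
  pr <- digging_profile()
  doses <- 10^seq(-2, 1, by = 0.5)
  mean_area <- vapply(doses, function(d) {
    mean(vapply(1:10, function(s)
      quantify_response(gen_trace(pr, "l_amino_acids", d, fs = 2000,
                                  seed = 40 + s), "l_amino_acids")$area,
      numeric(1)))
  }, numeric(1))
  expect_gt(stats::cor(mean_area, doses, method = "spearman"), 0.9)
})

test_that("dose-response generator recovers the species thresholds", {
  ser_d <- gen_dose_response(digging_profile(), n_reps = 4, seed = 11,
                             fs = 2000)
  est_d <- estimate_threshold(ser_d)
  expect_equal(est_d$threshold, 0.1)        # 100 uM
  ser_n <- gen_dose_response(nondigging_profile(), n_reps = 4, seed = 11,
                             fs = 2000)
  est_n <- estimate_threshold(ser_n)
  expect_equal(est_n$threshold, 10)         # 10 mM
  expect_equal(est_n$threshold / est_d$threshold, 100)
  # a compound the species has no receptor gain for stays flat
  flat <- gen_dose_response(digging_profile(), compound = "choline",
                            n_reps = 3, seed = 11, fs = 2000)
  expect_true(is.na(estimate_threshold(flat)$threshold))
  # CSV round trip preserves the series
  path <- tempfile(fileext = ".csv")
  write_dose_response_csv(ser_d, path)
  back <- read_dose_response_csv(path)
  expect_equal(back$doses, ser_d$doses)
  expect_equal(back$blanks, ser_d$blanks, tolerance = 1e-10)
  expect_equal(estimate_threshold(back)$threshold, 0.1)
})

test_that("generator-to-estimator pipeline recovers the threshold across seeds", {
  hits <- vapply(1:10, function(sd) {
    thr <- estimate_threshold(gen_dose_response(digging_profile(),
                                                n_reps = 4, seed = 300 + sd,
                                                fs = 2000))$threshold
    # within one half-decade dose step of the nominal 0.1 mol/m3
    !is.na(thr) && abs(log10(thr) - log10(0.1)) <= 0.5 + 1e-9
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("trial generator follows the model's detectability flags", {
  det <- structure(list(c0 = 100, depth_l = 5e-3, c_star = 0.01,
                        onset_time = 300, peak_surface_conc = 1,
                        detected_within_t_max = TRUE,
                        scenario = "free_interface"),
                   class = "detectability_result")
  undet <- det
  undet$detected_within_t_max <- FALSE
  undet$onset_time <- NA_real_
  grid <- data.frame(c0 = c(100, 100), depth = c(5e-3, 40e-3))
  # undetectable conditions never succeed; encounter_prob 1 always succeeds
  tbl <- gen_trials(grid, list(det, undet), encounter_prob = 1,
                    n_trials = 10, seed = 2)
  expect_true(all(tbl$success[tbl$depth == 5e-3] == 1))
  expect_true(all(tbl$success[tbl$depth == 40e-3] == 0))
  # calibration: success counts stay inside the binomial 95% band
  counts <- vapply(1:100, function(sd)
    sum(gen_trials(grid[1, , drop = FALSE], list(det),
                   encounter_prob = 0.8, n_trials = 10,
                   seed = sd)$success), numeric(1))
  band <- stats::qbinom(c(0.025, 0.975), 10, 0.8)
  expect_gte(mean(counts >= band[1] & counts <= band[2]), 0.9)
  expect_error(gen_trials(grid, list(det), seed = 1), "differ")
  expect_error(gen_trials(grid, list(det, undet), encounter_prob = 0,
                          seed = 1), "encounter_prob")
})

test_that("trial summaries use exact binomial confidence intervals", {
  det <- structure(list(c0 = 100, depth_l = 5e-3, c_star = 0.01,
                        onset_time = 300, peak_surface_conc = 1,
                        detected_within_t_max = TRUE,
                        scenario = "free_interface"),
                   class = "detectability_result")
  grid <- data.frame(c0 = 100, depth = 5e-3)
  tbl <- gen_trials(grid, list(det), encounter_prob = 1, n_trials = 10,
                    seed = 4)
  s <- summarize_trials(tbl)
  expect_equal(s$rate, 1)
  # Clopper-Pearson lower bound for 10/10 is 0.025^(1/10) ~ 0.692
  expect_equal(s$ci_lo, 0.025^(1 / 10), tolerance = 1e-6)
  expect_equal(s$ci_hi, 1)
  undet <- det
  undet$detected_within_t_max <- FALSE
  tbl0 <- gen_trials(grid, list(undet), encounter_prob = 0.8,
                     n_trials = 10, seed = 4)
  expect_equal(summarize_trials(tbl0)$rate, 0)
})

test_that("deeper burial never raises the model-driven success rate", {
  p <- betaine_params()
  dm <- detectability_map(p, 100, c(5e-3, 9e-3, 14e-3), "free_interface")
  grid <- as.data.frame(dm)[, c("c0", "depth_l")]
  names(grid) <- c("c0", "depth")
  tbl <- gen_trials(grid, dm, encounter_prob = 1, n_trials = 20, seed = 6)
  s <- summarize_trials(tbl)
  s <- s[order(s$depth), ]
  expect_true(all(diff(s$rate) <= 0))
  expect_equal(s$rate[1], 1)     # shallow, concentrated: always found
  expect_equal(s$rate[nrow(s)], 0)  # beyond diffusive reach: never found
})
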