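test_that("symbolic sources carry their closed-form entropy rates", {
  expect_equal(attr(generate_symbolic("constant", 100, 2), "analytic_rate"),
               0)
  expect_equal(attr(generate_symbolic("periodic", 100, 3), "analytic_rate"),
               0)
  expect_equal(attr(generate_symbolic("iid", 100, 4, seed = 1),
                    "analytic_rate"), 2) # log2(4)
  expect_equal(
    attr(generate_symbolic("iid", 100, probs = c(0.5, 0.25, 0.25),
                           seed = 1), "analytic_rate"), 1.5)
  P <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(attr(generate_symbolic("markov", 100, transition = P,
                                      seed = 1), "analytic_rate"),
               -(0.9 * log2(0.9) + 0.1 * log2(0.1)), tolerance = 1e-12)
  # an asymmetric chain: rate weighted by the stationary distribution
  Q <- rbind(c(0.8, 0.2), c(0.4, 0.6)) # pi = (2/3, 1/3)
  hQ <- attr(generate_symbolic("markov", 100, transition = Q, seed = 1),
             "analytic_rate")
  h2 <- function(p) -(p * log2(p) + (1 - p) * log2(1 - p))
  expect_equal(hQ, (2 / 3) * h2(0.2) + (1 / 3) * h2(0.4), tolerance = 1e-12)
})

test_that("symbolic generation is reproducible and validated", {
  s1 <- generate_symbolic("iid", 500, 3, seed = 77)
  s2 <- generate_symbolic("iid", 500, 3, seed = 77)
  expect_identical(as.integer(s1), as.integer(s2))
  expect_equal(alphabet_size(s1), 3L)
  expect_error(generate_symbolic("iid", 100, probs = c(0.5, 0.2)),
               class = "mkse_invalid_parameter")
  expect_error(generate_symbolic("markov", 100,
                                 transition = rbind(c(1, 1), c(0.5, 0.5))),
               class = "mkse_invalid_parameter")
  expect_error(generate_symbolic("markov", 100),
               class = "mkse_invalid_parameter")
})

test_that("cohorts are stationary AR(1) surrogates inside the amplitude bounds", {
  cohort <- generate_cohort(n_subjects = 3, rr_mean = 0.9, rr_sd = 0.05,
                            ar1 = 0.8, series_length = 4000,
                            amplitude_bounds = c(0.6, 1.84), seed = 8)
  expect_named(cohort, c("subject_id", "group", "beat", "time_s", "rr_s"))
  expect_equal(dplyr::n_distinct(cohort$subject_id), 3L)
  expect_true(all(cohort$rr_s >= 0.6 & cohort$rr_s <= 1.84))
  # beat times accumulate the RR intervals
  one <- cohort[cohort$subject_id == cohort$subject_id[1], ]
  expect_equal(one$time_s, cumsum(one$rr_s), tolerance = 1e-9)
  # marginal moments close to the spec of the process
  expect_equal(mean(one$rr_s), 0.9, tolerance = 0.05)
  expect_equal(sd(one$rr_s), 0.05, tolerance = 0.02)
  ac <- acf(one$rr_s, plot = FALSE, lag.max = 1)$acf[2]
  expect_equal(ac, 0.8, tolerance = 0.1)
  # identical specs and seeds give identical cohorts
  again <- generate_cohort(n_subjects = 3, rr_mean = 0.9, rr_sd = 0.05,
                           ar1 = 0.8, series_length = 4000,
                           amplitude_bounds = c(0.6, 1.84), seed = 8)
  expect_identical(cohort$rr_s, again$rr_s)
  # zero variance collapses to the mean
  flat <- generate_cohort(n_subjects = 1, rr_sd = 0, series_length = 100,
                          seed = 1)
  expect_true(all(flat$rr_s == 0.9))
})

test_that("cohort generation rejects impossible specifications and counts clipping", {
  expect_error(generate_cohort(2, rr_mean = 2.5,
                               amplitude_bounds = c(0.6, 1.84)),
               class = "mkse_invalid_parameter")
  expect_error(generate_cohort(2, ar1 = 1), class = "mkse_invalid_parameter")
  tight <- generate_cohort(2, rr_mean = 0.9, rr_sd = 0.3,
                           amplitude_bounds = c(0.85, 0.95),
                           series_length = 500, seed = 3)
  clipped <- attr(tight, "n_clipped")
  expect_true(all(clipped$n_clipped > 0))
  expect_true(all(tight$rr_s >= 0.85 & tight$rr_s <= 0.95))
})

test_that("a higher-variance cohort has higher entropy at a fine partition", {
  lo <- generate_cohort(4, rr_sd = 0.02, series_length = 3000, group = "lo",
                        seed = 91)
  hi <- generate_cohort(4, rr_sd = 0.08, series_length = 3000, group = "hi",
                        seed = 92)
  surf <- mkse(rbind(lo, hi), scales = 1L, cardinalities = 10L)
  med <- tapply(surf$entropy, surf$group, median)
  expect_gt(med[["hi"]], med[["lo"]])
})

test_that("logistic-map orbits are reproducible binary strings", {
  s <- logistic_orbit(2000, seed = 13)
  expect_identical(as.integer(s), as.integer(logistic_orbit(2000, seed = 13)))
  expect_equal(alphabet_size(s), 2L)
  expect_equal(attr(s, "analytic_rate"), 1)
  # the invariant density visits both halves roughly equally
  expect_equal(mean(as.integer(s) == 1), 0.5, tolerance = 0.1)
  expect_error(logistic_orbit(10, x0 = 1), class = "mkse_invalid_parameter")
})
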