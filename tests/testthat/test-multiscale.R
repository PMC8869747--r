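test_that("coarse-graining averages non-overlapping windows and drops the remainder", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
  x <- rnorm(57)
  expect_identical(coarse_grain(x, 1), x) # tau = 1 is the identity
  expect_length(coarse_grain(x, 5), 57 %/% 5)
  expect_error(coarse_grain(x, 0), class = "mkse_invalid_scale")
  expect_error(coarse_grain(x, 58), class = "mkse_invalid_scale")
})

test_that("coarse-graining conserves the mean and composes across scales", {
  withr::with_seed(21, {
    x <- runif(1000)
    for (tau in c(2, 3, 7)) {
      k <- length(x) %/% tau
      expect_equal(mean(coarse_grain(x, tau)), mean(x[seq_len(k * tau)]),
                   tolerance = 1e-12)
    }
    y <- runif(600) # 600 = 4 * 150, both factorizations divide N
    expect_equal(coarse_grain(y, 6), coarse_grain(coarse_grain(y, 2), 3),
                 tolerance = 1e-12)
    expect_equal(coarse_grain(y, 6), coarse_grain(coarse_grain(y, 3), 2),
                 tolerance = 1e-12)
  })
})

test_that("coarse-graining contracts the variance of i.i.d. series", {
  withr::with_seed(22, {
    ratios <- replicate(25, {
      x <- runif(2000)
      var(coarse_grain(x, 5)) / var(x)
    })
    expect_lt(mean(ratios), 1) # the regularizing effect of window averaging
    expect_true(all(ratios < 1))
  })
})

test_that("resampling interpolates the tachogram on a uniform grid", {
  # piecewise-linear evaluation by hand at 1 Hz
  expect_equal(resample_rr(c(1, 1, 2), beat_times = c(1, 2, 4), fs = 1),
               c(1.0, 1.0, 1.5, 2.0))
  expect_equal(resample_rr(rep(1, 5), fs = 2), rep(1, 9))
  withr::with_seed(23, {
    rr <- sort(runif(50, 0.6, 1.2)) # monotone tachogram
    out <- resample_rr(rr, fs = 2)
    expect_true(all(diff(out) >= 0))
    expect_true(all(out >= min(rr) & out <= max(rr)))
  })
  expect_error(resample_rr(1.0, fs = 2), class = "mkse_insufficient_data")
})

test_that("truncation caps the length and rejects degenerate caps", {
  expect_length(truncate_series(rnorm(12000), 10000), 10000)
  x <- rnorm(500)
  expect_identical(truncate_series(x, 10000), x)
  expect_error(truncate_series(x, 0), class = "mkse_invalid_parameter")
})

test_that("mkse builds a tidy surface over the (tau, n) grid", {
  cohort <- generate_cohort(n_subjects = 2, series_length = 2400, seed = 5)
  surf <- suppressWarnings(
    mkse(cohort, scales = 1:2, cardinalities = c(2, 4)))
  expect_s3_class(surf, "mkse_tbl")
  expect_equal(nrow(surf), 2 * 2 * 2)
  expect_named(surf, c("subject_id", "group", "tau", "n", "entropy",
                       "length", "out_of_range"))
  expect_true(all(surf$entropy >= 0))
  expect_equal(unique(surf$length[surf$tau == 2]), 1200L)
  # default cardinality grid has 19 partitions
  surf19 <- suppressWarnings(
    mkse(cohort[cohort$subject_id == cohort$subject_id[1], ], scales = 1L))
  expect_equal(sort(unique(surf19$n)), 2:20)
  expect_equal(nrow(surf19), 19L)
})

test_that("mkse surfaces respond to amplitude structure as expected", {
  withr::with_seed(31, {
    # i.i.d. uniform amplitudes: finer partitions carry more information
    iid <- tibble::tibble(subject_id = "u", rr_s = runif(4000, 0.6, 1.84))
    s <- mkse(iid, interval = c(0.6, 1.84), scales = 1:2,
              cardinalities = c(2, 4))
    for (t in 1:2) {
      expect_gt(s$entropy[s$tau == t & s$n == 4],
                s$entropy[s$tau == t & s$n == 2])
    }
    # a constant series has (near) zero entropy in every cell
    const <- tibble::tibble(subject_id = "c", rr_s = rep(0.9, 4000))
    sc <- mkse(const, interval = c(0.6, 1.84), scales = 1:2,
               cardinalities = c(2, 4))
    expect_true(all(sc$entropy < 0.1))
  })
})

test_that("mkse is non-decreasing in cardinality for i.i.d. uniform data", {
  withr::with_seed(32, {
    diffs <- replicate(20, {
      d <- tibble::tibble(subject_id = "u", rr_s = runif(3000, 0.6, 1.84))
      s <- mkse(d, interval = c(0.6, 1.84), scales = 1L,
                cardinalities = c(2, 6, 12, 20))
      diff(s$entropy[order(s$n)])
    })
    # mean step up in n, within one standard error
    m <- rowMeans(diffs)
    se <- apply(diffs, 1, sd) / sqrt(ncol(diffs))
    expect_true(all(m > -se))
  })
})

test_that("mkse validates its inputs", {
  cohort <- generate_cohort(n_subjects = 1, series_length = 1200, seed = 9)
  expect_error(mkse(cohort, scales = c(1, 1)),
               class = "mkse_invalid_parameter")
  expect_error(mkse(cohort, cardinalities = 1:3),
               class = "mkse_invalid_parameter")
  expect_error(mkse(cohort, interval = c(2, 1)),
               class = "mkse_invalid_parameter")
  expect_error(suppressWarnings(mkse(cohort, scales = 2000L)),
               class = "mkse_invalid_scale")
  # a series entirely outside a fixed interval is an error, not silence
  expect_error(
    suppressWarnings(mkse(tibble::tibble(rr_s = rep(3, 1500)),
                          interval = c(0.6, 1.84), scales = 1L)),
    class = "mkse_out_of_range")
  expect_warning(
    mkse(tibble::tibble(rr_s = runif(600, 0.6, 1.84)),
         interval = c(0.6, 1.84), scales = 1L, cardinalities = 2L),
    class = "mkse_short_string")
})
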