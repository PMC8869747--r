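#' Coarse-grain a series over a scale factor
#'
#' Replaces the series by the means of non-overlapping windows of length
#' `tau`: element `j` of the output is the average of input values
#' `(j-1)*tau + 1` through `j*tau`. The output has length `floor(N / tau)`;
#' a trailing remainder shorter than `tau` is discarded. With `tau = 1` the
#' series is returned unchanged. Coarse-graining is the scale-`tau` view of
#' the dynamics used to build the multiscale entropy surface.
#'
#' @param values Numeric vector.
#' @param tau Scale factor, an integer with `1 <= tau <= length(values)`.
#' @return Numeric vector of window means, length `floor(length(values)/tau)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5), 2) # 1.5 3.5 (the trailing 5 is dropped)
#' @export
coarse_grain <- function(values, tau) {
  if (length(tau) != 1L || !is.finite(tau) || tau != as.integer(tau) ||
      tau < 1) {
    abort("`tau` must be a single integer >= 1.", class = "mkse_invalid_scale")
  }
  tau <- as.integer(tau)
  if (tau > length(values)) {
    abort(sprintf("scale %d exceeds the series length %d.",
                  tau, length(values)), class = "mkse_invalid_scale")
  }
  if (tau == 1L) return(values)
  k <- length(values) %/% tau
  .colMeans(values[seq_len(k * tau)], tau, k)
}

#' Resample an RR series to a uniform sampling rate
#'
#' Treats the RR value as a function of cumulative beat time (the tachogram)
#' and interpolates it on a uniform grid from the first to the last beat
#' time. Resampling different-length recordings at a common rate (2 Hz in
#' short-term protocols) removes series length as a confounder before
#' entropy estimation. Linear interpolation is the default because it keeps
#' every resampled value inside the observed amplitude range; a cubic spline
#' is available but may overshoot.
#'
#' @param rr RR intervals in seconds.
#' @param beat_times Cumulative beat times in seconds (monotone increasing);
#'   defaults to `cumsum(rr)`.
#' @param fs Sampling frequency in Hz.
#' @param method `"linear"` (default) or `"spline"`.
#' @return Numeric vector of resampled RR values.
#' @examples
#' resample_rr(c(1, 1, 2), beat_times = c(1, 2, 4), fs = 1) # 1.0 1.0 1.5 2.0
#' @export
resample_rr <- function(rr, beat_times = NULL, fs = 2,
                        method = c("linear", "spline")) {
  method <- match.arg(method)
  if (length(rr) < 2L) {
    abort("resampling needs at least 2 beats.",
          class = "mkse_insufficient_data")
  }
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.",
          class = "mkse_invalid_parameter")
  }
  beat_times <- beat_times %||% cumsum(rr)
  if (length(beat_times) != length(rr) || any(diff(beat_times) <= 0)) {
    abort("`beat_times` must be monotone increasing and match `rr`.",
          class = "mkse_invalid_parameter")
  }
  grid <- seq(beat_times[1L], beat_times[length(beat_times)], by = 1 / fs)
  if (method == "linear") {
    approx(beat_times, rr, xout = grid, method = "linear")$y
  } else {
    spline(beat_times, rr, xout = grid)$y
  }
}

#' Truncate a series to a maximum length
#'
#' Keeps the first `min(length(values), max_len)` values. Truncating
#' long-term recordings to a common length (10,000 samples in the long-term
#' protocol) avoids length-driven biases in the compression estimate.
#'
#' @param values Numeric vector.
#' @param max_len Positive integer cap.
#' @return The truncated vector.
#' @export
truncate_series <- function(values, max_len) {
  if (length(max_len) != 1L || !is.finite(max_len) ||
      max_len != as.integer(max_len) || max_len < 1) {
    abort("`max_len` must be a single integer >= 1.",
          class = "mkse_invalid_parameter")
  }
  values[seq_len(min(length(values), max_len))]
}

process_one_series <- function(rr, time_s = NULL, resample_hz = NULL,
                               truncate_len = NULL,
                               interp = c("linear", "spline")) {
  if (!is.null(resample_hz)) {
    rr <- resample_rr(rr, beat_times = time_s, fs = resample_hz,
                      method = match.arg(interp))
  }
  if (!is.null(truncate_len)) rr <- truncate_series(rr, truncate_len)
  rr
}

#' Multiscale partition-based Kolmogorov-Sinai entropy surface
#'
#' The main estimator. For each subject the (optionally resampled and/or
#' truncated) RR series is coarse-grained at every scale `tau`, symbolized
#' against uniform partitions of the amplitude interval at every cardinality
#' `n`, and the per-symbol entropy rate of each symbolic string is estimated
#' by pair-coding compression. The result is one entropy value per
#' `(subject, tau, n)` cell — the multiscale K-S entropy (MKSE) surface —
#' returned as a tidy tibble ready for group comparison with
#' [mkse_mann_whitney()] or [mkse_kruskal_wallis()].
#'
#' @param data A data frame with one row per beat: numeric column `rr_s`
#'   (RR in seconds), optional `time_s` (cumulative beat time), optional
#'   `subject_id` and `group` labels (a single unlabelled series is treated
#'   as one subject).
#' @param interval Length-2 numeric, the fixed amplitude interval all
#'   partitions divide. `NULL` (default) uses the global range of the
#'   processed series across all subjects — the construction used when the
#'   interval is defined as the complete range between the minimum and
#'   maximum interbeat interval over a study population. Fixed per-dataset
#'   intervals (e.g. `c(0.60, 1.84)` s for short-term, `c(0.32, 1.25)` s for
#'   long-term recordings) can be passed explicitly or via [mkse_config()]
#'   presets.
#' @param scales Integer vector of coarse-graining factors (default `1:10`).
#' @param cardinalities Integer vector of partition cardinalities
#'   (default `2:20`, i.e. 19 partitions).
#' @param resample_hz If non-`NULL`, resample each series at this rate
#'   (see [resample_rr()]) before anything else.
#' @param truncate_len If non-`NULL`, truncate each processed series to this
#'   many samples.
#' @param interp Interpolation method for resampling.
#' @param min_length Coarse-grained lengths below this floor trigger a
#'   warning (compression estimates get unreliable); default 1000.
#' @param out_of_range Out-of-range policy passed to [symbolize()]; only
#'   relevant with a fixed `interval` narrower than the data.
#' @return A tibble of class `mkse_tbl` with columns `subject_id`, `group`,
#'   `tau`, `n`, `entropy` (bits/symbol), `length` (coarse-grained series
#'   length) and `out_of_range` (clamped values). The amplitude interval
#'   actually used is stored in `attr(, "interval")`.
#' @examples
#' cohort <- generate_cohort(n_subjects = 2, series_length = 2000, seed = 1)
#' surf <- mkse(cohort, scales = 1:2, cardinalities = c(2, 4))
#' surf
#' @export
mkse <- function(data, interval = NULL, scales = 1:10,
                 cardinalities = 2:20, resample_hz = NULL,
                 truncate_len = NULL, interp = c("linear", "spline"),
                 min_length = 1000L, out_of_range = c("clamp", "error")) {
  interp <- match.arg(interp)
  out_of_range <- match.arg(out_of_range)
  if (is.numeric(data)) data <- tibble::tibble(rr_s = as.numeric(data))
  if (!is.data.frame(data) || !"rr_s" %in% names(data)) {
    abort("`data` must be a data frame with an `rr_s` column.",
          class = "mkse_invalid_parameter")
  }
  if (!"subject_id" %in% names(data)) data$subject_id <- "s1"
  if (!"group" %in% names(data)) data$group <- NA_character_
  scales <- validate_grid(scales, "scales", min = 1L)
  cardinalities <- validate_grid(cardinalities, "cardinalities", min = 2L)

  processed <- data |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(
      series = list(process_one_series(
        .data$rr_s,
        time_s = if ("time_s" %in% names(data)) .data$time_s else NULL,
        resample_hz = resample_hz, truncate_len = truncate_len,
        interp = interp)),
      .groups = "drop")

  if (is.null(interval)) {
    interval <- range(unlist(processed$series))
  }
  if (length(interval) != 2L || !all(is.finite(interval)) ||
      interval[1L] >= interval[2L]) {
    abort("`interval` must be two finite numbers with lower < upper.",
          class = "mkse_invalid_parameter")
  }
  partitions <- lapply(cardinalities, function(n)
    uniform_partition(interval[1L], interval[2L], n))

  surf <- processed |>
    dplyr::mutate(cells = purrr::map(.data$series, function(x) {
      if (max(scales) > length(x)) {
        abort(sprintf(
          "series of length %d is shorter than the largest scale %d.",
          length(x), max(scales)), class = "mkse_invalid_scale")
      }
      purrr::map_dfr(scales, function(tau) {
        y <- coarse_grain(x, tau)
        purrr::map_dfr(partitions, function(p) {
          s <- symbolize(y, p, out_of_range = out_of_range)
          if (attr(s, "out_of_range_count") == length(y)) {
            abort(sprintf(
              "all %d values at scale %d lie outside the interval [%g, %g].",
              length(y), tau, p$lower, p$upper), class = "mkse_out_of_range")
          }
          tibble::tibble(
            tau = tau, n = p$n,
            entropy = suppressWarnings(
              estimate_entropy_rate(s, min_length = min_length)),
            length = length(y),
            out_of_range = attr(s, "out_of_range_count"))
        })
      })
    })) |>
    dplyr::select(-"series") |>
    tidyr::unnest("cells")

  short <- dplyr::filter(
    dplyr::distinct(surf, .data$subject_id, .data$tau, .data$length),
    .data$length < min_length)
  if (nrow(short) > 0L) {
    warn(sprintf(
      "%d coarse-grained series (e.g. subject %s at scale %d, length %d) fall below the %d-point compression floor; their entropy estimates are dominated by coder start-up cost.",
      nrow(short), short$subject_id[1L], short$tau[1L], short$length[1L],
      as.integer(min_length)), class = "mkse_short_string")
  }

  structure(surf, class = c("mkse_tbl", class(tibble::tibble()))) |>
    `attr<-`("interval", interval)
}

validate_grid <- function(x, name, min) {
  if (length(x) == 0L || anyNA(x) || any(x != as.integer(x)) ||
      any(x < min) || anyDuplicated(x)) {
    abort(sprintf("`%s` must be distinct integers >= %d.", name, min),
          class = "mkse_invalid_parameter")
  }
  as.integer(x)
}
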