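#' Read an RR-interval series from a text file
#'
#' Accepts either a plain-text file with one RR interval (seconds) per line,
#' or a CSV with header columns `time_s,rr_s` giving the cumulative beat
#' time and the RR interval. Non-positive, non-finite or unparseable rows are
#' rejected with their 1-based row numbers. For CSV input the beat-time
#' differences are checked against the RR column.
#'
#' @param path File path.
#' @return A tibble with columns `beat`, `time_s` (cumulative beat time;
#'   `cumsum(rr_s)` for plain files) and `rr_s`.
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "mkse_io_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("time_s", first, fixed = TRUE)) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("time_s", "rr_s") %in% names(df))) {
      abort(sprintf("%s: CSV input needs columns time_s and rr_s.", path),
            class = "mkse_parse_error")
    }
    check_rr_values(df$rr_s, path)
    if (any(diff(df$time_s) <= 0)) {
      abort(sprintf("%s: time_s must be strictly increasing.", path),
            class = "mkse_parse_error")
    }
    dt <- diff(df$time_s)
    if (max(abs(dt - df$rr_s[-1L])) > 1e-6) {
      warn(sprintf(
        "%s: differences of time_s disagree with rr_s by up to %.3g s.",
        path, max(abs(dt - df$rr_s[-1L]))))
    }
    tibble::tibble(beat = seq_len(nrow(df)), time_s = df$time_s,
                   rr_s = df$rr_s)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rr <- suppressWarnings(as.numeric(lines))
    if (anyNA(rr)) {
      bad <- which(is.na(rr))
      abort(sprintf("%s: unparseable value%s at row%s %s.", path,
                    if (length(bad) > 1L) "s" else "",
                    if (length(bad) > 1L) "s" else "",
                    paste(head(bad, 5L), collapse = ", ")),
            class = "mkse_parse_error")
    }
    check_rr_values(rr, path)
    tibble::tibble(beat = seq_along(rr), time_s = cumsum(rr), rr_s = rr)
  }
}

check_rr_values <- function(rr, path) {
  bad <- which(!is.finite(rr) | rr <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("%s: non-positive or non-finite RR at row%s %s.", path,
                  if (length(bad) > 1L) "s" else "",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "mkse_parse_error")
  }
  invisible(rr)
}

#' Write / read an MKSE surface table
#'
#' Tidy CSV round trip for [mkse()] results (columns `subject_id`, `group`,
#' `tau`, `n`, `entropy`, `length`, `out_of_range`).
#'
#' @param surfaces An [mkse()] surface tibble.
#' @param path Output / input CSV path.
#' @return `write_mkse()` returns `path` invisibly; `read_mkse()` the tibble.
#' @export
write_mkse <- function(surfaces, path) {
  readr::write_csv(surfaces, path)
  invisible(path)
}

#' @rdname write_mkse
#' @export
read_mkse <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          subject_id = readr::col_character(),
                          group = readr::col_character()))
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  structure(df, class = c("mkse_tbl", class(tibble::tibble())))
}

#' Pipeline configuration
#'
#' Bundles every parameter that affects the numbers a pipeline run produces.
#' Presets encode the two experimental protocols: `"fantasia"` (short-term
#' recordings: resample at 2 Hz, fixed interval 0.60-1.84 s, no truncation)
#' and `"longterm"` (long-term recordings: truncate at 10,000 samples, fixed
#' interval 0.32-1.25 s, no resampling). Any field can be overridden after
#' choosing a preset; `preset = "custom"` starts from data-range interval,
#' no resampling, no truncation.
#'
#' @param input Input directory of RR files, or a manifest CSV with columns
#'   `subject_id,group,path`.
#' @param preset `"fantasia"`, `"longterm"` or `"custom"`.
#' @param interval,scales,cardinalities,resample_hz,truncate_len,alpha0
#'   Overrides of the preset values; see [mkse()].
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param output_dir Where [run_pipeline()] writes its outputs.
#' @return A `list` of class `mkse_config`.
#' @export
mkse_config <- function(input = NULL,
                        preset = c("custom", "fantasia", "longterm"),
                        interval = NULL, scales = 1:10,
                        cardinalities = 2:20, resample_hz = NULL,
                        truncate_len = NULL, alpha0 = 0.05, seed = NULL,
                        output_dir = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    fantasia = list(interval = c(0.60, 1.84), resample_hz = 2,
                    truncate_len = NULL),
    longterm = list(interval = c(0.32, 1.25), resample_hz = NULL,
                    truncate_len = 10000L),
    custom = list(interval = NULL, resample_hz = NULL, truncate_len = NULL))
  cfg <- list(
    input = input, preset = preset,
    interval = interval %||% defaults$interval,
    scales = scales, cardinalities = cardinalities,
    resample_hz = resample_hz %||% defaults$resample_hz,
    truncate_len = truncate_len %||% defaults$truncate_len,
    alpha0 = alpha0, seed = seed, output_dir = output_dir)
  structure(cfg, class = "mkse_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [mkse_config()] arguments.
#' @return An `mkse_config`.
#' @export
read_mkse_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(mkse_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key%s: %s",
                  if (length(unknown) > 1L) "s" else "",
                  paste(unknown, collapse = ", ")),
          class = "mkse_parse_error")
  }
  do.call(mkse_config, y)
}

read_input_manifest <- function(input) {
  if (length(input) == 1L && dir.exists(input)) {
    paths <- list.files(input, pattern = "\\.(txt|csv|rr)$",
                        full.names = TRUE)
    if (length(paths) == 0L) {
      abort(sprintf("no RR files (*.txt, *.csv, *.rr) found in %s", input),
            class = "mkse_io_error")
    }
    tibble::tibble(
      subject_id = tools::file_path_sans_ext(basename(paths)),
      group = NA_character_, path = paths)
  } else if (length(input) == 1L && file.exists(input)) {
    mf <- readr::read_csv(input, show_col_types = FALSE, progress = FALSE)
    if (!all(c("subject_id", "group", "path") %in% names(mf))) {
      abort("manifest CSV needs columns subject_id, group, path.",
            class = "mkse_parse_error")
    }
    mf$path <- ifelse(file.exists(mf$path), mf$path,
                      file.path(dirname(input), mf$path))
    mf
  } else {
    abort(sprintf("input not found: %s", input), class = "mkse_io_error")
  }
}

#' Run the full MKSE pipeline from a configuration
#'
#' Reads every subject's RR file, computes the MKSE surface with the
#' configured preprocessing and grid, and (when `output_dir` is set) writes
#' the combined tidy surface CSV plus a JSON run manifest recording every
#' parameter, package version, and any per-subject failures or warnings.
#' Subjects that fail are recorded and skipped; the run errors only if all
#' subjects fail.
#'
#' @param config An [mkse_config()] (or path to a YAML file).
#' @return The combined surface tibble (invisibly when written to disk),
#'   with the run manifest in `attr(, "manifest")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_mkse_config(config)
  if (!inherits(config, "mkse_config")) {
    abort("`config` must be an mkse_config or a YAML path.",
          class = "mkse_invalid_parameter")
  }
  manifest_tbl <- read_input_manifest(config$input)
  failures <- list()
  warnings_log <- character()
  surfaces <- purrr::pmap(manifest_tbl, function(subject_id, group, path,
                                                 ...) {
    tryCatch({
      rr <- read_rr(path)
      dat <- tibble::tibble(subject_id = subject_id, group = group,
                            time_s = rr$time_s, rr_s = rr$rr_s)
      withCallingHandlers(
        mkse(dat, interval = config$interval, scales = config$scales,
             cardinalities = config$cardinalities,
             resample_hz = config$resample_hz,
             truncate_len = config$truncate_len),
        warning = function(w) {
          warnings_log <<- c(warnings_log,
                             sprintf("%s: %s", subject_id,
                                     conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    }, error = function(e) {
      failures[[subject_id]] <<- conditionMessage(e)
      NULL
    })
  })
  surfaces <- purrr::compact(surfaces)
  if (length(surfaces) == 0L) {
    abort("every subject failed; nothing to write.",
          class = "mkse_pipeline_error")
  }
  combined <- dplyr::bind_rows(surfaces)
  manifest <- list(
    package = "mkse",
    version = as.character(utils::packageVersion("mkse")),
    preset = config$preset,
    interval = config$interval %||% "data-range",
    scales = config$scales, cardinalities = config$cardinalities,
    resample_hz = config$resample_hz, truncate_len = config$truncate_len,
    alpha0 = config$alpha0, seed = config$seed,
    n_subjects = length(surfaces),
    failures = failures, warnings = warnings_log)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_mkse(combined, file.path(config$output_dir, "surfaces.csv"))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    attr(combined, "manifest") <- manifest
    return(invisible(combined))
  }
  attr(combined, "manifest") <- manifest
  combined
}
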