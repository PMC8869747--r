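#' Uniform amplitude partition
#'
#' Divides the amplitude interval `[lower, upper]` (in seconds, for RR series)
#' into `n` cells of identical width. Cells are left-closed/right-open except
#' the last, which is closed at `upper`, so every value in the interval
#' belongs to exactly one cell. The cell index (1 to `n`) is the symbol a
#' value is mapped to by [symbolize()].
#'
#' @param lower,upper Interval bounds, `lower < upper`. For heartbeat series
#'   these are the minimal and maximal RR interval the partition must cover;
#'   common choices are the global data range or a fixed per-dataset interval
#'   such as `c(0.60, 1.84)`.
#' @param n Partition cardinality (number of cells), an integer `>= 2`.
#'
#' @return An object of class `uniform_partition`: a list with elements
#'   `lower`, `upper`, `n`, `width`, and the cell `breaks` (length `n + 1`).
#' @examples
#' p <- uniform_partition(0.60, 1.84, 2)
#' p$breaks # 0.60 1.22 1.84
#' @export
uniform_partition <- function(lower, upper, n) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1L ||
      length(upper) != 1L || !is.finite(lower) || !is.finite(upper)) {
    abort("`lower` and `upper` must be single finite numbers.",
          class = "mkse_invalid_parameter")
  }
  if (lower >= upper) {
    abort("`lower` must be strictly smaller than `upper`.",
          class = "mkse_invalid_parameter")
  }
  if (length(n) != 1L || !is.finite(n) || n != as.integer(n) || n < 2) {
    abort("`n` must be a single integer >= 2.",
          class = "mkse_invalid_parameter")
  }
  n <- as.integer(n)
  structure(
    list(lower = lower, upper = upper, n = n,
         width = (upper - lower) / n,
         breaks = seq(lower, upper, length.out = n + 1L)),
    class = "uniform_partition"
  )
}

#' @export
print.uniform_partition <- function(x, ...) {
  cat(sprintf("<uniform_partition> [%g, %g] s, %d cells of width %g\n",
              x$lower, x$upper, x$n, x$width))
  invisible(x)
}

#' Symbolic string over a finite alphabet
#'
#' Wraps an integer vector with symbols in `{1, ..., alphabet_size}`,
#' the input type of the compressor. Usually produced by [symbolize()] or
#' [generate_symbolic()].
#'
#' @param symbols Integer vector, all values in `{1, ..., alphabet_size}`.
#' @param alphabet_size Number of distinct symbols the alphabet admits.
#' @param out_of_range_count Number of input values that fell outside the
#'   partition interval and were clamped (0 for directly constructed strings).
#' @return A `symbolic_string` object (an integer vector with attributes
#'   `alphabet_size` and `out_of_range_count`).
#' @export
symbolic_string <- function(symbols, alphabet_size,
                            out_of_range_count = 0L) {
  symbols <- as.integer(symbols)
  alphabet_size <- as.integer(alphabet_size)
  if (length(symbols) == 0L) {
    abort("a symbolic string must be non-empty.", class = "mkse_empty_string")
  }
  if (is.na(alphabet_size) || alphabet_size < 1L) {
    abort("`alphabet_size` must be a positive integer.",
          class = "mkse_invalid_parameter")
  }
  if (anyNA(symbols) || any(symbols < 1L) || any(symbols > alphabet_size)) {
    bad <- which(is.na(symbols) | symbols < 1L | symbols > alphabet_size)[1L]
    abort(sprintf("symbol %s at position %d is outside {1..%d}.",
                  symbols[bad], bad, alphabet_size),
          class = "mkse_invalid_symbol")
  }
  structure(symbols, alphabet_size = alphabet_size,
            out_of_range_count = as.integer(out_of_range_count),
            class = "symbolic_string")
}

#' @export
print.symbolic_string <- function(x, ...) {
  n <- length(x)
  shown <- paste(head(unclass(x), 20L), collapse = "")
  cat(sprintf("<symbolic_string> length %d, alphabet %d: %s%s\n",
              n, alphabet_size(x), shown, if (n > 20L) "..." else ""))
  oor <- attr(x, "out_of_range_count")
  if (!is.null(oor) && oor > 0L)
    cat(sprintf("  (%d values clamped into the partition interval)\n", oor))
  invisible(x)
}

#' @rdname symbolic_string
#' @param x A `symbolic_string`.
#' @export
alphabet_size <- function(x) {
  as.integer(attr(x, "alphabet_size"))
}

#' Symbolize a real-valued series against a uniform partition
#'
#' Maps each value to the index of the partition cell containing it,
#' converting the series into a string over the alphabet `{1, ..., n}`.
#' Values outside `[lower, upper]` are, by default, clamped to the first or
#' last cell and counted, so the symbolization stays total when new data
#' exceed the interval the partition was built for.
#'
#' @param values Numeric vector of finite values (e.g. coarse-grained RR
#'   intervals in seconds).
#' @param partition A [uniform_partition()].
#' @param out_of_range `"clamp"` (default) maps values below `lower` to
#'   symbol 1 and above `upper` to symbol `n`, incrementing the
#'   `out_of_range_count` attribute; `"error"` fails on the first such value.
#' @return A [symbolic_string()] with `alphabet_size = partition$n`.
#' @examples
#' p <- uniform_partition(0, 1, 4)
#' symbolize(c(0.1, 0.5, 0.99), p)
#' @export
symbolize <- function(values, partition,
                      out_of_range = c("clamp", "error")) {
  out_of_range <- match.arg(out_of_range)
  if (!inherits(partition, "uniform_partition")) {
    abort("`partition` must be a uniform_partition object.",
          class = "mkse_invalid_parameter")
  }
  if (length(values) == 0L || !is.numeric(values) || !all(is.finite(values))) {
    abort("`values` must be a non-empty numeric vector of finite values.",
          class = "mkse_invalid_parameter")
  }
  low <- values < partition$lower
  high <- values > partition$upper
  n_oor <- sum(low) + sum(high)
  if (n_oor > 0L && out_of_range == "error") {
    bad <- which(low | high)[1L]
    abort(sprintf("value %g at position %d lies outside [%g, %g].",
                  values[bad], bad, partition$lower, partition$upper),
          class = "mkse_out_of_range")
  }
  sym <- findInterval(values, partition$breaks, rightmost.closed = TRUE)
  sym[low] <- 1L
  sym[high] <- partition$n
  symbolic_string(sym, partition$n, out_of_range_count = n_oor)
}

#' Empirical Shannon entropy of a symbolic string
#'
#' The plug-in entropy \eqn{-\sum_i \hat p_i \log \hat p_i} of the empirical
#' symbol frequencies, with \eqn{0 \log 0 = 0}. For an i.i.d. source this is
#' a consistent estimate of the entropy rate and serves as a cross-check for
#' the compression-based estimator; for dependent sources it is only an upper
#' bound on the rate.
#'
#' @param string A [symbolic_string()] (or plain integer vector of symbols).
#' @param base Logarithm base: `2` (default, bits) or `exp(1)` (nats).
#' @return Entropy in `[0, log(alphabet_size, base)]`.
#' @examples
#' shannon_entropy(symbolic_string(c(1, 2, 1, 2), 2)) # 1 bit
#' @export
shannon_entropy <- function(string, base = 2) {
  if (length(string) == 0L) {
    abort("`string` must be non-empty.", class = "mkse_empty_string")
  }
  p <- tabulate(as.integer(string))
  p <- p[p > 0] / length(string)
  -sum(p * log(p, base = base))
}
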