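#' Bonferroni-corrected significance threshold
#'
#' `alpha0 / n_comparisons`. In the multiscale protocol the correction family
#' is the number of scales at a fixed partition (e.g. `0.05 / 10 = 0.005`),
#' and for pairwise follow-ups the number of group pairs
#' (e.g. `0.005 / 3 ~= 0.0017`).
#'
#' @param alpha0 Uncorrected significance level in (0, 1).
#' @param n_comparisons Number of comparisons in the correction family.
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(alpha0, n_comparisons) {
  if (length(alpha0) != 1L || !is.finite(alpha0) || alpha0 <= 0 ||
      alpha0 >= 1) {
    abort("`alpha0` must be a single number in (0, 1).",
          class = "mkse_invalid_parameter")
  }
  if (length(n_comparisons) != 1L || !is.finite(n_comparisons) ||
      n_comparisons != as.integer(n_comparisons) || n_comparisons < 1) {
    abort("`n_comparisons` must be a single integer >= 1.",
          class = "mkse_invalid_parameter")
  }
  alpha0 / n_comparisons
}

# Two-sided Mann-Whitney p for one cell. Exact distribution for small
# tie-free samples (normal-approximation p-values are misleading there),
# tie-corrected normal approximation otherwise.
mw_cell_p <- function(x, y, exact_max = 8L) {
  if (length(unique(c(x, y))) == 1L) return(1) # fully tied: no evidence
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = !use_exact)$p.value)
}

new_mkse_grid_test <- function(grid, test, alpha0, alpha_corrected, groups,
                               pairwise = NULL) {
  structure(
    list(grid = grid, test = test, alpha0 = alpha0,
         alpha_corrected = alpha_corrected, groups = groups,
         pairwise = pairwise),
    class = "mkse_grid_test")
}

check_surfaces <- function(data, n_groups_expected = NULL) {
  needed <- c("subject_id", "group", "tau", "n", "entropy")
  if (!is.data.frame(data) || !all(needed %in% names(data))) {
    abort(paste("`data` must be an MKSE surface table with columns",
                paste(needed, collapse = ", ")),
          class = "mkse_invalid_parameter")
  }
  if (anyNA(data$group)) {
    abort("every subject needs a `group` label for comparison.",
          class = "mkse_invalid_parameter")
  }
  counts <- dplyr::distinct(data, .data$subject_id, .data$group) |>
    dplyr::count(.data$group)
  if (any(counts$n < 2L)) {
    abort("each group needs at least 2 subjects.",
          class = "mkse_invalid_parameter")
  }
  cells <- data |>
    dplyr::count(.data$subject_id, name = "n_cells") |>
    dplyr::distinct(.data$n_cells)
  if (nrow(cells) != 1L) {
    abort("all subjects must share the same (tau, n) grid.",
          class = "mkse_shape_error")
  }
  sort(unique(data$group))
}

#' Mann-Whitney comparison grid for two groups of MKSE surfaces
#'
#' Runs a two-sided Mann-Whitney (Wilcoxon rank-sum) test of equal median
#' entropy between the two groups in every `(tau, n)` cell of the surface
#' table, and flags cells whose p-value falls below the Bonferroni-corrected
#' threshold. The correction family defaults to the number of scales at a
#' fixed partition (so `alpha0 = 0.05` over 10 scales gives 0.005), the
#' convention of the multiscale protocol this estimator belongs to.
#'
#' @param data An [mkse()] surface table containing exactly two groups.
#' @param alpha0 Uncorrected significance level (default 0.05).
#' @param family_size Size of the Bonferroni family; defaults to the number
#'   of distinct scales in `data`.
#' @param exact_max Largest group size for which the exact Mann-Whitney
#'   distribution is used when there are no ties (default 8); larger samples
#'   or ties use the tie-corrected normal approximation.
#' @return An `mkse_grid_test` object; [tidy()] returns the per-cell
#'   p-values and significance flags, [glance()] a one-row summary, and
#'   [autoplot()] a p-value heatmap.
#' @examples
#' a <- mkse(generate_cohort(3, rr_sd = 0.02, series_length = 2000,
#'                           group = "A", seed = 1),
#'           scales = 1:2, cardinalities = c(2, 10))
#' b <- mkse(generate_cohort(3, rr_sd = 0.08, series_length = 2000,
#'                           group = "B", seed = 2),
#'           scales = 1:2, cardinalities = c(2, 10))
#' tidy(mkse_mann_whitney(rbind(a, b)))
#' @export
mkse_mann_whitney <- function(data, alpha0 = 0.05, family_size = NULL,
                              exact_max = 8L) {
  groups <- check_surfaces(data)
  if (length(groups) != 2L) {
    abort(sprintf(
      "mkse_mann_whitney() compares exactly 2 groups (got %d); use mkse_kruskal_wallis() for more.",
      length(groups)), class = "mkse_invalid_parameter")
  }
  family_size <- family_size %||% length(unique(data$tau))
  alpha_c <- bonferroni_threshold(alpha0, family_size)
  grid <- data |>
    dplyr::group_by(.data$tau, .data$n) |>
    dplyr::summarise(
      p = mw_cell_p(.data$entropy[.data$group == groups[1L]],
                    .data$entropy[.data$group == groups[2L]],
                    exact_max = exact_max),
      .groups = "drop") |>
    dplyr::mutate(significant = .data$p < alpha_c)
  new_mkse_grid_test(grid, "mann_whitney", alpha0, alpha_c, groups)
}

#' Kruskal-Wallis comparison grid for three or more groups
#'
#' Runs an omnibus Kruskal-Wallis test of equal median entropy across all
#' groups in every `(tau, n)` cell, plus pairwise Mann-Whitney follow-up
#' grids for every group pair with the pairwise Bonferroni threshold
#' `alpha0 / n_pairs` (three groups at `alpha0 = 0.005` give ~0.0017).
#'
#' @param data An [mkse()] surface table with at least three groups.
#' @param alpha0 Significance level for the omnibus grid; it is divided by
#'   the number of group pairs for the pairwise grids.
#' @inheritParams mkse_mann_whitney
#' @return An `mkse_grid_test` object whose `pairwise` element is a named
#'   list of pairwise `mkse_grid_test`s.
#' @export
mkse_kruskal_wallis <- function(data, alpha0 = 0.005, exact_max = 8L) {
  groups <- check_surfaces(data)
  if (length(groups) < 3L) {
    abort("fewer than 3 groups: use mkse_mann_whitney() instead.",
          class = "mkse_invalid_parameter")
  }
  grid <- data |>
    dplyr::group_by(.data$tau, .data$n) |>
    dplyr::summarise(
      p = if (length(unique(.data$entropy)) == 1L) 1 else
        suppressWarnings(
          kruskal.test(.data$entropy, factor(.data$group))$p.value),
      .groups = "drop") |>
    dplyr::mutate(significant = .data$p < alpha0)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  alpha_pair <- bonferroni_threshold(alpha0, length(pairs))
  pairwise <- purrr::map(pairs, function(pr) {
    sub <- dplyr::filter(data, .data$group %in% pr)
    out <- mkse_mann_whitney(sub, alpha0 = alpha0,
                             family_size = length(pairs),
                             exact_max = exact_max)
    out
  })
  names(pairwise) <- purrr::map_chr(pairs, paste, collapse = " vs ")
  new_mkse_grid_test(grid, "kruskal_wallis", alpha0, alpha0, groups,
                     pairwise = pairwise)
}

#' @export
print.mkse_grid_test <- function(x, ...) {
  cat(sprintf("<mkse_grid_test> %s: %s\n", x$test,
              paste(x$groups, collapse = " vs ")))
  cat(sprintf("  %d cells, threshold %g, %d significant\n",
              nrow(x$grid), x$alpha_corrected, sum(x$grid$significant)))
  if (!is.null(x$pairwise)) {
    cat(sprintf("  pairwise Mann-Whitney grids (threshold %g): %s\n",
                x$pairwise[[1L]]$alpha_corrected,
                paste(names(x$pairwise), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname mkse_mann_whitney
#' @param x An `mkse_grid_test`.
#' @param ... Unused.
#' @export
tidy.mkse_grid_test <- function(x, ...) {
  dplyr::mutate(x$grid, test = x$test,
                alpha_corrected = x$alpha_corrected)
}

#' @rdname mkse_mann_whitney
#' @export
glance.mkse_grid_test <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    n_groups = length(x$groups),
    n_cells = nrow(x$grid),
    n_significant = sum(x$grid$significant),
    min_p = min(x$grid$p),
    alpha0 = x$alpha0,
    alpha_corrected = x$alpha_corrected)
}
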