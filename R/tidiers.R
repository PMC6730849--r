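#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a one-sided dS t-test
#'
#' @param x A `matloci_ttest` from [compare_ds_sets()].
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `parameter` (df), `p.value`, `alternative`.
#' @export
tidy.matloci_ttest <- function(x, ...) {
  tibble(estimate = x$mean_between - x$mean_within,
         statistic = x$statistic, parameter = x$df, p.value = x$p_value,
         alternative = "greater")
}

#' @rdname tidy.matloci_ttest
#' @export
glance.matloci_ttest <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, df = x$df,
         n1 = x$n1, n2 = x$n2,
         mean_between = x$mean_between, mean_within = x$mean_within)
}

#' Tidy a rank-sum test result
#'
#' @param x A `ranksum_result` from [rank_sum_test()].
#' @param ... Unused.
#' @return A one-row tibble: `statistic` (U), `p.value`, `method`,
#'   `alternative`.
#' @export
tidy.ranksum_result <- function(x, ...) {
  tibble(statistic = x$U, p.value = x$p_value, method = x$method,
         alternative = x$alternative)
}

#' Tidy synteny blocks into one row per block
#'
#' @param x A `synteny_blocks` from [detect_blocks()].
#' @param ... Unused.
#' @return The blocks tibble without the list-column.
#' @export
tidy.synteny_blocks <- function(x, ...) {
  select(x$blocks, -"genes")
}

#' @rdname tidy.synteny_blocks
#' @export
glance.synteny_blocks <- function(x, ...) {
  tibble(n_blocks = nrow(x$blocks),
         n_inverted = sum(x$blocks$orientation == "inverted"),
         n_colinear = sum(x$blocks$orientation == "colinear"),
         n_singletons = nrow(x$singletons),
         n_breakpoints = nrow(x$breakpoints))
}

#' Summarize a full characterization report
#'
#' @param x A `mat_report` from [run_characterize()].
#' @param ... Unused.
#' @return A one-row tibble of headline quantities.
#' @export
glance.mat_report <- function(x, ...) {
  tibble(
    n_strains = nrow(x$reports),
    n_linked = sum(x$reports$linked, na.rm = TRUE),
    median_distance_bp = stats::median(x$reports$distance_bp, na.rm = TRUE),
    n_inverted_blocks = if (!is.null(x$synteny)) {
      sum(x$synteny$blocks$blocks$orientation == "inverted")
    } else NA_integer_,
    ds_ttest_p = if (!is.null(x$divergence$ttest)) x$divergence$ttest$p_value
      else NA_real_,
    ste3_pattern = if (!is.null(x$genealogy) && nrow(x$genealogy)) {
      x$genealogy$pattern[match("STE3", x$genealogy$role)]
    } else NA_character_)
}
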