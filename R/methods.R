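#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline labs
#'   geom_col geom_hline theme_minimal
#' @export
ggplot2::autoplot

#' @export
print.tam_perm <- function(x, ...) {
  cat(sprintf("One-sided %s permutation test (%s)\n", x$statistic, x$metric))
  cat(sprintf("  flagged windows k = %d of %d included\n", x$k, x$n_included))
  cat(sprintf("  observed %s = %.4g\n", x$statistic, x$observed))
  cat(sprintf("  p = %.4g  (%d permutations, tie rule: %s)\n",
              x$p_value, x$n_permutations, x$tie_rule))
  if (!is.null(x$gc_band)) {
    cat(sprintf("  GC band [%.2f, %.2f], %.1f%% of windows retained\n",
                x$gc_band[1], x$gc_band[2], 100 * x$prop_retained))
  }
  invisible(x)
}

#' Tidy a permutation test result
#'
#' @param x A `tam_perm` object.
#' @param ... Unused.
#' @return `tidy()` gives the test-statistic row (metric, statistic,
#'   observed value, k, universe size); `glance()` gives the model-level
#'   row (p-value and sampling parameters).
#' @export
tidy.tam_perm <- function(x, ...) {
  tibble(metric = x$metric, statistic = x$statistic, observed = x$observed,
         k = x$k, n_included = x$n_included)
}

#' @rdname tidy.tam_perm
#' @export
glance.tam_perm <- function(x, ...) {
  tibble(p_value = x$p_value, n_permutations = x$n_permutations,
         tie_rule = x$tie_rule, add_one = x$add_one, seed = x$seed)
}

#' Plot the permutation null distribution
#'
#' Histogram of permuted medians with the observed median of
#' mutation-containing windows as a dashed vertical line (the layout used
#' to present permutation batteries in this field).
#'
#' @param object A `tam_perm` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tam_perm <- function(object, ...) {
  df <- tibble(null_stat = object$null_stats)
  ggplot(df, aes(x = .data$null_stat)) +
    geom_histogram(bins = 40, fill = "grey25") +
    geom_vline(xintercept = object$observed, linetype = "dashed",
               colour = "#2166ac", linewidth = 0.8) +
    labs(x = sprintf("permuted %s of %s", object$statistic, object$metric),
         y = "permutations",
         title = sprintf("p = %.4g (k = %d, %s)", object$p_value, object$k,
                         object$tie_rule)) +
    theme_minimal()
}

#' Plot quartile enrichment of mutated windows
#'
#' @param object A `tam_quartiles` tibble from [quartile_enrichment()].
#' @param ... Unused.
#' @return A ggplot of flagged-window fractions per expression quartile,
#'   with the uniform 0.25 expectation as a dashed line.
#' @export
autoplot.tam_quartiles <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$quartile), y = .data$flagged_fraction)) +
    geom_col(fill = "grey25") +
    geom_hline(yintercept = 0.25, linetype = "dashed", colour = "#2166ac") +
    labs(x = "expression quartile (1 = lowest)",
         y = "fraction of mutation-containing windows") +
    theme_minimal()
}
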