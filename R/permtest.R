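#' One-sided median permutation test for expression in mutated windows
#'
#' Tests whether windows that contain mutations sit in more highly expressed
#' regions than expected by chance. The observed statistic is the median of
#' the chosen metric over the k flagged (mutation-containing) included
#' windows. Each permutation draws k windows uniformly without replacement
#' from all included windows and records their median; the p-value is the
#' fraction of permuted medians that exceed (or, under
#' `tie_rule = "greater_or_equal"`, equal or exceed) the observed median.
#' Small p therefore means flagged windows are unusually highly expressed.
#'
#' Expression metrics are heavy-tailed and zero-inflated, so a resampling
#' test on the median is used rather than a parametric or rank test; the
#' p-value is invariant under any strictly monotone transform of the metric.
#'
#' @param data Tibble of windows with the metric, a logical flag column, and
#'   optionally `excluded` (excluded rows are dropped first).
#' @param metric Bare column name of the metric (e.g. `depth_tpm`).
#' @param flag Bare column name of the logical flag (default `has_mutation`).
#' @param n_permutations Number of permutations (default 10000).
#' @param seed Integer seed; the global RNG state is untouched.
#' @param tie_rule `"strict_greater"` (permuted median strictly greater
#'   than observed counts toward p) or `"greater_or_equal"`. Strict
#'   comparison can degenerate to p = 0 under heavy ties (e.g. breadth
#'   saturated at 100%); the inclusive rule is the conservative choice
#'   there.
#' @param statistic `"median"` (default) or `"mean"`.
#' @param add_one If `TRUE`, report the bias-corrected p = (b + 1)/(B + 1)
#'   instead of b/B.
#' @return A `tam_perm` object: a list with `observed`, `k`, `n_included`,
#'   `null_stats`, `p_value`, and the test parameters. Use [tidy()] /
#'   [glance()] for one-row tibble summaries and [autoplot()] for the null
#'   distribution plot.
#' @export
permutation_test <- function(data, metric = depth_tpm, flag = has_mutation,
                             n_permutations = 10000, seed = 1,
                             tie_rule = c("strict_greater", "greater_or_equal"),
                             statistic = c("median", "mean"),
                             add_one = FALSE) {
  tie_rule <- match.arg(tie_rule)
  statistic <- match.arg(statistic)
  metric_q <- enquo(metric); flag_q <- enquo(flag)
  pd <- perm_data(data, metric_q, flag_q)
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  stat_fun <- if (statistic == "median") stats::median else mean
  observed <- stat_fun(pd$values[pd$flagged])
  k <- sum(pd$flagged); n <- length(pd$values)
  values <- pd$values
  # partial-sort median avoids median.default dispatch in the hot loop
  h1 <- (k + 1L) %/% 2L; h2 <- (k + 2L) %/% 2L
  perm_stat <- if (statistic == "median") {
    function(i) {
      s <- sort(values[sample.int(n, k)], partial = c(h1, h2))
      (s[h1] + s[h2]) / 2
    }
  } else {
    function(i) mean(values[sample.int(n, k)])
  }
  null_stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), perm_stat, numeric(1))
  })
  b <- if (tie_rule == "strict_greater") sum(null_stats > observed)
       else sum(null_stats >= observed)
  p <- if (add_one) (b + 1) / (n_permutations + 1) else b / n_permutations
  structure(
    list(metric = as_name(metric_q), statistic = statistic,
         observed = observed, k = k, n_included = n,
         null_stats = null_stats, p_value = p,
         n_permutations = as.integer(n_permutations),
         tie_rule = tie_rule, add_one = add_one, seed = as.integer(seed)),
    class = "tam_perm")
}

# Extract included metric values and flags, validating the test
# preconditions shared by the Monte-Carlo and exhaustive routes.
perm_data <- function(data, metric_q, flag_q) {
  df <- if ("excluded" %in% names(data)) {
    dplyr::filter(data, !.data$excluded)
  } else data
  values <- dplyr::pull(df, !!metric_q)
  flagged <- dplyr::pull(df, !!flag_q)
  if (anyNA(values)) abort("metric contains NA among included windows")
  if (!is.logical(flagged)) abort("flag column must be logical")
  if (sum(flagged) == 0) abort("no mutation-containing windows")
  list(values = values, flagged = flagged)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every k-subset of the included windows and computes the exact
#' fraction whose median satisfies the tie rule against the observed median.
#' Intended as a verification oracle for [permutation_test()] on small
#' instances; refuses instances with more than 10^6 subsets.
#'
#' @inheritParams permutation_test
#' @return A list with `p_value`, `observed`, `k`, `n_included`,
#'   `n_subsets`.
#' @export
exhaustive_pvalue <- function(data, metric = depth_tpm, flag = has_mutation,
                              tie_rule = c("strict_greater", "greater_or_equal"),
                              statistic = c("median", "mean")) {
  tie_rule <- match.arg(tie_rule)
  statistic <- match.arg(statistic)
  pd <- perm_data(data, enquo(metric), enquo(flag))
  k <- sum(pd$flagged); n <- length(pd$values)
  n_subsets <- choose(n, k)
  if (n_subsets > 1e6) {
    abort(sprintf(
      "choose(%d, %d) = %g subsets exceeds 10^6; use permutation_test()",
      n, k, n_subsets))
  }
  stat_fun <- if (statistic == "median") stats::median else mean
  observed <- stat_fun(pd$values[pd$flagged])
  subset_stats <- utils::combn(pd$values, k, stat_fun)
  b <- if (tie_rule == "strict_greater") sum(subset_stats > observed)
       else sum(subset_stats >= observed)
  list(p_value = b / n_subsets, observed = observed, k = k,
       n_included = n, n_subsets = n_subsets)
}

#' GC-matched permutation test
#'
#' Repeats the permutation test with both the flagged set and the sampling
#' universe restricted to windows whose GC fraction lies in a band
#' (inclusive at both ends; default 30--50%, a range chosen to retain the
#' bulk of windows while making GC indistinguishable between flagged
#' windows and the universe). Controls for GC content as a confounder of
#' both transcription and mutation rate.
#'
#' @inheritParams permutation_test
#' @param gc_low,gc_high GC band bounds, inclusive (defaults 0.30, 0.50).
#' @return A `tam_perm` object with extra fields `gc_band`,
#'   `prop_retained` (fraction of included windows inside the band), and
#'   `gc_summary` (quartiles of GC for flagged vs all retained windows).
#' @export
gc_matched_test <- function(data, metric = depth_tpm, flag = has_mutation,
                            gc_low = 0.30, gc_high = 0.50,
                            n_permutations = 10000, seed = 1,
                            tie_rule = c("strict_greater", "greater_or_equal"),
                            statistic = c("median", "mean"),
                            add_one = FALSE) {
  assert_cols(data, "gc_fraction", "windows")
  tie_rule <- match.arg(tie_rule); statistic <- match.arg(statistic)
  flag_q <- enquo(flag)
  df <- if ("excluded" %in% names(data)) {
    dplyr::filter(data, !.data$excluded)
  } else data
  keep <- !is.na(df$gc_fraction) &
    df$gc_fraction >= gc_low & df$gc_fraction <= gc_high
  inside <- df[keep, , drop = FALSE]
  flagged_inside <- dplyr::pull(inside, !!flag_q)
  if (sum(flagged_inside) == 0) {
    abort("no mutation-containing windows within the GC band")
  }
  res <- permutation_test(inside, metric = {{ metric }}, flag = !!flag_q,
                          n_permutations = n_permutations, seed = seed,
                          tie_rule = tie_rule, statistic = statistic,
                          add_one = add_one)
  res$gc_band <- c(gc_low, gc_high)
  res$prop_retained <- nrow(inside) / nrow(df)
  res$gc_summary <- dplyr::bind_rows(
    tibble(set = "all_retained",
           q25 = stats::quantile(inside$gc_fraction, 0.25),
           median = stats::median(inside$gc_fraction),
           q75 = stats::quantile(inside$gc_fraction, 0.75)),
    tibble(set = "flagged",
           q25 = stats::quantile(inside$gc_fraction[flagged_inside], 0.25),
           median = stats::median(inside$gc_fraction[flagged_inside]),
           q75 = stats::quantile(inside$gc_fraction[flagged_inside], 0.75)))
  res
}

#' Expression-quartile enrichment of mutated windows
#'
#' Ranks included windows by the metric (ties broken by a seeded random
#' ranking so the four groups are equal-sized and the uniform 0.25 null is
#' exact even with many zero-expression windows), splits them into
#' quartiles, and reports the fraction of mutation-containing windows
#' falling in each.
#'
#' @inheritParams permutation_test
#' @param seed Seed for the random tie-break.
#' @return A `tam_quartiles` tibble: `quartile` (1 = lowest expression),
#'   `n_windows`, `n_flagged`, `flagged_fraction`, `metric_min`,
#'   `metric_max`.
#' @export
quartile_enrichment <- function(data, metric = depth_tpm,
                                flag = has_mutation, seed = 1) {
  pd <- perm_data(data, enquo(metric), enquo(flag))
  n <- length(pd$values)
  if (n < 4) abort("need at least 4 included windows for quartiles")
  rk <- withr::with_seed(as.integer(seed),
                         order(order(pd$values, stats::runif(n))))
  quartile <- dplyr::ntile(rk, 4)
  total_flagged <- sum(pd$flagged)
  out <- tibble(quartile = quartile, value = pd$values,
                flagged = pd$flagged) |>
    dplyr::group_by(.data$quartile) |>
    dplyr::summarise(n_windows = dplyr::n(),
                     n_flagged = sum(.data$flagged),
                     metric_min = min(.data$value),
                     metric_max = max(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(flagged_fraction = .data$n_flagged / total_flagged,
                  .after = "n_flagged")
  class(out) <- c("tam_quartiles", class(out))
  out
}
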