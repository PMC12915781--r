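#' Run the full permutation-test battery
#'
#' One permutation test per combination of expression profile, genotype,
#' metric, and (optionally) mutation-type stratum — the design used to ask
#' whether elevated expression in mutated windows is robust across
#' genotypes, developmental stages, and conditions. Per-row seeds are
#' derived reproducibly from the master seed and the row key, so the whole
#' battery is deterministic and rows do not share a random stream.
#'
#' @param profiles Named list of quantified window tibbles (from
#'   [quantify_windows()]), one per expression profile.
#' @param mutations Mutation tibble with a `genotype` column; one flag set
#'   is computed per genotype.
#' @param metrics Character vector of metric columns (default
#'   `c("depth_tpm", "breadth_pct")`).
#' @param by_type If `TRUE`, add one stratum per mutation type alongside
#'   the pooled `"all"` stratum.
#' @param gc_band Optional length-2 numeric: restrict every test to windows
#'   with GC fraction inside this inclusive band (the GC-matched control).
#' @inheritParams permutation_test
#' @return A tibble with one row per test: identifiers, `status` (`"ok"` or
#'   `"skipped"` with `reason`), `n_included`, `k`, `observed`, `p_value`,
#'   `p_bh` (Benjamini-Hochberg across the non-skipped rows, reported
#'   alongside the raw p, never substituted for it), and sampling
#'   parameters.
#' @export
run_battery <- function(profiles, mutations, metrics = c("depth_tpm", "breadth_pct"),
                        by_type = FALSE, gc_band = NULL,
                        n_permutations = 10000, seed = 1,
                        tie_rule = c("strict_greater", "greater_or_equal"),
                        statistic = c("median", "mean"), add_one = FALSE) {
  tie_rule <- match.arg(tie_rule); statistic <- match.arg(statistic)
  if (length(profiles) == 0) abort("need at least one expression profile")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- purrr::imap_chr(
      profiles, function(p, i) attr(p, "profile") %||% paste0("profile", i))
  }
  genotypes <- unique(mutations$genotype)
  if (length(genotypes) == 0) abort("mutation set is empty")
  strata <- if (by_type) c("all", sort(unique(mutations$type))) else "all"

  grid <- tidyr::expand_grid(profile = names(profiles),
                             genotype = genotypes,
                             metric = metrics,
                             type_stratum = strata)
  rows <- purrr::pmap(grid, function(profile, genotype, metric, type_stratum) {
    row_seed <- derive_seed(seed, paste(profile, genotype, metric,
                                        type_stratum, sep = "|"))
    muts <- mutations[mutations$genotype == genotype, , drop = FALSE]
    if (type_stratum != "all") {
      muts <- muts[muts$type == type_stratum, , drop = FALSE]
    }
    base <- tibble(profile = profile, genotype = genotype, metric = metric,
                   type_stratum = type_stratum, seed = row_seed)
    if (nrow(muts) == 0) {
      return(dplyr::mutate(base, status = "skipped",
                           reason = "no mutations in stratum",
                           n_included = NA_integer_, k = NA_integer_,
                           observed = NA_real_, p_value = NA_real_))
    }
    flagged <- suppressWarnings(
      flag_mutation_windows(muts, profiles[[profile]]))
    included <- if ("excluded" %in% names(flagged)) {
      flagged[!flagged$excluded, , drop = FALSE]
    } else flagged
    if (sum(included$has_mutation) == 0) {
      return(dplyr::mutate(base, status = "skipped",
                           reason = "no mutation-containing included windows",
                           n_included = nrow(included), k = 0L,
                           observed = NA_real_, p_value = NA_real_))
    }
    res <- if (is.null(gc_band)) {
      permutation_test(flagged, metric = !!rlang::sym(metric),
                       n_permutations = n_permutations, seed = row_seed,
                       tie_rule = tie_rule, statistic = statistic,
                       add_one = add_one)
    } else {
      gc_matched_test(flagged, metric = !!rlang::sym(metric),
                      gc_low = gc_band[1], gc_high = gc_band[2],
                      n_permutations = n_permutations, seed = row_seed,
                      tie_rule = tie_rule, statistic = statistic,
                      add_one = add_one)
    }
    dplyr::mutate(base, status = "ok", reason = NA_character_,
                  n_included = res$n_included, k = res$k,
                  observed = res$observed, p_value = res$p_value)
  })
  out <- purrr::list_rbind(rows)
  out$p_bh <- NA_real_
  ok <- out$status == "ok"
  out$p_bh[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  dplyr::mutate(out, n_permutations = as.integer(n_permutations),
                tie_rule = tie_rule, statistic = statistic,
                master_seed = as.integer(seed))
}
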