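test_that("single-flag instances give hand-enumerable p-values", {
  w <- value_windows(c(1, 2, 3, 4, 100), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # no draw can exceed 100: p = 0 exactly for any number of permutations
  expect_equal(permutation_test(w, n_permutations = 500, seed = 1)$p_value, 0)
  expect_equal(exhaustive_pvalue(w)$p_value, 0)

  wlow <- value_windows(c(1, 2, 3, 4, 100), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # exactly 4 of the 5 single-window draws exceed 1
  expect_equal(exhaustive_pvalue(wlow)$p_value, 0.8)
  mc <- permutation_test(wlow, n_permutations = 5000, seed = 2)$p_value
  expect_lt(abs(mc - 0.8), 3 * sqrt(0.8 * 0.2 / 5000))
})

test_that("tie degeneracy distinguishes the two tie rules", {
  w <- value_windows(rep(7, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(permutation_test(w, n_permutations = 100, seed = 1,
                                tie_rule = "strict_greater")$p_value, 0)
  expect_equal(permutation_test(w, n_permutations = 100, seed = 1,
                                tie_rule = "greater_or_equal")$p_value, 1)
  # flagged set = all windows: every permuted median equals the observed
  wall <- value_windows(c(1, 5, 9), rep(TRUE, 3))
  expect_equal(permutation_test(wall, n_permutations = 100, seed = 1)$p_value, 0)
  expect_equal(exhaustive_pvalue(wall)$p_value, 0)
  expect_equal(exhaustive_pvalue(wall, tie_rule = "greater_or_equal")$p_value, 1)
})

test_that("exhaustive enumeration matches independent subset enumeration", {
  # n = 4, k = 2, values 1..4, flagged {1,2}: subset medians
  # {1.5, 2, 2.5, 2.5, 3, 3.5} -> 5/6 strictly exceed 1.5
  w <- value_windows(1:4, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(exhaustive_pvalue(w)$p_value, 5 / 6)
  set.seed(20)
  for (i in 1:5) {
    vals <- round(rexp(10), 2)
    flg <- seq_len(10) %in% sample.int(10, 3)
    w <- value_windows(vals, flg)
    expect_equal(exhaustive_pvalue(w)$p_value,
                 oracle_exact_p(vals, which(flg)))
    expect_equal(exhaustive_pvalue(w, tie_rule = "greater_or_equal")$p_value,
                 oracle_exact_p(vals, which(flg), "greater_or_equal"))
  }
  big <- value_windows(rnorm(40), c(rep(TRUE, 15), rep(FALSE, 25)))
  expect_error(exhaustive_pvalue(big), "10\\^6")
})

test_that("Monte-Carlo p converges to the exact p", {
  # values 1..12, k = 3, flagged median 2: oracle over all C(12,3) subsets
  w <- value_windows(as.numeric(1:12), c(rep(TRUE, 3), rep(FALSE, 9)))
  exact <- exhaustive_pvalue(w)$p_value
  mc <- permutation_test(w, n_permutations = 10000, seed = 4)$p_value
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 10000))
})

test_that("p-values are reproducible from seed and monotone-invariant", {
  set.seed(9)
  w <- value_windows(rlnorm(30), seq_len(30) %in% sample.int(30, 8))
  a <- permutation_test(w, n_permutations = 1000, seed = 11)
  b <- permutation_test(w, n_permutations = 1000, seed = 11)
  expect_identical(a$null_stats, b$null_stats)
  expect_identical(a$p_value, b$p_value)
  # strictly monotone transform of the metric preserves the p-value
  w2 <- dplyr::mutate(w, depth_tpm = log1p(depth_tpm) * 3 + 1)
  expect_equal(permutation_test(w2, n_permutations = 1000, seed = 11)$p_value,
               a$p_value)
  # excluded windows do not enter the universe
  w3 <- dplyr::bind_rows(w, dplyr::mutate(value_windows(rep(1e9, 5),
                                                        rep(FALSE, 5)),
                                          excluded = TRUE))
  expect_equal(permutation_test(w3, n_permutations = 1000, seed = 11)$p_value,
               a$p_value)
  expect_error(permutation_test(value_windows(1:3, rep(FALSE, 3))),
               "no mutation-containing")
})

test_that("GC-matched testing restricts the universe to the band", {
  set.seed(5)
  vals <- rlnorm(40)
  w <- value_windows(vals, seq_len(40) %in% sample.int(40, 6))
  w$gc_fraction <- seq(0.25, 0.64, by = 0.01)
  res <- gc_matched_test(w, n_permutations = 500, seed = 3)
  # inclusive bounds: 0.30 and 0.50 retained, 0.29 not
  expect_equal(res$n_included, sum(w$gc_fraction >= 0.30 & w$gc_fraction <= 0.50))
  expect_equal(res$gc_band, c(0.30, 0.50))
  expect_true(res$prop_retained < 1)

  # uniform GC: the filter is the identity and p matches given the seed
  wu <- dplyr::mutate(w, gc_fraction = 0.40)
  expect_equal(gc_matched_test(wu, n_permutations = 500, seed = 3)$p_value,
               permutation_test(wu, n_permutations = 500, seed = 3)$p_value)

  whigh <- dplyr::mutate(w, gc_fraction = dplyr::if_else(has_mutation, 0.60,
                                                         gc_fraction))
  expect_error(gc_matched_test(whigh), "GC band")
})

test_that("quartile enrichment reports flagged fractions per rank quartile", {
  w <- value_windows(c(0, 0, 0, 0, 10, 20, 30, 40),
                     c(rep(FALSE, 7), TRUE))
  q <- quartile_enrichment(w, seed = 1)
  expect_equal(q$n_windows, rep(2L, 4))
  expect_equal(q$flagged_fraction, c(0, 0, 0, 1))
  expect_equal(sum(q$flagged_fraction), 1)

  # all windows flagged: fractions 0.25 each (equal group sizes)
  wall <- value_windows(rlnorm(16), rep(TRUE, 16))
  qall <- quartile_enrichment(wall, seed = 2)
  expect_equal(qall$flagged_fraction, rep(0.25, 4))

  expect_error(quartile_enrichment(value_windows(1:3, c(TRUE, FALSE, FALSE))),
               "at least 4")
  # seeded tie-break keeps groups equal-sized even with heavy ties
  wt <- value_windows(rep(0, 10), c(TRUE, rep(FALSE, 9)))
  qt <- quartile_enrichment(wt, seed = 3)
  expect_equal(sort(qt$n_windows), c(2L, 2L, 3L, 3L))
  expect_equal(sum(qt$n_flagged), 1L)
})

test_that("battery covers the stratum grid deterministically", {
  set.seed(6)
  cfg <- small_sim_config(seed = 21)
  tab <- simulate_tables(cfg)
  w <- apply_mask(make_windows(tab$index, 1e4, 1e4), tab$mask)
  profiles <- lapply(tab$coverage, quantify_windows, windows = w,
                     index = tab$index, mask = tab$mask)
  batt <- run_battery(profiles, tab$mutations, metrics = "depth_tpm",
                      n_permutations = 200, seed = 17)
  expect_equal(nrow(batt), length(profiles) * 2L)  # 2 genotypes
  expect_true(all(batt$status == "ok"))
  expect_false(any(duplicated(batt$seed)))
  batt2 <- run_battery(profiles, tab$mutations, metrics = "depth_tpm",
                       n_permutations = 200, seed = 17)
  expect_identical(batt, batt2)

  both <- run_battery(profiles[1], tab$mutations[tab$mutations$genotype == "g1", ],
                      metrics = c("depth_tpm", "breadth_pct"),
                      n_permutations = 100, seed = 3)
  expect_equal(nrow(both), 2L)

  # type stratification: absent strata are recorded as skipped
  subs_only <- dplyr::filter(tab$mutations, type == "base_substitution",
                             genotype == "g1")
  bt <- run_battery(profiles[1], subs_only, metrics = "depth_tpm",
                    by_type = TRUE, n_permutations = 100, seed = 5)
  expect_setequal(bt$type_stratum, c("all", "base_substitution"))
  expect_true(all(bt$status == "ok"))
  # BH column accompanies, never replaces, the raw p
  expect_true(all(c("p_value", "p_bh") %in% names(bt)))
})
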