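# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing is read from disk except files the helpers themselves write
# to tempdir().

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

write_bed3 <- function(df, path = tempfile(fileext = ".bed")) {
  readr::write_tsv(df, path, col_names = FALSE)
  path
}

write_bedgraph <- function(df, path = tempfile(fileext = ".bedGraph")) {
  readr::write_tsv(df, path, col_names = FALSE)
  path
}

# A minimal window table with injected metric values and flags, for testing
# the statistics in isolation from quantification.
value_windows <- function(values, flagged, metric = "depth_tpm") {
  n <- length(values)
  out <- tibble::tibble(
    chrom = "chr1",
    start = (seq_len(n) - 1L) * 100L,
    end = seq_len(n) * 100L,
    window_id = sprintf("w%03d", seq_len(n)),
    is_canonical = TRUE,
    effective_length = 100L,
    excluded = FALSE,
    gc_fraction = 0.4,
    has_mutation = flagged)
  out[[metric]] <- values
  out
}

# Uniform-coverage bedGraph tibble over given intervals.
cov_tbl <- function(chrom, start, end, coverage) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), coverage = as.numeric(coverage))
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chromosomes = 1, chromosome_length = 2e5,
             n_profiles = 2, n_genotypes = 2, mutations_per_genotype = 15,
             ...)
}

# Geometry used by the calibration and power checks: 1 Mb genome, 10 kb
# tiling, one genotype of 100 mutations, one profile.
calibration_config <- function(seed, effect_size = 0) {
  sim_config(seed = seed, n_chromosomes = 1, chromosome_length = 1e6,
             n_profiles = 1, n_genotypes = 1, mutations_per_genotype = 100,
             effect_size = effect_size)
}

# One end-to-end pass at calibration geometry: simulate in memory, quantify
# the canonical tiling, flag, test. Returns the tam_perm object.
calibration_test <- function(seed, effect_size = 0,
                             tie_rule = "greater_or_equal",
                             n_permutations = 10000) {
  cfg <- calibration_config(seed, effect_size)
  tab <- simulate_tables(cfg)
  w <- apply_mask(make_windows(tab$index, 1e4, 1e4), tab$mask)
  prof <- quantify_windows(tab$coverage[[1]], w, tab$index, tab$mask)
  flagged <- suppressWarnings(flag_mutation_windows(tab$mutations, prof))
  permutation_test(flagged, n_permutations = n_permutations, seed = seed,
                   tie_rule = tie_rule)
}
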