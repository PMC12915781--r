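# Independent brute-force oracles. These deliberately use per-base arrays
# and all-pairs scans instead of the package's interval/Rle machinery so the
# two routes share no code.

# Per-base-array quantification: depth rate, TPM (canonical-tiling
# normalisation) and breadth for every window.
oracle_quantify <- function(cov, windows, mask, index) {
  base_cov <- lapply(seq_len(nrow(index)), function(i) {
    v <- numeric(index$length[i])
    ci <- cov[cov$chrom == index$chrom[i], , drop = FALSE]
    for (r in seq_len(nrow(ci))) {
      idx <- (ci$start[r] + 1):ci$end[r]
      v[idx] <- v[idx] + ci$coverage[r]
    }
    v
  })
  names(base_cov) <- index$chrom
  unmasked <- lapply(seq_len(nrow(index)), function(i) {
    u <- rep(TRUE, index$length[i])
    mi <- mask[mask$chrom == index$chrom[i], , drop = FALSE]
    for (r in seq_len(nrow(mi))) u[(mi$start[r] + 1):mi$end[r]] <- FALSE
    u
  })
  names(unmasked) <- index$chrom

  n <- nrow(windows)
  eff <- integer(n); covsum <- numeric(n); covered <- integer(n)
  for (i in seq_len(n)) {
    idx <- (windows$start[i] + 1):windows$end[i]
    u <- unmasked[[windows$chrom[i]]][idx]
    v <- base_cov[[windows$chrom[i]]][idx]
    eff[i] <- sum(u)
    covsum[i] <- sum(v[u])
    covered[i] <- sum(v[u] >= 1)
  }
  rate <- ifelse(eff == 0, NA_real_, covsum / eff)
  total <- sum(rate[windows$is_canonical & eff > 0])
  tpm <- if (is.na(total) || total == 0) ifelse(eff == 0, NA_real_, 0) else
    ifelse(eff == 0, NA_real_, 1e6 * rate / total)
  tibble::tibble(window_id = windows$window_id,
                 effective_length = eff,
                 coverage_sum = covsum,
                 depth_tpm = tpm,
                 breadth_pct = ifelse(eff == 0, NA_real_, 100 * covered / eff))
}

# All-pairs mutation/window overlap: anchor base in [start, end).
oracle_overlap <- function(mutations, windows) {
  hits <- logical(nrow(windows))
  counts <- integer(nrow(windows))
  for (m in seq_len(nrow(mutations))) {
    a <- mutations$pos[m] - 1L
    sel <- windows$chrom == mutations$chrom[m] &
      windows$start <= a & a < windows$end
    hits <- hits | sel
    counts <- counts + as.integer(sel)
  }
  tibble::tibble(window_id = windows$window_id, has_mutation = hits,
                 n_mutations = counts)
}

# Exact permutation p-value by explicit subset enumeration over indices
# (independent of the package's combn-over-values route).
oracle_exact_p <- function(values, flagged_idx, tie_rule = "strict_greater") {
  k <- length(flagged_idx)
  obs <- stats::median(values[flagged_idx])
  subsets <- utils::combn(length(values), k)
  meds <- apply(subsets, 2, function(ix) stats::median(values[ix]))
  if (tie_rule == "strict_greater") mean(meds > obs) else mean(meds >= obs)
}
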