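#' Read a per-base coverage track from a bedGraph file
#'
#' Consumes the 4-column output of `bedtools genomecov -bga` (or any
#' bedGraph): `chrom`, `start`, `end`, `value` with 0-based half-open
#' coordinates. Bases not covered by any interval have coverage 0;
#' overlapping intervals sum, so multiple libraries for one expression
#' profile can be merged by concatenating their tracks.
#'
#' @param path Path to a bedGraph file.
#' @param index Genome index tibble; intervals are checked against it.
#' @param profile Optional label (e.g. "genotype.stage.condition") attached
#'   as the `profile` attribute.
#' @return A tibble `chrom`, `start`, `end`, `coverage`.
#' @export
read_coverage <- function(path, index, profile = NULL) {
  if (!file.exists(path)) abort(sprintf("coverage bedGraph not found: %s", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- tibble(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                start = BiocGenerics::start(gr) - 1L,
                end   = BiocGenerics::end(gr),
                coverage = as.numeric(gr$score))
  validate_coverage(cov, index)
  attr(cov, "profile") <- profile
  cov
}

validate_coverage <- function(cov, index) {
  assert_cols(cov, c("chrom", "start", "end", "coverage"), "coverage track")
  if (any(cov$coverage < 0)) abort("coverage values must be non-negative")
  unknown <- setdiff(unique(cov$chrom), index$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("coverage names unknown chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  chk <- dplyr::left_join(cov, index, by = "chrom")
  if (any(chk$start < 0 | chk$end > chk$length)) {
    abort("coverage interval outside chromosome bounds")
  }
  invisible(cov)
}

# Per-chromosome run-length encodings used by all quantification: coverage
# with masked bases zeroed, and the unmasked indicator.
chrom_rles <- function(cov, mask, chrom, len) {
  ci <- cov[cov$chrom == chrom, , drop = FALSE]
  if (nrow(ci) > 0) {
    cov_rle <- IRanges::coverage(IRanges::IRanges(ci$start + 1L, ci$end),
                                 weight = ci$coverage, width = len)
  } else {
    cov_rle <- S4Vectors::Rle(0, len)
  }
  mi <- mask[mask$chrom == chrom, , drop = FALSE]
  if (nrow(mi) > 0) {
    masked <- IRanges::coverage(IRanges::IRanges(mi$start + 1L, mi$end),
                                width = len) > 0L
  } else {
    masked <- S4Vectors::Rle(FALSE, len)
  }
  unmasked <- (!masked) + 0L
  list(coverage = cov_rle * unmasked, unmasked = unmasked)
}

# Shared engine for window- and gene-level quantification. For each region:
# coverage sum and covered-base count over unmasked bases, effective length,
# rate = sum / effective_length; TPM rescales rates so the normalisation
# universe sums to one million.
quantify_regions <- function(cov, regions, index, mask, universe) {
  mask <- merge_mask(mask, index)
  n <- nrow(regions)
  cov_sum <- numeric(n); covered <- numeric(n); eff <- numeric(n)
  for (chrom in unique(regions$chrom)) {
    len <- index$length[index$chrom == chrom]
    if (length(len) != 1) abort(sprintf("unknown chromosome in regions: %s", chrom))
    rl <- chrom_rles(cov, mask, chrom, len)
    ri <- which(regions$chrom == chrom)
    v <- IRanges::Views(rl$coverage, start = regions$start[ri] + 1L,
                        end = regions$end[ri])
    cov_sum[ri] <- IRanges::viewSums(v)
    ind <- (rl$coverage >= 1) + 0L
    covered[ri] <- IRanges::viewSums(
      IRanges::Views(ind, start = regions$start[ri] + 1L, end = regions$end[ri]))
    eff[ri] <- IRanges::viewSums(
      IRanges::Views(rl$unmasked, start = regions$start[ri] + 1L,
                     end = regions$end[ri]))
  }
  excluded <- eff == 0
  rate <- ifelse(excluded, NA_real_, cov_sum / eff)
  in_universe <- universe & !excluded
  total <- sum(rate[in_universe])
  tpm <- if (is.na(total) || total == 0) {
    ifelse(excluded, NA_real_, 0)
  } else {
    ifelse(excluded, NA_real_, 1e6 * rate / total)
  }
  dplyr::mutate(regions,
                effective_length = as.integer(eff),
                excluded = excluded,
                coverage_sum = cov_sum,
                depth_tpm = tpm,
                breadth_pct = ifelse(excluded, NA_real_, 100 * covered / eff))
}

#' Quantify expression depth and breadth per window
#'
#' For window *i*, the coverage rate is the sum of per-base coverage over its
#' unmasked bases divided by its effective (unmasked) length. Depth is the
#' rate rescaled to transcripts-per-million: rates are summed over the
#' canonical non-overlapping tiling (so overlapping sliding windows do not
#' double-count the library) and each window's rate is multiplied by
#' 10^6 / total. Breadth is the percentage of unmasked bases with coverage
#' of at least one read.
#'
#' @param coverage Coverage tibble from [read_coverage()].
#' @param windows Window tibble from [make_windows()] (optionally already
#'   masked; the mask given here is authoritative for coverage).
#' @param index Genome index tibble.
#' @param mask Optional mask tibble.
#' @return The window tibble with `coverage_sum`, `depth_tpm`, `breadth_pct`,
#'   and updated `effective_length` / `excluded` columns. Excluded windows
#'   carry `NA` metrics. The coverage track's `profile` attribute propagates.
#' @export
quantify_windows <- function(coverage, windows, index, mask = NULL) {
  assert_cols(windows, c("chrom", "start", "end", "is_canonical"), "windows")
  out <- quantify_regions(coverage, windows, index, mask,
                          universe = windows$is_canonical)
  out <- keep_window_attrs(out, windows)
  attr(out, "profile") <- attr(coverage, "profile")
  out
}

#' @rdname quantify_windows
#' @export
window_depth <- function(coverage, windows, index, mask = NULL) {
  dplyr::select(quantify_windows(coverage, windows, index, mask),
                -"breadth_pct")
}

#' @rdname quantify_windows
#' @export
window_breadth <- function(coverage, windows, index, mask = NULL) {
  dplyr::select(quantify_windows(coverage, windows, index, mask),
                -"depth_tpm", -"coverage_sum")
}

#' Read gene records from a GFF3 annotation
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (default `"gene"`).
#' @return A tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open,
#'   full genomic span).
#' @export
read_genes <- function(path, feature = "gene") {
  if (!file.exists(path)) abort(sprintf("GFF3 not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("gene%06d", seq_along(gr))
  tibble(gene_id = ids,
         chrom = as.character(GenomeInfoDb::seqnames(gr)),
         start = BiocGenerics::start(gr) - 1L,
         end   = BiocGenerics::end(gr))
}

#' Quantify expression depth and breadth per gene
#'
#' Same rate/TPM definitions as [quantify_windows()], computed over each
#' gene's full genomic span, with the TPM normalisation total taken over all
#' included genes. Genes with no unmasked bases are flagged `excluded`.
#'
#' @param coverage Coverage tibble.
#' @param genes Gene tibble from [read_genes()].
#' @param index Genome index tibble.
#' @param mask Optional mask tibble.
#' @return The gene tibble with expression columns appended.
#' @export
gene_expression <- function(coverage, genes, index, mask = NULL) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  out <- quantify_regions(coverage, genes, index, mask,
                          universe = rep(TRUE, nrow(genes)))
  attr(out, "profile") <- attr(coverage, "profile")
  out
}
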