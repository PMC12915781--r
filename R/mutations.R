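#' Classify a mutation by its REF/ALT alleles
#'
#' Single-base equal-length alleles are base substitutions; a longer ALT is
#' an insertion and a shorter ALT a deletion. Equal-length multi-base
#' replacements (MNPs) are rejected: they are not one of the three
#' categories the analysis stratifies on.
#'
#' @param ref,alt Character vectors of REF and ALT alleles.
#' @return Character vector: `"base_substitution"`, `"insertion"`, or
#'   `"deletion"`.
#' @export
#' @examples
#' classify_mutation_type(c("G", "C", "TAC"), c("C", "CGG", "T"))
classify_mutation_type <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt)) || anyNA(ref) || anyNA(alt)) {
    abort("REF and ALT alleles must be non-empty")
  }
  lr <- nchar(ref); la <- nchar(alt)
  bad <- lr == la & lr > 1
  if (any(bad)) {
    abort(sprintf("equal-length multi-base replacement (MNP) not supported: %s>%s",
                  ref[which(bad)[1]], alt[which(bad)[1]]))
  }
  dplyr::case_when(lr == la ~ "base_substitution",
                   la > lr ~ "insertion",
                   TRUE ~ "deletion")
}

#' Read mutation calls from a VCF or TSV file
#'
#' Accepts a VCF 4.x file (plain or bgzipped) or a headered TSV with columns
#' `chrom`, `pos`, `ref`, `alt` and optionally `genotype`. Multi-allelic VCF
#' records are split into one mutation per ALT allele. Symbolic and breakend
#' alleles are rejected.
#'
#' @param path Input path.
#' @param genotype_label Label for the MA line these calls belong to;
#'   overrides any `genotype` column.
#' @param index Optional genome index; positions are bounds-checked when
#'   given.
#' @return A tibble `mutation_id`, `chrom`, `pos` (1-based anchor), `ref`,
#'   `alt`, `type`, `genotype`.
#' @export
read_mutations <- function(path, genotype_label = NULL, index = NULL) {
  if (!file.exists(path)) abort(sprintf("mutation file not found: %s", path))
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path) || startsWith(first, "##fileformat")
  if (is_vcf) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix[, , drop = FALSE], stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      mut <- tibble(chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    genotype = character())
    } else {
      mut <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    genotype = NA_character_)
      mut <- tidyr::separate_rows(mut, "alt", sep = ",")
    }
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE)
    names(raw) <- tolower(names(raw))
    assert_cols(raw, c("chrom", "pos", "ref", "alt"), "mutation TSV")
    mut <- tibble(chrom = as.character(raw$chrom), pos = as.integer(raw$pos),
                  ref = as.character(raw$ref), alt = as.character(raw$alt),
                  genotype = if ("genotype" %in% names(raw))
                    as.character(raw$genotype) else NA_character_)
    mut <- tidyr::separate_rows(mut, "alt", sep = ",")
  }
  symbolic <- grepl("[][<>]", mut$alt) | grepl("[][<>]", mut$ref) |
    mut$alt == "*"
  if (any(symbolic)) {
    abort(sprintf("symbolic/breakend allele not supported: %s at %s:%d",
                  mut$alt[which(symbolic)[1]], mut$chrom[which(symbolic)[1]],
                  mut$pos[which(symbolic)[1]]))
  }
  if (!is.null(genotype_label)) mut$genotype <- genotype_label
  if (!is.null(index)) {
    chk <- dplyr::left_join(mut, index, by = "chrom")
    if (anyNA(chk$length)) {
      abort(sprintf("mutation on unknown chromosome: %s",
                    chk$chrom[which(is.na(chk$length))[1]]))
    }
    if (any(mut$pos < 1 | mut$pos > chk$length)) {
      abort("mutation position outside chromosome bounds")
    }
  }
  dplyr::mutate(mut,
                type = classify_mutation_type(.data$ref, .data$alt),
                mutation_id = sprintf("%s:%d:%s>%s", .data$chrom, .data$pos,
                                      .data$ref, .data$alt),
                .before = 1)
}

# GRanges of the single anchor base of each mutation (VCF POS; indels are
# assigned by their leftmost-aligned anchor, not their span).
mutation_anchors <- function(mutations) {
  GenomicRanges::GRanges(mutations$chrom,
                         IRanges::IRanges(mutations$pos, width = 1L))
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

#' Map each mutation to the windows it overlaps
#'
#' A mutation overlaps a window iff its anchor base lies in
#' `[start, end)`; with sliding windows one mutation can hit up to
#' `size / step` windows.
#'
#' @param mutations Mutation tibble from [read_mutations()].
#' @param windows Window (or gene) tibble.
#' @return A tibble `mutation_id`, `genotype`, `type`, `window_id` with one
#'   row per (mutation, overlapped window) pair.
#' @export
mutation_window_map <- function(mutations, windows) {
  assert_cols(mutations, c("mutation_id", "chrom", "pos"), "mutations")
  id_col <- if ("window_id" %in% names(windows)) "window_id" else "gene_id"
  ov <- GenomicRanges::findOverlaps(mutation_anchors(mutations),
                                    regions_granges(windows))
  tibble(mutation_id = mutations$mutation_id[S4Vectors::queryHits(ov)],
         genotype = mutations$genotype[S4Vectors::queryHits(ov)],
         type = mutations$type[S4Vectors::queryHits(ov)],
         window_id = windows[[id_col]][S4Vectors::subjectHits(ov)])
}

#' Flag windows that contain mutations
#'
#' Adds pooled overlap flags to a window tibble. Mutations whose only
#' overlapping windows are excluded (fully masked) trigger a warning and
#' contribute no included window.
#'
#' @param mutations Mutation tibble; filter it by `genotype` or `type` first
#'   for stratified flags (pooled flags equal the union of per-stratum
#'   flags).
#' @param windows Window tibble (typically with expression columns already
#'   joined, as from [quantify_windows()]).
#' @return The window tibble with `n_mutations` and `has_mutation` appended.
#' @export
flag_mutation_windows <- function(mutations, windows) {
  assert_cols(windows, c("chrom", "start", "end", "window_id"), "windows")
  map <- mutation_window_map(mutations, windows)
  counts <- dplyr::count(map, .data$window_id, name = "n_mutations")
  out <- dplyr::left_join(windows, counts, by = "window_id")
  out <- dplyr::mutate(out,
                       n_mutations = as.integer(.data$n_mutations %na% 0L),
                       has_mutation = .data$n_mutations > 0L)
  if ("excluded" %in% names(out)) {
    hit_included <- unique(map$window_id[
      map$window_id %in% out$window_id[!out$excluded]])
    orphaned <- setdiff(unique(map$mutation_id),
                        map$mutation_id[map$window_id %in% hit_included])
    lost <- setdiff(unique(mutations$mutation_id), map$mutation_id)
    if (length(orphaned) + length(lost) > 0) {
      warn(sprintf("%d mutation(s) overlap no included window",
                   length(orphaned) + length(lost)))
    }
  }
  keep_window_attrs(out, windows)
}

#' Flag genes that contain mutations
#'
#' A gene is flagged iff at least one mutation anchor lies within its span;
#' per-type mutation counts are reported alongside so mutation-type
#' stratified gene analyses can reuse the same table.
#'
#' @param mutations Mutation tibble.
#' @param genes Gene tibble (typically from [gene_expression()]).
#' @return The gene tibble with `n_mutations`, `has_mutation`, and one
#'   `n_<type>` column per mutation type.
#' @export
genic_overlap <- function(mutations, genes) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  map <- mutation_window_map(mutations, genes)
  counts <- dplyr::count(map, .data$window_id, name = "n_mutations")
  out <- dplyr::left_join(genes, counts,
                          by = c(gene_id = "window_id"))
  out <- dplyr::mutate(out,
                       n_mutations = as.integer(.data$n_mutations %na% 0L),
                       has_mutation = .data$n_mutations > 0L)
  for (ty in c("base_substitution", "insertion", "deletion")) {
    tc <- dplyr::count(map[map$type == ty, ], .data$window_id, name = "nt")
    idx <- match(out$gene_id, tc$window_id)
    out[[paste0("n_", ty)]] <- as.integer(tc$nt[idx] %na% 0L)
  }
  out
}
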