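#' Read the sequence index of a genome FASTA
#'
#' Builds the coordinate space for all downstream window operations: one row
#' per sequence, in file order, with its length in base pairs.
#'
#' @param fasta Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @return A tibble with columns `chrom` (character) and `length` (integer bp).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' read_genome_index(fa)
read_genome_index <- function(fasta) {
  seqs <- read_genome(fasta)
  if (length(seqs) == 0) abort("FASTA contains no sequences")
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    abort("FASTA records must all be named")
  }
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate sequence name(s) in FASTA: %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  tibble(chrom = nm, length = Biostrings::width(seqs))
}

# Load a genome as a DNAStringSet; FASTA headers are truncated at the first
# whitespace (the conventional sequence identifier).
read_genome <- function(fasta) {
  if (methods::is(fasta, "DNAStringSet")) return(fasta)
  if (!file.exists(fasta)) abort(sprintf("FASTA file not found: %s", fasta))
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read a BED3 mask into merged, sorted intervals
#'
#' Masked regions (repeats, low-confidence calls) are excluded from both
#' mutation calling upstream and the expression denominators here; the same
#' mask must be applied to both for depth to be comparable.
#'
#' @param path Path to a BED3 file (0-based half-open).
#' @param index Optional genome index tibble from [read_genome_index()]; when
#'   given, intervals are checked against chromosome bounds.
#' @return A tibble `chrom`, `start`, `end` (0-based half-open), merged and
#'   sorted, non-overlapping.
#' @export
read_mask <- function(path, index = NULL) {
  if (!file.exists(path)) abort(sprintf("mask BED not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (ncol(raw) < 3) abort("mask BED must have at least 3 columns")
  bed <- tibble(chrom = as.character(raw[[1]]),
                start = as.integer(raw[[2]]),
                end   = as.integer(raw[[3]]))
  bad <- which(!(bed$start < bed$end))
  if (length(bad) > 0) {
    abort(sprintf("malformed BED interval (start >= end) at line %d of %s",
                  bad[1], path))
  }
  merge_mask(bed, index)
}

# Normalise a mask tibble: bounds-check, sort, merge overlapping intervals.
merge_mask <- function(mask, index = NULL) {
  if (is.null(mask) || nrow(mask) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  assert_cols(mask, c("chrom", "start", "end"), "mask")
  if (!is.null(index)) {
    chk <- dplyr::left_join(mask, index, by = "chrom")
    if (anyNA(chk$length)) {
      abort(sprintf("mask names unknown chromosome(s): %s",
                    paste(unique(chk$chrom[is.na(chk$length)]), collapse = ", ")))
    }
    if (any(chk$start < 0 | chk$end > chk$length)) {
      abort("mask interval outside chromosome bounds")
    }
  }
  parts <- split(mask, mask$chrom)
  out <- purrr::imap(parts, function(df, chrom) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    tibble(chrom = chrom,
           start = IRanges::start(ir) - 1L,
           end   = IRanges::end(ir))
  })
  dplyr::arrange(purrr::list_rbind(out), .data$chrom, .data$start)
}

#' Build sliding windows over a genome
#'
#' Windows of `size` bp slide in increments of `step` bp from the start of
#' each chromosome; the trailing window is truncated at the chromosome end
#' (mirroring `bedtools makewindows`). Windows whose start is a multiple of
#' `size` form the canonical non-overlapping tiling that downstream TPM
#' normalisation uses as its universe.
#'
#' @param index Genome index tibble from [read_genome_index()].
#' @param size Nominal window size in bp (default 10000).
#' @param step Slide increment in bp; must divide `size` (default 1000) so
#'   the canonical tiling is a subset of the sliding set.
#' @return A tibble of windows: `chrom`, `start`, `end` (0-based half-open),
#'   `window_id`, `is_canonical`, `effective_length` (initially `end - start`),
#'   `excluded` (initially `FALSE`), `gc_fraction` (initially `NA`). The
#'   window size and step are carried as attributes.
#' @export
make_windows <- function(index, size = 10000, step = 1000) {
  assert_cols(index, c("chrom", "length"), "genome index")
  size <- as.integer(size); step <- as.integer(step)
  if (size < 1) abort("window size must be >= 1")
  if (step < 1 || step > size) abort("step must satisfy 1 <= step <= size")
  if (size %% step != 0) abort("window size must be divisible by step")
  if (any(index$length < 1)) abort("chromosome lengths must be >= 1")

  out <- purrr::pmap(list(index$chrom, index$length), function(chrom, len) {
    starts <- seq.int(0L, len - 1L, by = step)
    tibble(chrom = chrom,
           start = starts,
           end   = pmin(starts + size, len))
  })
  windows <- purrr::list_rbind(out)
  windows <- dplyr::mutate(
    windows,
    window_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
    is_canonical = .data$start %% size == 0L,
    effective_length = .data$end - .data$start,
    excluded = FALSE,
    gc_fraction = NA_real_
  )
  attr(windows, "window_size") <- size
  attr(windows, "window_step") <- step
  windows
}

#' Apply a region mask to windows
#'
#' Subtracts masked base pairs from each window's effective length. Windows
#' left with zero unmasked bases are flagged `excluded` and drop out of all
#' downstream statistics.
#'
#' @param windows Window tibble from [make_windows()].
#' @param mask Mask tibble (`chrom`, `start`, `end`, 0-based half-open) from
#'   [read_mask()], or `NULL`/empty for no masking.
#' @return The window tibble with `effective_length` and `excluded` updated.
#' @export
apply_mask <- function(windows, mask) {
  assert_cols(windows, c("chrom", "start", "end"), "windows")
  mask <- merge_mask(mask)
  if (nrow(mask) == 0) {
    out <- dplyr::mutate(windows,
                         effective_length = .data$end - .data$start,
                         excluded = FALSE)
    return(keep_window_attrs(out, windows))
  }
  masked_bp <- overlap_bp(windows, mask)
  out <- dplyr::mutate(windows,
                       effective_length = .data$end - .data$start - masked_bp,
                       excluded = .data$effective_length == 0L)
  keep_window_attrs(out, windows)
}

# Base pairs of overlap between each window and a merged interval set.
overlap_bp <- function(windows, intervals) {
  out <- integer(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    wi <- which(windows$chrom == chrom)
    mi <- intervals[intervals$chrom == chrom, , drop = FALSE]
    if (nrow(mi) == 0) next
    wr <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    mr <- IRanges::IRanges(mi$start + 1L, mi$end)
    ov <- IRanges::findOverlaps(wr, mr)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      wr[S4Vectors::queryHits(ov)], mr[S4Vectors::subjectHits(ov)]))
    out[wi] <- out[wi] + as.integer(tapply(w, factor(S4Vectors::queryHits(ov),
                                                     levels = seq_along(wr)),
                                           sum, default = 0L))
  }
  out
}

#' Annotate windows with GC content
#'
#' GC fraction is (G + C) / (A + C + G + T) over the unmasked bases of each
#' window; N bases count in neither numerator nor denominator. Windows with
#' no unmasked non-N bases get `NA` and are excluded from GC-filtered
#' analyses only.
#'
#' @param windows Window tibble.
#' @param fasta Genome FASTA path or `DNAStringSet`.
#' @param mask Optional mask tibble; masked bases are ignored.
#' @return The window tibble with `gc_fraction` filled in.
#' @export
annotate_gc <- function(windows, fasta, mask = NULL) {
  seqs <- read_genome(fasta)
  mask <- merge_mask(mask)
  gc <- rep(NA_real_, nrow(windows))
  for (chrom in unique(windows$chrom)) {
    if (!chrom %in% names(seqs)) {
      abort(sprintf("windows name chromosome absent from FASTA: %s", chrom))
    }
    seq <- seqs[[chrom]]
    wi <- which(windows$chrom == chrom)
    if (any(windows$end[wi] > length(seq))) {
      abort(sprintf("window extends beyond end of %s", chrom))
    }
    mi <- mask[mask$chrom == chrom, , drop = FALSE]
    if (nrow(mi) > 0) {
      seq <- Biostrings::replaceAt(
        seq,
        IRanges::IRanges(mi$start + 1L, mi$end),
        as(strrep("N", mi$end - mi$start), "DNAStringSet"))
    }
    v <- Biostrings::Views(seq, start = windows$start[wi] + 1L,
                           end = windows$end[wi])
    lf <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    denom <- rowSums(lf)
    gc[wi] <- ifelse(denom > 0, (lf[, "G"] + lf[, "C"]) / denom, NA_real_)
  }
  out <- dplyr::mutate(windows, gc_fraction = gc)
  keep_window_attrs(out, windows)
}

#' Write windows as a BED-style TSV
#'
#' @param windows Window tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  out <- dplyr::select(windows, "chrom", "start", "end", "window_id",
                       "effective_length", "gc_fraction")
  readr::write_tsv(out, path)
  invisible(path)
}
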