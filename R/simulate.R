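#' Configuration for the synthetic dataset generator
#'
#' Defines a synthetic study with the statistical structure of a
#' mutation-accumulation (MA) experiment scored against RNA-seq coverage:
#' a multi-chromosome genome with a masked fraction, zero-inflated
#' heavy-tailed window-level expression, several dozen mutations per
#' genotype, and a tunable dependence of mutation placement on local
#' expression. Defaults mirror the scale of the study design the package
#' targets: nine genotypes with 73 mutations each (657 total, within the
#' reported 39--136 per genotype) over a multi-megabase genome, and four
#' expression profiles so the default battery has 36 tests.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_chromosomes,chromosome_length Genome geometry (default 3 x 1 Mb).
#' @param window_size Resolution at which expression truth is defined
#'   (default 10000 bp, the canonical tiling).
#' @param masked_fraction Fraction of the genome covered by masked
#'   intervals, in `[0, 1)` (default 0.1).
#' @param mask_cell Length of each masked interval before merging
#'   (default 2000 bp).
#' @param gc_mean,gc_sd Per-window GC content, truncated normal
#'   (defaults 0.40, 0.05 — centred where most windows fall in a 30--50%
#'   GC band).
#' @param zero_fraction Probability a window is unexpressed (default 0.3,
#'   emulating zero inflation of whole-body RNA-seq).
#' @param log_mu,log_sigma Log-normal parameters of nonzero window
#'   expression rates (defaults 1.0, 1.5 — heavy-tailed).
#' @param read_depth Scaling from expression rate to mean per-base read
#'   coverage (default 30).
#' @param coverage_segment Resolution of simulated coverage noise in bp
#'   (default 100): each segment's coverage is Poisson with mean
#'   `lambda * read_depth`.
#' @param n_profiles Number of expression profiles (e.g. stage x condition
#'   combinations) sharing the same window-level truth (default 4).
#' @param n_genotypes,mutations_per_genotype MA design (defaults 9, 73).
#' @param effect_size Expression-to-mutation effect beta >= 0. Each
#'   mutation's window is drawn with probability proportional to
#'   `exp(beta * z_w)` where `z_w` is the z-score of `log1p(lambda_w)`
#'   across included windows; `beta = 0` is the null of placement
#'   independent of expression.
#' @param type_mix Named proportions of base_substitution / insertion /
#'   deletion; must sum to 1.
#' @param gene_fraction,gene_length Simulated gene annotation: non-
#'   overlapping genes of `gene_length` bp covering about `gene_fraction`
#'   of each chromosome (defaults 0.3, 2000).
#' @return A validated `tam_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 3, chromosome_length = 1e6,
                       window_size = 1e4,
                       masked_fraction = 0.1, mask_cell = 2000,
                       gc_mean = 0.40, gc_sd = 0.05,
                       zero_fraction = 0.3, log_mu = 1.0, log_sigma = 1.5,
                       read_depth = 30, coverage_segment = 100,
                       n_profiles = 4,
                       n_genotypes = 9, mutations_per_genotype = 73,
                       effect_size = 0,
                       type_mix = c(base_substitution = 0.8,
                                    insertion = 0.1, deletion = 0.1),
                       gene_fraction = 0.3, gene_length = 2000) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              window_size = as.integer(window_size),
              masked_fraction = masked_fraction, mask_cell = as.integer(mask_cell),
              gc_mean = gc_mean, gc_sd = gc_sd,
              zero_fraction = zero_fraction, log_mu = log_mu,
              log_sigma = log_sigma,
              read_depth = read_depth,
              coverage_segment = as.integer(coverage_segment),
              n_profiles = as.integer(n_profiles),
              n_genotypes = as.integer(n_genotypes),
              mutations_per_genotype = as.integer(mutations_per_genotype),
              effect_size = effect_size,
              type_mix = type_mix,
              gene_fraction = gene_fraction,
              gene_length = as.integer(gene_length))
  if (cfg$masked_fraction < 0 || cfg$masked_fraction >= 1) {
    abort("masked_fraction must lie in [0, 1)")
  }
  if (cfg$zero_fraction < 0 || cfg$zero_fraction >= 1) {
    abort("zero_fraction must lie in [0, 1)")
  }
  if (cfg$effect_size < 0) abort("effect_size must be >= 0")
  if (abs(sum(cfg$type_mix) - 1) > 1e-8) abort("type_mix must sum to 1")
  if (is.null(names(cfg$type_mix)) ||
      !setequal(names(cfg$type_mix),
                c("base_substitution", "insertion", "deletion"))) {
    abort("type_mix must name base_substitution, insertion, deletion")
  }
  if (cfg$n_chromosomes < 1 || cfg$chromosome_length < cfg$window_size) {
    abort("genome must hold at least one window per chromosome")
  }
  structure(cfg, class = "tam_sim_config")
}

#' Simulate a genome sequence and mask
#'
#' Bases are i.i.d. within each tiling window with the window's GC drawn
#' from a truncated normal; the mask covers `masked_fraction` of each
#' chromosome with randomly placed, merged fixed-length cells.
#'
#' @param config A [sim_config()] object.
#' @return A list with `sequences` (named character vector), `index`
#'   (genome index tibble), and `mask` (merged mask tibble).
#' @export
simulate_genome <- function(config) {
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  L <- config$chromosome_length
  sequences <- withr::with_seed(derive_seed(config$seed, "genome"), {
    vapply(chroms, function(chrom) {
      starts <- seq.int(0L, L - 1L, by = config$window_size)
      widths <- pmin(starts + config$window_size, L) - starts
      gc <- pmin(pmax(stats::rnorm(length(starts), config$gc_mean,
                                   config$gc_sd), 0.02), 0.98)
      codes <- unlist(lapply(seq_along(starts), function(i) {
        p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
        sample.int(4L, widths[i], replace = TRUE, prob = p)
      }), use.names = FALSE)
      intToUtf8(utf8ToInt("ACGT")[codes])
    }, character(1))
  })
  index <- tibble(chrom = chroms, length = unname(nchar(sequences)))
  mask <- withr::with_seed(derive_seed(config$seed, "mask"), {
    if (config$masked_fraction == 0) {
      tibble(chrom = character(), start = integer(), end = integer())
    } else {
      purrr::list_rbind(purrr::map(chroms, function(chrom) {
        n_cells <- L %/% config$mask_cell
        n_pick <- floor(config$masked_fraction * n_cells)
        cells <- sort(sample.int(n_cells, n_pick)) - 1L
        tibble(chrom = chrom,
               start = cells * config$mask_cell,
               end = (cells + 1L) * config$mask_cell)
      }))
    }
  })
  list(sequences = sequences, index = index, mask = merge_mask(mask, index))
}

#' Simulate window-level expression truth and coverage tracks
#'
#' Each tiling window's true rate `lambda_w` is zero with probability
#' `zero_fraction` and otherwise log-normal. Coverage is piecewise constant
#' at `coverage_segment` resolution, each segment Poisson with mean
#' `lambda_w * read_depth`; every profile gets independent sampling noise
#' around the shared truth. Doubling `read_depth` doubles coverage
#' everywhere and so leaves TPM unchanged in expectation.
#'
#' @param config A [sim_config()] object.
#' @param index Genome index tibble (from [simulate_genome()]).
#' @return A list with `lambda` (tibble `window_id`, `chrom`, `start`,
#'   `end`, `lambda`) and `coverage` (named list of coverage tibbles, one
#'   per profile).
#' @export
simulate_expression <- function(config, index) {
  tiling <- make_windows(index, size = config$window_size,
                         step = config$window_size)
  lambda <- withr::with_seed(derive_seed(config$seed, "lambda"), {
    n <- nrow(tiling)
    lam <- ifelse(stats::runif(n) < config$zero_fraction, 0,
                  stats::rlnorm(n, config$log_mu, config$log_sigma))
    dplyr::mutate(dplyr::select(tiling, "window_id", "chrom", "start", "end"),
                  lambda = lam)
  })
  profiles <- sprintf("profile%d", seq_len(config$n_profiles))
  seg <- config$coverage_segment
  coverage <- lapply(profiles, function(p) {
    withr::with_seed(derive_seed(config$seed, paste0("coverage|", p)), {
      rows <- purrr::pmap(lambda, function(window_id, chrom, start, end, lambda) {
        if (lambda == 0) return(NULL)
        seg_starts <- seq.int(start, end - 1L, by = seg)
        seg_ends <- pmin(seg_starts + seg, end)
        val <- stats::rpois(length(seg_starts), lambda * config$read_depth)
        keep <- val > 0
        if (!any(keep)) return(NULL)
        tibble(chrom = chrom, start = seg_starts[keep], end = seg_ends[keep],
               coverage = as.numeric(val[keep]))
      })
      out <- purrr::list_rbind(purrr::compact(rows))
      if (nrow(out) == 0) {
        out <- tibble(chrom = character(), start = integer(),
                      end = integer(), coverage = numeric())
      }
      attr(out, "profile") <- p
      out
    })
  })
  names(coverage) <- profiles
  list(lambda = lambda, coverage = coverage)
}

# Unmasked sub-intervals of each window, as a list of two-column matrices
# (start, end; 0-based half-open), computed chromosome-wise in one pass.
unmasked_by_window <- function(windows, mask, index) {
  out <- vector("list", nrow(windows))
  for (chrom in unique(windows$chrom)) {
    len <- index$length[index$chrom == chrom]
    mi <- mask[mask$chrom == chrom, , drop = FALSE]
    free <- if (nrow(mi) > 0) {
      BiocGenerics::setdiff(IRanges::IRanges(1L, len),
                            IRanges::IRanges(mi$start + 1L, mi$end))
    } else {
      IRanges::IRanges(1L, len)
    }
    wi <- which(windows$chrom == chrom)
    wr <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    ov <- IRanges::findOverlaps(free, wr)
    pieces <- IRanges::pintersect(free[S4Vectors::queryHits(ov)],
                                  wr[S4Vectors::subjectHits(ov)])
    ps <- IRanges::start(pieces) - 1L; pe <- IRanges::end(pieces)
    hit <- S4Vectors::subjectHits(ov)
    for (j in seq_along(wi)) {
      sel <- which(hit == j)
      out[[wi[j]]] <- cbind(ps[sel], pe[sel])
    }
  }
  out
}

#' Simulate per-genotype mutation sets
#'
#' Draws each mutation's window with probability proportional to
#' `exp(beta * z_w)`, `z_w` the z-score of `log1p(lambda_w)` over included
#' windows, then places it uniformly over the window's unmasked positions.
#' REF alleles are read from the simulated sequence so generated VCFs
#' round-trip consistently; insertion/deletion lengths are 1--3 bp.
#'
#' @param config A [sim_config()] object.
#' @param lambda Window truth tibble from [simulate_expression()].
#' @param genome List from [simulate_genome()].
#' @return A mutation tibble (as from [read_mutations()]) covering all
#'   genotypes, with genotypes labelled `g1`, `g2`, ...
#' @export
simulate_mutations <- function(config, lambda, genome) {
  windows <- apply_mask(
    make_windows(genome$index, config$window_size, config$window_size),
    genome$mask)
  wl <- dplyr::inner_join(dplyr::select(windows, "window_id", "chrom",
                                        "start", "end", "effective_length"),
                          dplyr::select(lambda, "window_id", "lambda"),
                          by = "window_id")
  wl <- wl[wl$effective_length > 0, , drop = FALSE]
  if (nrow(wl) == 0) abort("no unmasked positions available for mutations")
  lz <- log1p(wl$lambda)
  z <- if (stats::sd(lz) > 0) (lz - mean(lz)) / stats::sd(lz) else rep(0, length(lz))
  w <- exp(config$effect_size * z)
  free_by_window <- unmasked_by_window(wl, genome$mask, genome$index)

  genos <- sprintf("g%d", seq_len(config$n_genotypes))
  muts <- purrr::map(genos, function(g) {
    withr::with_seed(derive_seed(config$seed, paste0("mutations|", g)), {
      m <- config$mutations_per_genotype
      if (m == 0) return(NULL)
      widx <- sample.int(nrow(wl), m, replace = TRUE, prob = w)
      pos0 <- vapply(widx, function(i) {
        iv <- free_by_window[[i]]
        widths <- iv[, 2] - iv[, 1]
        j <- if (nrow(iv) == 1) 1L else
          sample.int(nrow(iv), 1L, prob = widths)
        iv[j, 1] + sample.int(widths[j], 1L) - 1L
      }, integer(1))
      chrom <- wl$chrom[widx]
      type <- sample(names(config$type_mix), m, replace = TRUE,
                     prob = config$type_mix)
      pos <- pos0 + 1L  # VCF 1-based anchor
      seqs <- genome$sequences
      chrom_len <- nchar(seqs)[match(chrom, names(seqs))]
      # deletions need room for 1-3 deleted bases after the anchor
      del_len <- pmin(sample.int(3L, m, replace = TRUE), chrom_len - pos)
      fix_del <- type == "deletion" & del_len < 1L
      type[fix_del] <- "base_substitution"
      ref_base <- substr(seqs[chrom], pos, pos)
      alleles <- purrr::pmap(
        list(type, chrom, pos, ref_base, del_len),
        function(type, chrom, pos, ref_base, del_len) {
          bases <- c("A", "C", "G", "T")
          if (type == "base_substitution") {
            list(ref = ref_base,
                 alt = sample(setdiff(bases, ref_base), 1L))
          } else if (type == "insertion") {
            ins <- paste(sample(bases, sample.int(3L, 1L), replace = TRUE),
                         collapse = "")
            list(ref = ref_base, alt = paste0(ref_base, ins))
          } else {
            list(ref = substr(seqs[chrom], pos, pos + del_len),
                 alt = ref_base)
          }
        })
      tibble(chrom = chrom, pos = pos,
             ref = purrr::map_chr(alleles, "ref"),
             alt = purrr::map_chr(alleles, "alt"),
             type = type, genotype = g)
    })
  })
  out <- purrr::list_rbind(purrr::compact(muts))
  if (nrow(out) == 0) {
    return(tibble(mutation_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  type = character(), genotype = character()))
  }
  out <- dplyr::arrange(out, .data$genotype, .data$chrom, .data$pos)
  dplyr::mutate(out,
                mutation_id = sprintf("%s:%d:%s>%s", .data$chrom, .data$pos,
                                      .data$ref, .data$alt),
                .before = 1)
}

# Non-overlapping simulated genes on a fixed grid covering ~gene_fraction
# of each chromosome.
simulate_genes <- function(config, index) {
  withr::with_seed(derive_seed(config$seed, "genes"), {
    purrr::list_rbind(purrr::pmap(index, function(chrom, length) {
      n_cells <- length %/% config$gene_length
      n_genes <- max(1L, floor(config$gene_fraction * n_cells))
      cells <- sort(sample.int(n_cells, n_genes)) - 1L
      tibble(gene_id = sprintf("%s_gene%04d", chrom, seq_along(cells)),
             chrom = chrom,
             start = cells * config$gene_length,
             end = (cells + 1L) * config$gene_length)
    }))
  })
}

#' Simulate a full in-memory dataset
#'
#' Orchestrates genome, expression, gene, and mutation simulation without
#' touching the filesystem; [simulate_dataset()] adds the file round-trip.
#'
#' @param config A [sim_config()] object.
#' @return A list: `config`, `sequences`, `index`, `mask`, `lambda`,
#'   `coverage` (list per profile), `genes`, `mutations`.
#' @export
simulate_tables <- function(config) {
  genome <- simulate_genome(config)
  expr <- simulate_expression(config, genome$index)
  genes <- simulate_genes(config, genome$index)
  mutations <- simulate_mutations(config, expr$lambda, genome)
  list(config = config, sequences = genome$sequences, index = genome$index,
       mask = genome$mask, lambda = expr$lambda, coverage = expr$coverage,
       genes = genes, mutations = mutations)
}

#' Simulate a dataset and write it to disk
#'
#' Writes the standard-format bundle the analysis pipeline consumes —
#' genome FASTA, mask BED3, one bedGraph per expression profile, gene
#' GFF3, one VCF per genotype — plus `truth.json` recording the true
#' window rates, effect size, and configuration. Identical configurations
#' (including seed) produce byte-identical bundles.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `tables` and a `paths`
#'   list naming every file written.
#' @export
simulate_dataset <- function(config, dir) {
  tables <- simulate_tables(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                mask = file.path(dir, "mask.bed"),
                gff3 = file.path(dir, "genes.gff3"),
                truth = file.path(dir, "truth.json"))

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(tables$sequences), paths$fasta)
  readr::write_tsv(tables$mask, paths$mask, col_names = FALSE)

  paths$coverage <- purrr::imap_chr(tables$coverage, function(cov, p) {
    path <- file.path(dir, sprintf("coverage_%s.bedGraph", p))
    readr::write_tsv(cov, path, col_names = FALSE)
    path
  })

  gff <- dplyr::mutate(tables$genes,
                       line = sprintf("%s\ttamscan\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                                      .data$chrom, .data$start + 1L, .data$end,
                                      .data$gene_id))
  writeLines(c("##gff-version 3", gff$line), paths$gff3)

  paths$vcf <- vapply(sprintf("g%d", seq_len(config$n_genotypes)), function(g) {
    path <- file.path(dir, sprintf("mutations_%s.vcf", g))
    m <- tables$mutations[tables$mutations$genotype == g, , drop = FALSE]
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>",
                        tables$index$chrom, tables$index$length),
                paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                    "QUAL", "FILTER", "INFO"),
                                  collapse = "\t")))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", m$chrom, m$pos, m$ref, m$alt)
    writeLines(c(header, body), path)
    path
  }, character(1))

  jsonlite::write_json(
    list(effect_size = config$effect_size,
         seed = config$seed,
         lambda = tables$lambda,
         config = unclass(config)),
    paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(tables = tables, paths = paths))
}
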