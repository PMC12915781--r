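test_that("alleles classify into the three mutation categories", {
  expect_equal(classify_mutation_type(c("G", "C", "TAC", "A", "AT"),
                                      c("C", "CGG", "T", "AT", "A")),
               c("base_substitution", "insertion", "deletion",
                 "insertion", "deletion"))
  expect_error(classify_mutation_type("AT", "GC"), "MNP")
  expect_error(classify_mutation_type("", "A"), "non-empty")
})

test_that("VCF and TSV mutation input agree, with multi-allelics split", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000>",
               paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                   "FILTER", "INFO"), collapse = "\t")),
               "chr1\t101\t.\tA\tT\t.\tPASS\t.",
               "chr1\t201\t.\tA\tAT\t.\tPASS\t.",
               "chr1\t301\t.\tAT\tA\t.\tPASS\t.",
               "chr1\t401\t.\tG\tA,C\t.\tPASS\t."), vcf)
  mv <- read_mutations(vcf, genotype_label = "gX")
  expect_equal(nrow(mv), 5L)  # multi-allelic record split
  expect_equal(mv$type[1:3], c("base_substitution", "insertion", "deletion"))
  expect_equal(mv$genotype, rep("gX", 5))

  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(mv, chrom, pos, ref, alt, genotype), tsv)
  mt <- read_mutations(tsv)
  expect_equal(mt$mutation_id, mv$mutation_id)
  expect_equal(mt$type, mv$type)

  idx <- tibble::tibble(chrom = "chr1", length = 300L)
  expect_error(read_mutations(vcf, index = idx), "bounds")

  sym <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                   "FILTER", "INFO"), collapse = "\t")),
               "chr1\t10\t.\tA\t<DEL>\t.\tPASS\t."), sym)
  expect_error(read_mutations(sym), "symbolic")
})

test_that("a mutation overlaps every sliding window containing its anchor", {
  # anchor base 10,500 with 10 kb windows stepping 1 kb: starts 1,000..10,000
  idx <- tibble::tibble(chrom = "chr1", length = 50000L)
  w <- make_windows(idx, 10000, 1000)
  mut <- tibble::tibble(mutation_id = "m1", chrom = "chr1", pos = 10501L,
                        ref = "A", alt = "T", type = "base_substitution",
                        genotype = "g1")
  map <- mutation_window_map(mut, w)
  hit <- w[w$window_id %in% map$window_id, ]
  expect_equal(sort(hit$start), seq(1000L, 10000L, by = 1000L))
  expect_equal(nrow(map), 10L)

  # anchor at base 0 (pos 1) overlaps only the window starting at 0
  mut0 <- dplyr::mutate(mut, pos = 1L, mutation_id = "m0")
  map0 <- mutation_window_map(mut0, w)
  expect_equal(w$start[w$window_id %in% map0$window_id], 0L)
})

test_that("window flags count windows, not mutations, and match the oracle", {
  set.seed(3)
  idx <- tibble::tibble(chrom = c("c1", "c2"), length = c(40000L, 25000L))
  w <- make_windows(idx, 5000, 1000)
  muts <- tibble::tibble(
    chrom = sample(idx$chrom, 60, TRUE),
    pos = NA_integer_, ref = "A", alt = "T",
    type = "base_substitution",
    genotype = sample(c("g1", "g2"), 60, TRUE))
  muts$pos <- ifelse(muts$chrom == "c1", sample.int(40000L, 60, TRUE),
                     sample.int(25000L, 60, TRUE))
  muts$mutation_id <- sprintf("m%02d:%s", seq_len(60), muts$chrom)
  got <- flag_mutation_windows(muts, w)
  want <- oracle_overlap(muts, w)
  expect_equal(got$has_mutation, want$has_mutation)
  expect_equal(got$n_mutations, want$n_mutations)
  size <- 5000; step <- 1000
  expect_lte(sum(got$has_mutation), nrow(muts) * ceiling(size / step))

  # two mutations in one window flag it once
  two <- muts[1:2, ]; two$pos <- c(100L, 200L); two$chrom <- "c1"
  g2 <- flag_mutation_windows(two, w)
  expect_equal(g2$n_mutations[g2$window_id == w$window_id[1]], 2L)
  expect_equal(sum(g2$has_mutation), sum(oracle_overlap(two, w)$has_mutation))

  # pooled flags equal the union of per-genotype flags
  per <- lapply(split(muts, muts$genotype),
                function(m) flag_mutation_windows(m, w)$has_mutation)
  expect_equal(got$has_mutation, Reduce(`|`, per))
})

test_that("mutations confined to excluded windows warn and are dropped", {
  idx <- tibble::tibble(chrom = "chr1", length = 20000L)
  mask <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L)
  w <- apply_mask(make_windows(idx, 10000, 10000), mask)
  mut <- tibble::tibble(mutation_id = "m1", chrom = "chr1", pos = 500L,
                        ref = "A", alt = "T", type = "base_substitution",
                        genotype = "g1")
  expect_warning(out <- flag_mutation_windows(mut, w), "no included window")
  expect_true(out$has_mutation[1])   # retained on the excluded window
  expect_true(out$excluded[1])
})

test_that("genic overlap is half-open and stratifies by type", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          start = c(100L, 500L), end = c(200L, 600L))
  muts <- tibble::tibble(
    mutation_id = c("m1", "m2", "m3"),
    chrom = "chr1", pos = c(150L, 201L, 550L),
    ref = c("A", "C", "CT"), alt = c("T", "CA", "C"),
    type = c("base_substitution", "insertion", "deletion"),
    genotype = "g1")
  ov <- genic_overlap(muts, genes)
  # pos 201 is anchor base 200, one past gA's half-open end
  expect_equal(ov$has_mutation, c(TRUE, TRUE))
  expect_equal(ov$n_mutations, c(1L, 1L))
  expect_equal(ov$n_base_substitution, c(1L, 0L))
  expect_equal(ov$n_deletion, c(0L, 1L))

  # a deletion-free gene set yields an empty deletion stratum
  no_del <- genic_overlap(muts[muts$type == "insertion", ], genes)
  expect_equal(sum(no_del$n_deletion), 0L)
})
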