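idx2 <- tibble::tibble(chrom = "chr1", length = 20000L)

test_that("coverage parsing fills gaps with zero and validates input", {
  idx <- tibble::tibble(chrom = "chr1", length = 200L)
  bg <- write_bedgraph(cov_tbl("chr1", 0, 100, 5))
  cov <- read_coverage(bg, idx)
  w <- make_windows(idx, 100, 100)
  q <- quantify_windows(cov, w, idx)
  expect_equal(q$coverage_sum, c(500, 0))

  empty <- write_bedgraph(cov_tbl(character(), integer(), integer(), numeric()))
  cov0 <- read_coverage(empty, idx)
  q0 <- quantify_windows(cov0, w, idx)
  expect_equal(q0$depth_tpm, c(0, 0))

  neg <- write_bedgraph(cov_tbl("chr1", 0, 10, -1))
  expect_error(read_coverage(neg, idx), "non-negative")
  alien <- write_bedgraph(cov_tbl("chrX", 0, 10, 1))
  expect_error(read_coverage(alien, idx), "chrX")
})

test_that("window TPM normalises rates to one million over the tiling", {
  w <- make_windows(idx2, 10000, 10000)
  cov <- cov_tbl(c("chr1", "chr1"), c(0, 10000), c(10000, 20000),
                 c(10, 30) / 10000)  # coverage sums 10 and 30
  q <- quantify_windows(cov, w, idx2)
  expect_equal(q$depth_tpm, c(250000, 750000))
  expect_equal(sum(q$depth_tpm), 1e6)
})

test_that("effective-length normalisation equalises rates under masking", {
  # window 1 masked on [0,5000) with uniform coverage 2 on the unmasked
  # half; window 2 fully unmasked with uniform coverage 2. Rates are both
  # 2, so TPM splits 500,000 / 500,000.
  w <- make_windows(idx2, 10000, 10000)
  mask <- tibble::tibble(chrom = "chr1", start = 0L, end = 5000L)
  cov <- cov_tbl("chr1", 5000, 20000, 2)
  q <- quantify_windows(cov, apply_mask(w, mask), idx2, mask)
  expect_equal(q$effective_length, c(5000L, 10000L))
  expect_equal(q$depth_tpm, c(500000, 500000))
})

test_that("breadth is the percentage of unmasked bases covered", {
  w <- make_windows(tibble::tibble(chrom = "chr1", length = 10000L),
                    10000, 10000)
  idx <- tibble::tibble(chrom = "chr1", length = 10000L)
  expect_equal(quantify_windows(cov_tbl("chr1", 0, 2500, 1), w, idx)$breadth_pct,
               25)
  expect_equal(quantify_windows(cov_tbl("chr1", 0, 10000, 3), w, idx)$breadth_pct,
               100)
  expect_equal(
    quantify_windows(cov_tbl(character(), integer(), integer(), numeric()),
                     w, idx)$breadth_pct, 0)
})

test_that("interval quantification matches the per-base oracle exactly", {
  set.seed(7)
  idx <- tibble::tibble(chrom = c("cA", "cB"), length = c(5000L, 3000L))
  w <- apply_mask(
    make_windows(idx, 1000, 500),
    mask <- tibble::tibble(chrom = c("cA", "cB"), start = c(700L, 100L),
                           end = c(1600L, 900L)))
  cov <- dplyr::bind_rows(
    cov_tbl("cA", seq(0, 4900, by = 100), seq(100, 5000, by = 100),
            rpois(50, 3)),
    cov_tbl("cB", seq(0, 2900, by = 137)[1:20],
            pmin(seq(0, 2900, by = 137)[1:20] + 137, 3000), rpois(20, 1)))
  got <- quantify_windows(cov, w, idx, mask)
  want <- oracle_quantify(cov, w, mask, idx)
  expect_equal(got$effective_length, want$effective_length)
  expect_equal(got$coverage_sum, want$coverage_sum)
  expect_equal(got$depth_tpm, want$depth_tpm)
  expect_equal(got$breadth_pct, want$breadth_pct)
})

test_that("TPM is scale invariant and breadth is monotone in coverage", {
  set.seed(11)
  idx <- tibble::tibble(chrom = "chr1", length = 10000L)
  w <- make_windows(idx, 1000, 1000)
  cov <- cov_tbl("chr1", seq(0, 9900, 100), seq(100, 10000, 100),
                 rpois(100, 2))
  q1 <- quantify_windows(cov, w, idx)
  cov2 <- dplyr::mutate(cov, coverage = coverage * 7)
  q2 <- quantify_windows(cov2, w, idx)
  expect_equal(q1$depth_tpm, q2$depth_tpm)
  expect_equal(q1$breadth_pct, q2$breadth_pct)
  # adding coverage never decreases breadth
  extra <- dplyr::bind_rows(cov, cov_tbl("chr1", 0, 10000, 1))
  q3 <- quantify_windows(extra, w, idx)
  expect_true(all(q3$breadth_pct >= q1$breadth_pct))
})

test_that("gene TPM normalises over genes; fully masked genes are excluded", {
  idx <- tibble::tibble(chrom = "chr1", length = 4000L)
  genes <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                          chrom = "chr1",
                          start = c(0L, 1000L, 3000L),
                          end = c(1000L, 3000L, 3500L))
  # lengths 1000 and 2000, coverage sums 100 and 200 -> equal rates
  cov <- dplyr::bind_rows(cov_tbl("chr1", 0, 1000, 0.1),
                          cov_tbl("chr1", 1000, 3000, 0.1))
  mask <- tibble::tibble(chrom = "chr1", start = 3000L, end = 3500L)
  ge <- gene_expression(cov, genes, idx, mask)
  expect_equal(ge$depth_tpm[1:2], c(500000, 500000))
  expect_true(ge$excluded[3])
  expect_true(is.na(ge$depth_tpm[3]))
  # single expressed gene takes the whole million
  ge1 <- gene_expression(cov_tbl("chr1", 0, 500, 4), genes[1, ], idx)
  expect_equal(ge1$depth_tpm, 1e6)
})

test_that("generated files round-trip through the parsers", {
  dir <- tempfile()
  out <- simulate_dataset(small_sim_config(seed = 5), dir)
  idx <- read_genome_index(out$paths$fasta)
  expect_equal(idx$chrom, out$tables$index$chrom)
  expect_equal(idx$length, out$tables$index$length)
  expect_equal(as.data.frame(read_mask(out$paths$mask, idx)),
               as.data.frame(out$tables$mask))
  cov <- read_coverage(out$paths$coverage[[1]], idx)
  expect_equal(as.data.frame(cov),
               as.data.frame(out$tables$coverage[[1]]), ignore_attr = TRUE)
  genes <- read_genes(out$paths$gff3)
  expect_equal(genes$start, out$tables$genes$start)
  expect_equal(genes$end, out$tables$genes$end)
  muts <- read_mutations(out$paths$vcf[["g1"]], genotype_label = "g1",
                         index = idx)
  ref <- out$tables$mutations[out$tables$mutations$genotype == "g1", ]
  expect_equal(muts$pos, ref$pos)
  expect_equal(muts$ref, ref$ref)
  expect_equal(muts$alt, ref$alt)
  expect_equal(muts$type, ref$type)
})
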