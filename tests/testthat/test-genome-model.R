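test_that("BED12 and GTF readers map coordinates and strand onto TSS/TES", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t1000\t5000\tgeneA\t0\t+\t1200\t4800\t0\t2\t1000,1000\t0,3000",
    "chr1\t1000\t5000\tgeneB\t0\t-\t1000\t1000\t0\t1\t4000\t0"), bed)
  gm <- read_gene_models(bed, "bed12")
  expect_equal(gm$tss, c(1000, 5000))
  expect_equal(gm$tes, c(5000, 1000))
  # blocks converted to absolute half-open exons; zero-width thick = no CDS
  expect_equal(gm$exons[[1]], cbind(c(1000, 4000), c(2000, 5000)))
  expect_equal(gm$cds[[1]], c(1200, 4800))
  expect_null(gm$cds[[2]])

  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t1001\t2000\t.\t+\t.\t",
           "gene_id \"gX\"; transcript_id \"gX.1\";"),
    paste0("chr1\tsrc\texon\t4001\t5000\t.\t+\t.\t",
           "gene_id \"gX\"; transcript_id \"gX.1\";"),
    paste0("chr1\tsrc\tCDS\t1501\t4500\t.\t+\t.\t",
           "gene_id \"gX\"; transcript_id \"gX.1\";")), gtf)
  gx <- read_gene_models(gtf, "gtf")
  expect_equal(nrow(gx), 1L)
  # 1-based closed GTF becomes 0-based half-open with two sorted exons
  expect_equal(gx$exons[[1]], cbind(c(1000, 4000), c(2000, 5000)))
  expect_equal(gx$cds[[1]], c(1500, 4500))
  expect_equal(gx$tss, 1000)
})

test_that("malformed BED lines are rejected with their line number", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tg1\t0\t+", "chr1\tzero\t100\tg2\t0\t+"), bad)
  expect_error(read_gene_models(bad, "bed12"), "line 2")
})

test_that("partition matches the per-base oracle on hand-built cases", {
  toy <- toy_single_gene()
  part <- suppressMessages(build_partition(toy$genes, toy$sizes))
  expect_equal(partition_labels(part, "chr1"),
               brute_force_labels(toy$genes, 10000))
  # spec'd layout: promoter [0,2000), exon bases in the cds bucket,
  # downstream [5000,7000), intergenic elsewhere
  expect_equal(unname(part$base_counts[c("promoter", "cds", "downstream",
                                         "intergenic")]),
               c(2000, 3000, 2000, 3000))

  genes <- toy_coding_genes()
  sizes <- chrom_sizes(c(chr1 = 12000))
  part <- build_partition(genes, sizes)
  expect_equal(partition_labels(part, "chr1"),
               brute_force_labels(genes, 12000))
  expect_true(all(part$base_counts[c("utr5", "cds", "utr3", "intron")] > 0))
})

test_that("promoter of one gene outranks intron of another", {
  # minus-strand gene whose promoter [4000,6000) falls in the intron of g1
  genes <- gene_models(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = c("+", "-"),
    tss = c(1000, 4000), tes = c(8000, 2500),
    exons = list(cbind(c(1000, 7000), c(2000, 8000)), cbind(2500, 4000)))
  sizes <- chrom_sizes(c(chr1 = 10000))
  part <- suppressMessages(build_partition(genes, sizes))
  expect_equal(partition_labels(part, "chr1"),
               brute_force_labels(genes, 10000))
  expect_equal(partition_class_at(part, "chr1", c(4500, 5999)),
               c("promoter", "promoter"))
})

test_that("empty annotation yields a single intergenic interval", {
  genes <- gene_models(character(), character(), character(),
                       numeric(), numeric(), exons = list(), cds = list())
  part <- build_partition(genes, chrom_sizes(c(chrZ = 5000)))
  expect_equal(part$intervals,
               data.frame(chrom = "chrZ", start = 0, end = 5000,
                          class = "intergenic", stringsAsFactors = FALSE))
  expect_equal(unname(part$base_counts["intergenic"]), 5000)
})

test_that("partition is complete, strand-symmetric, and order-invariant", {
  for (seed in 1:25) {
    genes <- random_toy_genes(seed)
    sizes <- chrom_sizes(c(chr1 = 10000))
    part <- suppressMessages(build_partition(genes, sizes))
    # completeness: labels sum exactly to the genome
    expect_identical(sum(part$base_counts), 10000)
    expect_equal(partition_labels(part, "chr1"),
                 brute_force_labels(genes, 10000))

    # order invariance: shuffling input genes changes nothing
    perm <- sample(nrow(genes))
    shuffled <- genes[perm, , drop = FALSE]
    class(shuffled) <- class(genes)
    part2 <- suppressMessages(build_partition(shuffled, sizes))
    expect_identical(part$intervals, part2$intervals)

    # strand symmetry: reflect coordinates, flip strands
    L <- 10000
    refl <- gene_models(
      gene_id = genes$gene_id, chrom = genes$chrom,
      strand = ifelse(genes$strand == "+", "-", "+"),
      tss = L - genes$tss, tes = L - genes$tes,
      exons = lapply(genes$exons, function(m)
        cbind(L - m[, 2], L - m[, 1])[rev(seq_len(nrow(m))), , drop = FALSE]),
      cds = lapply(genes$cds, function(cd)
        if (is.null(cd)) NULL else c(L - cd[2], L - cd[1])))
    part_r <- suppressMessages(build_partition(refl, sizes))
    expect_equal(part_r$base_counts, part$base_counts)
  }
})

test_that("chromosome-edge promoters are clipped, unknown chromosomes refused", {
  genes <- gene_models("g1", "chr1", "+", tss = 500, tes = 3000)
  part <- suppressMessages(build_partition(genes, chrom_sizes(c(chr1 = 5000))))
  expect_equal(unname(part$base_counts["promoter"]), 500)
  expect_identical(sum(part$base_counts), 5000)
  expect_error(build_partition(genes, chrom_sizes(c(chr9 = 5000))),
               "absent from sizes")
})

test_that("chrom sizes TSV round-trips and partition BED is written", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10000", "chr2\t5000"), p)
  sz <- read_chrom_sizes(p)
  expect_s3_class(sz, "ChromSizes")
  expect_equal(unname(sz["chr2"]), 5000)

  toy <- toy_single_gene()
  part <- suppressMessages(build_partition(toy$genes, toy$sizes))
  bed <- tempfile(fileext = ".bed"); cnt <- tempfile(fileext = ".tsv")
  write_partition(part, bed, cnt)
  reread <- read.table(bed, sep = "\t")
  expect_equal(sum(reread$V3 - reread$V2), 10000)
  counts <- read.table(cnt, sep = "\t", header = TRUE)
  expect_equal(sum(counts$bases), 10000)
})
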