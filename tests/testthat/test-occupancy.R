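# all-pairs overlap oracle: gene occupied iff any peak overlaps the single
# interval promoter-union-body by >= 1 base
oracle_occupied <- function(peaks, genes, promoter_bp = 2000) {
  hits <- character(0)
  for (i in seq_len(nrow(genes))) {
    bs <- min(genes$tss[i], genes$tes[i]); be <- max(genes$tss[i], genes$tes[i])
    if (genes$strand[i] == "+") bs <- bs - promoter_bp else be <- be + promoter_bp
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] == genes$chrom[i] &&
          peaks$start[j] < be && peaks$end[j] > bs) {
        hits <- c(hits, genes$gene_id[i]); break
      }
    }
  }
  sort(hits)
}

mk_peak_df <- function(chrom, start, end) {
  p <- data.frame(chrom = chrom, start = start, end = end,
                  summit = floor((start + end) / 2),
                  tag_count = 1, score = 5, stringsAsFactors = FALSE)
  class(p) <- c("PeakSet", "data.frame")
  p
}

test_that("promoter/body overlap rule honours half-open boundaries", {
  g <- gene_models("g", "chr1", "+", tss = 5000, tes = 8000)
  inside <- mk_peak_df("chr1", 6000, 6200)
  expect_equal(occupied_genes(inside, g), "g")
  # promoter begins at tss - 2000 = 3000; a peak ending there misses it
  expect_equal(occupied_genes(mk_peak_df("chr1", 2500, 3000), g), character(0))
  expect_equal(occupied_genes(mk_peak_df("chr1", 2500, 3001), g), "g")
  # gene body is half-open at the TES
  expect_equal(occupied_genes(mk_peak_df("chr1", 8000, 8400), g), character(0))
  # minus-strand promoter sits above the TSS
  gm <- gene_models("m", "chr1", "-", tss = 8000, tes = 5000)
  expect_equal(occupied_genes(mk_peak_df("chr1", 9900, 10000), gm), "m")
  expect_equal(occupied_genes(mk_peak_df("chr1", 10000, 10400), gm),
               character(0))
})

test_that("occupancy matches the all-pairs oracle on random instances", {
  for (seed in 1:50) {
    set.seed(seed)
    genes <- random_toy_genes(seed, L = 20000, n = 10)
    s <- sample.int(19500, 50)
    peaks <- mk_peak_df("chr1", s, s + sample.int(400, 50))
    expect_equal(occupied_genes(peaks, genes), oracle_occupied(peaks, genes))
  }
})

test_that("occupancy grows monotonically with peaks and promoter width", {
  genes <- random_toy_genes(3, L = 20000, n = 10)
  set.seed(99)
  s <- sample.int(19500, 30)
  peaks <- mk_peak_df("chr1", s, s + 200)
  base <- occupied_genes(peaks, genes)
  more <- occupied_genes(rbind(peaks, mk_peak_df("chr1", 100, 300)), genes)
  expect_true(all(base %in% more))
  wider <- occupied_genes(peaks, genes, promoter_bp = 5000)
  expect_true(all(base %in% wider))
})

test_that("venn decomposition matches direct membership enumeration", {
  expect_equal(unname(venn_counts(list(A = "a", B = "b", C = "c"))),
               c(1, 1, 1, 0, 0, 0, 0))
  same <- letters[1:5]
  vc <- venn_counts(list(A = same, B = same, C = same))
  expect_equal(unname(vc), c(0, 0, 0, 0, 0, 0, 5))
  expect_error(venn_counts(list(A = "a", B = "b")), "exactly 3")
  expect_error(venn_counts(setNames(list("a", "b", "c"), c("A", "A", "B"))),
               "unique")

  for (seed in 1:20) {
    set.seed(seed)
    pool <- sprintf("gene%02d", 1:30)
    sets <- list(s1 = sample(pool, sample.int(20, 1)),
                 s2 = sample(pool, sample.int(20, 1)),
                 s3 = sample(pool, sample.int(20, 1)))
    vc <- venn_counts(sets)
    u <- unique(unlist(sets))
    # conservation: the seven regions tile the union
    expect_equal(sum(vc), length(u))
    # per-sample totals recoverable from the four regions containing a sample
    expect_equal(unname(vc["s1_only"] + vc["s1_s2"] + vc["s1_s3"] +
                          vc["all_three"]),
                 length(unique(sets$s1)))
    regions <- vapply(u, function(g) paste(c("A", "B", "C")[
      c(g %in% sets$s1, g %in% sets$s2, g %in% sets$s3)], collapse = ""), "")
    expect_equal(unname(vc["s1_s2"]), sum(regions == "AB"))
    expect_equal(unname(vc["all_three"]), sum(regions == "ABC"))
  }
})

test_that("gene lists are written sorted, unique, and round-trip", {
  dir <- tempfile()
  occ <- list(mef = c("g2", "g1", "g2"), d7 = character(0))
  paths <- suppressMessages(sample_gene_lists(occ, dir))
  expect_equal(readLines(paths["mef"]), c("g1", "g2"))
  expect_equal(readLines(paths["d7"]), character(0))
})
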