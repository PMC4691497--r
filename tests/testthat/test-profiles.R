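test_that("coverage_vector matches a brute-force per-base overlap count", {
  set.seed(9)
  L <- 5000
  n <- 400
  pos <- sample.int(L, n, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ts <- tag_set("s", list(chr1 = pos), list(chr1 = strand))
  ext <- 150
  got <- coverage_vector(ts, "chr1", 0, L, ext)
  # oracle: count extended fragments overlapping each base, one by one
  want <- numeric(L)
  for (i in seq_len(n)) {
    fs <- if (strand[i] == "+") pos[i] else pos[i] - ext + 1
    rng <- max(fs, 0):min(fs + ext - 1, L - 1)
    want[rng + 1] <- want[rng + 1] + 1
  }
  expect_equal(got, want * 1e6 / n)
})

test_that("single and duplicated tags produce the expected pileups", {
  ts <- tag_set("s", list(chr1 = c(1000, 1000, 3000)),
                list(chr1 = c("+", "+", "-")))
  cv <- coverage_vector(ts, "chr1", 900, 1300, extension = 150)
  expect_equal(sum(cv > 0), 150)
  expect_equal(unique(cv[cv > 0]), 2 * 1e6 / 3)   # two identical plus tags
  cvm <- coverage_vector(ts, "chr1", 2800, 3100, extension = 150)
  # minus tag covers 0-based bases [3000 - 150 + 1, 3000]; map window indices
  # back to genomic coordinates before comparing
  expect_equal(which(cvm > 0) + 2800 - 1, 2851:3000)
  expect_error(coverage_vector(ts, "chr1", 500, 400), "inverted")
})

test_that("composite profiles are strand-aware and linear in gene cohorts", {
  L <- 30000
  sizes <- chrom_sizes(c(chr1 = L))
  set.seed(21)
  pos <- sample.int(L, 4000, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), 4000, replace = TRUE)
  ts <- tag_set("s", list(chr1 = pos), list(chr1 = strand))

  gplus <- gene_models("gp", "chr1", "+", tss = 12000, tes = 20000)
  prof_p <- composite_profile(ts, gplus, sizes, "TSS",
                              flank = 5000, window = 200)
  # mirrored genome: the minus-strand view of the same tags
  mpos <- L - 1 - pos
  mstrand <- ifelse(strand == "+", "-", "+")
  mts <- tag_set("m", list(chr1 = mpos), list(chr1 = mstrand))
  gminus <- gene_models("gm", "chr1", "-", tss = L - 12000, tes = L - 20000)
  prof_m <- composite_profile(mts, gminus, sizes, "TSS",
                              flank = 5000, window = 200)
  expect_equal(prof_m$values, prof_p$values)

  # linearity: cohort profile is the mean of two equal-size cohort profiles
  g2 <- gene_models(c("a", "b"), "chr1", c("+", "+"),
                    tss = c(8000, 21000), tes = c(14000, 25000))
  g_a <- g2[1, ]; class(g_a) <- class(g2)
  g_b <- g2[2, ]; class(g_b) <- class(g2)
  both <- composite_profile(ts, g2, sizes, "TSS", flank = 3000, window = 200)
  pa <- composite_profile(ts, g_a, sizes, "TSS", flank = 3000, window = 200)
  pb <- composite_profile(ts, g_b, sizes, "TSS", flank = 3000, window = 200)
  expect_equal(both$values, (pa$values + pb$values) / 2)

  # RPM normalization: duplicating the whole library changes nothing
  dbl <- tag_set("d", list(chr1 = c(pos, pos)),
                 list(chr1 = c(strand, strand)))
  prof_d <- composite_profile(dbl, gplus, sizes, "TSS",
                              flank = 5000, window = 200)
  expect_equal(prof_d$values, prof_p$values, tolerance = 1e-12)
})

test_that("genes crossing chromosome ends are excluded, empty regions zero", {
  sizes <- chrom_sizes(c(chr1 = 30000))
  ts <- tag_set("s", list(chr1 = 15000), list(chr1 = "+"))
  near_edge <- gene_models(c("edge", "mid"), "chr1", c("+", "+"),
                           tss = c(2000, 15000), tes = c(9000, 22000))
  expect_message(
    prof <- composite_profile(ts, near_edge, sizes, "TSS",
                              flank = 5000, window = 200),
    "excluded")
  expect_equal(prof$n_genes, 1L)
  expect_error(composite_profile(ts, near_edge[1, ], sizes, "TSS",
                                 flank = 5000, window = 200),
               "no gene region")
  lonely <- gene_models("far", "chr1", "+", tss = 6000, tes = 9000)
  zero <- composite_profile(tag_set("z", list(chr1 = 25000),
                                    list(chr1 = "+")),
                            lonely, sizes, "TSS", flank = 5000, window = 200)
  expect_equal(zero$values, rep(0, 50))
})

test_that("expression stratification splits ranks with ties resolved by id", {
  expr8 <- data.frame(gene_id = paste0("g", 1:8), expression = 8:1)
  cls <- stratify_by_expression(expr8)
  expect_equal(as.vector(table(cls)), c(2, 2, 2, 2))
  expect_equal(names(cls)[cls == "high"], c("g1", "g2"))

  expr9 <- data.frame(gene_id = sprintf("g%02d", 1:9), expression = 9:1)
  cls9 <- stratify_by_expression(expr9)
  expect_equal(as.vector(table(cls9)), c(3, 2, 2, 2))  # remainder to high

  tied <- data.frame(gene_id = c("b", "a", "d", "c"), expression = rep(5, 4))
  cls_t <- stratify_by_expression(tied)
  expect_equal(names(cls_t), c("a", "b", "c", "d"))
  expect_error(stratify_by_expression(tied, n_classes = 5), "at least")
})

test_that("stratified profiles follow planted class amplitudes", {
  sim <- sim_small()
  strat <- suppressMessages(
    stratified_profiles(sim$tags$MEF, sim$genes, sim$sizes, sim$expr))
  maxima <- vapply(strat, function(p) max(p$values), 0)
  expect_equal(names(maxima), c("high", "middle", "low", "lowest"))
  expect_true(all(diff(maxima) < 0))
})
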