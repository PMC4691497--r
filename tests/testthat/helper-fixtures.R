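# Shared fixtures and independent oracles. Oracles here are deliberately
# written as plain per-base / all-pairs enumerations, not via the package's
# interval machinery.

# --- tiny hand-built annotations -------------------------------------------

# one plus-strand gene [2000, 5000), single exon, no CDS, on a 10 kb chromosome
toy_single_gene <- function() {
  list(genes = gene_models("gA", "chr1", "+", tss = 2000, tes = 5000),
       sizes = chrom_sizes(c(chr1 = 10000)))
}

# coding two-exon gene on each strand
toy_coding_genes <- function() {
  gene_models(
    gene_id = c("plus", "minus"), chrom = c("chr1", "chr1"),
    strand = c("+", "-"), tss = c(1000, 9000), tes = c(4000, 6000),
    exons = list(cbind(c(1000, 3000), c(2000, 4000)),
                 cbind(c(6000, 8000), c(7000, 9000))),
    cds = list(c(1500, 3500), c(6500, 8500)))
}

# random possibly-overlapping toy annotation for property tests
random_toy_genes <- function(seed, L = 10000, n = 4) {
  set.seed(seed)
  gid <- sprintf("g%02d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gstart <- sort(sample.int(L - 3000, n))
  glen <- sample(800:2500, n, replace = TRUE)
  gend <- pmin(gstart + glen, L)
  exons <- vector("list", n); cds <- vector("list", n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < 0.5) {  # two exons with an intron
      m1 <- gstart[i] + round((gend[i] - gstart[i]) * 0.4)
      m2 <- gstart[i] + round((gend[i] - gstart[i]) * 0.6)
      exons[[i]] <- cbind(c(gstart[i], m2), c(m1, gend[i]))
    } else {
      exons[[i]] <- cbind(gstart[i], gend[i])
    }
    if (stats::runif(1) < 0.7) {
      q <- round(stats::quantile(c(gstart[i], gend[i]), c(0.3, 0.8)))
      if (q[1] < q[2]) cds[[i]] <- as.numeric(q)
    }
  }
  gene_models(gene_id = gid, chrom = "chr1", strand = strand,
              tss = ifelse(strand == "+", gstart, gend),
              tes = ifelse(strand == "+", gend, gstart),
              exons = exons, cds = cds)
}

# --- per-base partition oracle ----------------------------------------------

# label every base of one chromosome by direct enumeration
brute_force_labels <- function(genes, L, chrom = "chr1",
                               promoter_bp = 2000, downstream_bp = 2000) {
  priority <- c("promoter", "utr5", "cds", "utr3", "downstream", "intron")
  labels <- rep("intergenic", L)
  cand <- matrix(FALSE, nrow = L, ncol = length(priority),
                 dimnames = list(NULL, priority))
  mark <- function(cls, s, e) {
    s <- max(s, 0); e <- min(e, L)
    if (s < e) cand[(s + 1):e, cls] <<- TRUE
  }
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    st <- genes$strand[i]; tss <- genes$tss[i]; tes <- genes$tes[i]
    bstart <- min(tss, tes); bend <- max(tss, tes)
    ex <- genes$exons[[i]]; cd <- genes$cds[[i]]
    if (st == "+") {
      mark("promoter", tss - promoter_bp, tss)
      mark("downstream", tes, tes + downstream_bp)
    } else {
      mark("promoter", tss, tss + promoter_bp)
      mark("downstream", tes - downstream_bp, tes)
    }
    exonic <- rep(FALSE, L)
    for (r in seq_len(nrow(ex))) {
      exonic[(ex[r, 1] + 1):ex[r, 2]] <- TRUE
    }
    body <- rep(FALSE, L)
    body[(bstart + 1):bend] <- TRUE
    cand[body & !exonic, "intron"] <- cand[body & !exonic, "intron"] | TRUE
    if (is.null(cd)) {
      cand[exonic, "cds"] <- TRUE
    } else {
      b0 <- seq_len(L) - 1  # 0-based base coordinates
      in_cds <- exonic & b0 >= cd[1] & b0 < cd[2]
      before <- exonic & b0 < cd[1]
      after <- exonic & b0 >= cd[2]
      cand[in_cds, "cds"] <- TRUE
      if (st == "+") {
        cand[before, "utr5"] <- TRUE; cand[after, "utr3"] <- TRUE
      } else {
        cand[after, "utr5"] <- TRUE; cand[before, "utr3"] <- TRUE
      }
    }
  }
  for (cls in rev(priority)) labels[cand[, cls]] <- cls
  labels
}

# expand a partition to per-base labels for comparison with the oracle
partition_labels <- function(partition, chrom) {
  iv <- partition$intervals[partition$intervals$chrom == chrom, ]
  rep(iv$class, iv$end - iv$start)
}

# --- cached default-condition simulation -------------------------------------

.sim_cache <- new.env(parent = emptyenv())

sim_default <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- suppressMessages(
      simulate_experiment(simulation_config(seed = seed)))
  .sim_cache[[key]]
}

# small fast simulation for module-level tests
sim_small <- function(seed = 11) {
  key <- paste0("small", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- suppressMessages(simulate_experiment(
      simulation_config(n_chroms = 1, chrom_length = 6e5, n_genes = 20,
                        library_size = 2e5, seed = seed)))
  .sim_cache[[key]]
}

# uniform-background tag set (no signal) under the default geometry
uniform_tags <- function(seed = 3, n = 1e6, L = 2e6, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  ch <- sample(chroms, n, replace = TRUE)
  pos <- floor(stats::runif(n) * L)
  tag_set("null", split(pos, factor(ch, levels = chroms)),
          split(sample(c("+", "-"), n, TRUE), factor(ch, levels = chroms)))
}
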