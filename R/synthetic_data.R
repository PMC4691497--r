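#' Simulation configuration
#'
#' Defines the synthetic study conditions: a toy genome with non-overlapping,
#' strand-alternating genes; uniform Poisson background tags; and per-gene
#' signal drawn from a two-Gaussian mixture flanking the TSS (closer, taller
#' shoulder upstream at −100 bp and one downstream at +200 bp by default, 80 bp
#' spread), which produces the characteristic bimodal TSS profile with a local
#' dip over the TSS itself. Signal amplitude scales with the gene's expression
#' class and with a per-sample global intensity: the intermediate
#' reprogramming sample (Day7) carries the strongest TSS signal and the iPSC
#' sample the weakest, with the fibroblast (MEF) sample in between.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param n_genes total genes, spread evenly over chromosomes.
#' @param read_length nominal read length (bases).
#' @param extension fragment extension used to place read 5' ends around each
#'   fragment center.
#' @param library_size nominal per-sample tag budget; background uses its
#'   expected share and the remainder (scaled by the sample intensity) is
#'   signal.
#' @param background_rate uniform background density, tags per kb.
#' @param sample_intensity named vector of global signal intensity scalars,
#'   one per sample.
#' @param peak_offsets signal mode offsets from the TSS, in transcribed
#'   direction (negative = upstream).
#' @param peak_sd Gaussian spread of each signal mode (bases).
#' @param dip_width width in bases of the nucleosome-depleted zone between the
#'   two signal modes: fragment centers falling within `dip_width / 2` of the
#'   midpoint of `peak_offsets` are rejected and redrawn, producing the local
#'   coverage drop over the TSS.
#' @param amplitudes named relative signal amplitude per expression class,
#'   highest class first.
#' @param seed integer master seed.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_chroms = 2, chrom_length = 2e6, n_genes = 120,
                              read_length = 49, extension = 150,
                              library_size = 1e6, background_rate = 100,
                              sample_intensity = c(MEF = 1.0, Day7 = 1.3,
                                                   iPSC = 0.7),
                              peak_offsets = c(-100, 200), peak_sd = 80,
                              dip_width = 200,
                              amplitudes = c(high = 4, middle = 2, low = 1,
                                             lowest = 0.5),
                              seed = 1) {
  if (is.null(names(sample_intensity)) || anyDuplicated(names(sample_intensity)))
    abort("sample_intensity must carry unique sample names")
  if (any(amplitudes < 0)) abort("amplitudes must be non-negative")
  structure(list(n_chroms = n_chroms, chrom_length = chrom_length,
                 n_genes = n_genes, read_length = read_length,
                 extension = extension, library_size = library_size,
                 background_rate = background_rate,
                 sample_intensity = sample_intensity,
                 peak_offsets = peak_offsets, peak_sd = peak_sd,
                 dip_width = dip_width,
                 amplitudes = amplitudes, seed = as.integer(seed)),
            class = "SimulationConfig")
}

# internal: deterministic per-(seed, sample) RNG seed below 2^31
sample_seed <- function(seed, sample_id) {
  (abs(seed) * 97 + sum(utf8ToInt(sample_id)) * 1009L) %% 2147483647L
}

#' Generate a toy annotation (gene models + chromosome sizes)
#'
#' Genes are laid out in equal slots per chromosome with alternating strands,
#' each at least 7.5 kb from the slot edges so every +/- 5 kb anchor region
#' and 2 kb promoter fits inside the chromosome. Each gene gets three exons
#' and a CDS running from mid-first-exon to mid-last-exon, so the partition of
#' the output populates all seven feature classes. Deterministic per seed.
#'
#' @param config `SimulationConfig`.
#' @return list with `genes` (`GeneModels`) and `sizes` (`ChromSizes`).
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  sizes <- chrom_sizes(stats::setNames(rep(config$chrom_length, config$n_chroms),
                                       paste0("chr", seq_len(config$n_chroms))))
  if (config$n_genes == 0)
    return(list(genes = gene_models(character(), character(), character(),
                                    numeric(), numeric(), exons = list(),
                                    cds = list()),
                sizes = sizes))
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1L)))
  margin <- 7500
  max_len <- 12000
  rows <- list()
  g <- 0L
  for (ci in seq_len(config$n_chroms)) {
    npc <- per_chrom[ci]
    if (npc == 0L) next
    slot <- floor(config$chrom_length / npc)
    if (slot < max_len + 2 * margin)
      abort("genes cannot fit: need chromosomes of at least ",
            npc * (max_len + 2 * margin), " bases for ", npc, " genes")
    for (j in seq_len(npc)) {
      g <- g + 1L
      glen <- round(stats::runif(1, 6000, max_len))
      lo <- (j - 1L) * slot + margin
      hi <- j * slot - margin - glen
      gstart <- lo + floor(stats::runif(1) * max(1, hi - lo))
      strand <- if (g %% 2L) "+" else "-"
      # three exons at fixed relative positions; CDS mid-exon1 to mid-exon3
      b <- gstart + round(glen * c(0, .15, .35, .55, .80, 1))
      exons <- cbind(b[c(1, 3, 5)], b[c(2, 4, 6)])
      cds <- c(round((b[1] + b[2]) / 2), round((b[5] + b[6]) / 2))
      rows[[g]] <- list(gene_id = sprintf("gene%03d", g),
                        chrom = names(sizes)[ci], strand = strand,
                        tss = if (strand == "+") gstart else gstart + glen,
                        tes = if (strand == "+") gstart + glen else gstart,
                        exons = exons, cds = cds)
    }
  }
  genes <- gene_models(gene_id = vapply(rows, `[[`, "", "gene_id"),
                       chrom = vapply(rows, `[[`, "", "chrom"),
                       strand = vapply(rows, `[[`, "", "strand"),
                       tss = vapply(rows, `[[`, 0, "tss"),
                       tes = vapply(rows, `[[`, 0, "tes"),
                       exons = lapply(rows, `[[`, "exons"),
                       cds = lapply(rows, `[[`, "cds"))
  list(genes = genes, sizes = sizes)
}

#' Generate a synthetic per-gene expression table
#'
#' Log-normal expression values (meanlog 4, sdlog 1), standing in for a
#' microarray quantification; deterministic per seed.
#'
#' @param genes `GeneModels`.
#' @param seed integer seed.
#' @return data frame `gene_id`, `expression`.
#' @export
generate_expression <- function(genes, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = genes$gene_id,
             expression = stats::rlnorm(nrow(genes), meanlog = 4, sdlog = 1),
             stringsAsFactors = FALSE)
}

#' Generate synthetic tags for one sample, with planted truth
#'
#' Background: Poisson(`background_rate` x genome kb) tags uniform over the
#' genome with random strand. Signal: `round((library_size - expected
#' background) x intensity)` fragment centers, split across genes in
#' proportion to their expression-class amplitude, each drawn from the
#' two-Gaussian TSS mixture (offsets strand-aware). Each fragment center
#' yields one read 5' end half an extension to its left (plus strand) or right
#' (minus strand), with equal probability, so extension-based pileups are
#' centered on the planted signal. Deterministic per (config seed, sample id).
#'
#' @param genes `GeneModels`.
#' @param expr expression table for `genes`.
#' @param config `SimulationConfig`.
#' @param sample_id one of `names(config$sample_intensity)`.
#' @param sizes `ChromSizes` (defaults to the config geometry).
#' @return list with `tags` (`TagSet`) and `truth` (list: `per_gene` data
#'   frame gene_id/chrom/start/end/n_tags/expected_fold, `occupied` gene ids
#'   with planted tags, `n_background`).
#' @export
generate_tags <- function(genes, expr, config, sample_id, sizes = NULL) {
  if (!sample_id %in% names(config$sample_intensity))
    abort("unknown sample_id: ", sample_id)
  if (is.null(sizes))
    sizes <- chrom_sizes(stats::setNames(
      rep(config$chrom_length, config$n_chroms),
      paste0("chr", seq_len(config$n_chroms))))
  set.seed(sample_seed(config$seed, sample_id))
  genome_length <- sum(sizes)
  expected_bg <- config$background_rate * genome_length / 1000
  signal_budget <- config$library_size - expected_bg
  if (signal_budget < 0)
    abort("expected background (", round(expected_bg),
          ") exceeds the library_size budget")
  intensity <- config$sample_intensity[[sample_id]]
  n_signal <- if (nrow(genes)) round(signal_budget * intensity) else 0
  half <- floor(config$extension / 2)

  # background tags
  n_bg <- stats::rpois(1, expected_bg)
  bg_chrom <- sample(names(sizes), n_bg, replace = TRUE,
                     prob = sizes / genome_length)
  bg_pos <- floor(stats::runif(n_bg) * sizes[bg_chrom])
  bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)

  # signal tags
  sg_chrom <- character(0); sg_pos <- numeric(0); sg_strand <- character(0)
  counts <- integer(nrow(genes))
  if (n_signal > 0) {
    cls <- stratify_by_expression(expr, length(config$amplitudes))
    amp <- config$amplitudes[as.character(cls[genes$gene_id])]
    if (any(is.na(amp))) abort("expression table does not cover all genes")
    counts <- if (sum(amp) > 0)
      as.integer(stats::rmultinom(1, n_signal, amp)) else integer(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      cnt <- counts[i]
      if (cnt == 0L) next
      dir <- if (genes$strand[i] == "+") 1 else -1
      dip_mid <- mean(config$peak_offsets)
      rel <- numeric(0)  # centers relative to TSS, transcribed direction
      need <- cnt
      tries <- 0L
      while (need > 0) {
        if ((tries <- tries + 1L) > 1000L)
          abort("dip_width rejects nearly all signal mass; widen peak_offsets")
        offs <- sample(config$peak_offsets, need, replace = TRUE)
        cand <- offs + stats::rnorm(need, 0, config$peak_sd)
        keep <- abs(cand - dip_mid) > config$dip_width / 2
        rel <- c(rel, cand[keep])
        need <- cnt - length(rel)
      }
      centers <- genes$tss[i] + dir * rel
      minus <- stats::runif(cnt) < 0.5
      pos <- round(centers) + ifelse(minus, half, -half)
      L <- sizes[[genes$chrom[i]]]
      pos <- pmin(pmax(pos, 0), L - 1)
      sg_chrom <- c(sg_chrom, rep(genes$chrom[i], cnt))
      sg_pos <- c(sg_pos, pos)
      sg_strand <- c(sg_strand, ifelse(minus, "-", "+"))
    }
  }

  chrom <- c(bg_chrom, sg_chrom)
  pos <- c(bg_pos, sg_pos)
  strand <- c(bg_strand, sg_strand)
  positions <- split(pos, factor(chrom, levels = names(sizes)))
  strands <- split(strand, factor(chrom, levels = names(sizes)))
  tags <- tag_set(sample_id, positions, strands,
                  read_length = config$read_length)

  lambda_bg <- config$background_rate / 1000
  truth_rows <- NULL
  if (nrow(genes)) {
    dir <- ifelse(genes$strand == "+", 1, -1)
    m1 <- genes$tss + dir * min(config$peak_offsets)
    m2 <- genes$tss + dir * max(config$peak_offsets)
    lo <- pmin(m1, m2) - 3 * config$peak_sd - half
    hi <- pmax(m1, m2) + 3 * config$peak_sd + half
    truth_rows <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                             start = lo, end = hi, n_tags = counts,
                             expected_fold = 1 + (counts / (hi - lo)) / lambda_bg,
                             stringsAsFactors = FALSE)
  }
  list(tags = tags,
       truth = list(per_gene = truth_rows,
                    occupied = if (is.null(truth_rows)) character() else
                      truth_rows$gene_id[truth_rows$n_tags > 0],
                    n_background = n_bg))
}

#' Run the full simulator for every configured sample
#'
#' @param config `SimulationConfig`.
#' @return list with `genes`, `sizes`, `expr`, `tags` (named list of
#'   `TagSet`s) and `truth` (named list of planted-truth records).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  ann <- generate_annotation(config)
  expr <- generate_expression(ann$genes, config$seed)
  tags <- list(); truth <- list()
  for (id in names(config$sample_intensity)) {
    r <- generate_tags(ann$genes, expr, config, id, ann$sizes)
    tags[[id]] <- r$tags
    truth[[id]] <- r$truth
  }
  list(genes = ann$genes, sizes = ann$sizes, expr = expr,
       tags = tags, truth = truth)
}

#' Write gene models as BED12
#'
#' @param genes `GeneModels`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation_bed12 <- function(genes, path) {
  n <- nrow(genes)
  lines <- character(n)
  for (i in seq_len(n)) {
    ex <- genes$exons[[i]]
    bstart <- min(genes$tss[i], genes$tes[i])
    bend <- max(genes$tss[i], genes$tes[i])
    cd <- genes$cds[[i]]
    if (is.null(cd)) cd <- c(bstart, bstart)
    lines[i] <- paste(genes$chrom[i],
                      format(bstart, scientific = FALSE),
                      format(bend, scientific = FALSE),
                      genes$gene_id[i], 0, genes$strand[i],
                      format(cd[1L], scientific = FALSE),
                      format(cd[2L], scientific = FALSE), 0, nrow(ex),
                      paste0(ex[, 2L] - ex[, 1L], collapse = ","),
                      paste0(ex[, 1L] - bstart, collapse = ","),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write simulated inputs to a directory
#'
#' Writes the BED12 annotation, chromosome sizes TSV, expression TSV, one tag
#' BED per sample, and the planted truth as JSON.
#'
#' @param sim result of [simulate_experiment()].
#' @param out_dir output directory.
#' @return invisibly, named vector of paths.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = file.path(out_dir, "annotation.bed"),
             sizes = file.path(out_dir, "chrom_sizes.tsv"),
             expression = file.path(out_dir, "expression.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_annotation_bed12(sim$genes, paths["annotation"])
  utils::write.table(
    data.frame(names(sim$sizes),
               format(as.numeric(sim$sizes), scientific = FALSE, trim = TRUE)),
    paths["sizes"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (id in names(sim$tags)) {
    p <- file.path(out_dir, paste0("tags_", id, ".bed"))
    write_tags(sim$tags[[id]], p)
    paths[paste0("tags_", id)] <- p
  }
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
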