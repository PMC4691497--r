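#' Gene model table
#'
#' Constructs the package's gene-model container: one row per gene with
#' strand-aware TSS/TES anchors and exon/CDS structure. All coordinates are
#' 0-based half-open. The TSS and TES are stored as half-open boundary
#' positions, so for a plus-strand gene `tss < tes` and the gene body is
#' `[tss, tes)`, while for a minus-strand gene `tss > tes` and the body is
#' `[tes, tss)`. The promoter is the 2 kb (by default) immediately upstream of
#' the TSS in the transcribed direction; "downstream" is the 2 kb past the TES.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome name per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss,tes transcription start/end boundary positions (0-based).
#' @param exons list of two-column integer matrices (start, end), 0-based
#'   half-open, sorted and non-overlapping, all within the gene body. Defaults
#'   to a single exon spanning the whole body.
#' @param cds list of length-2 integer vectors `(start, end)` giving the
#'   coding interval, or `NULL` entries for non-coding genes.
#' @param symbol optional gene symbols.
#' @return a `GeneModels` data frame.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, tes,
                        exons = NULL, cds = NULL, symbol = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) abort("duplicated gene_id")
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(tss == tes)) abort("tss must differ from tes")
  bad <- (strand == "+" & tss >= tes) | (strand == "-" & tss <= tes)
  if (any(bad))
    abort("strand/anchor mismatch for gene(s): ",
          paste(gene_id[bad], collapse = ", "))
  bstart <- pmin(tss, tes)
  bend <- pmax(tss, tes)
  if (is.null(exons))
    exons <- lapply(seq_len(n), function(i) cbind(bstart[i], bend[i]))
  if (is.null(cds)) cds <- vector("list", n)
  if (is.null(symbol)) symbol <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) == 0L)
      abort("exons must be non-empty two-column matrices (gene ", gene_id[i], ")")
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 1L] >= ex[, 2L]) ||
        any(ex[, 1L] < bstart[i]) || any(ex[, 2L] > bend[i]) ||
        (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])))
      abort("exons of gene ", gene_id[i],
            " must be non-overlapping and within the gene body")
    exons[[i]] <- ex
    cd <- cds[[i]]
    if (!is.null(cd)) {
      if (length(cd) != 2L || cd[1L] >= cd[2L] ||
          cd[1L] < bstart[i] || cd[2L] > bend[i])
        abort("cds of gene ", gene_id[i], " must lie within the gene body")
    }
  }
  out <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                    strand = strand, tss = as.numeric(tss), tes = as.numeric(tes),
                    symbol = symbol, stringsAsFactors = FALSE)
  out$exons <- exons
  out$cds <- cds
  class(out) <- c("GeneModels", "data.frame")
  out
}

#' @export
print.GeneModels <- function(x, ...) {
  cat("GeneModels:", nrow(x), "genes on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print.data.frame(utils::head(x[, c("gene_id", "chrom", "strand", "tss", "tes")]),
                   ...)
  invisible(x)
}

#' Chromosome sizes
#'
#' @param x named numeric vector or two-column data frame (name, length).
#' @return named numeric vector of class `ChromSizes`.
#' @export
chrom_sizes <- function(x) {
  if (is.data.frame(x)) x <- stats::setNames(as.numeric(x[[2L]]), as.character(x[[1L]]))
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x)))
    abort("chromosome sizes need unique non-empty names")
  if (any(!is.finite(x)) || any(x <= 0) || any(x != floor(x)))
    abort("chromosome lengths must be positive integers")
  structure(as.numeric(x), names = names(x), class = "ChromSizes")
}

#' Read a two-column chromosome sizes table
#'
#' @param path TSV with columns chromosome name and length, no header.
#' @return `ChromSizes`.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  chrom_sizes(tab)
}

# internal: light structural scan of a BED file so parse errors carry line
# numbers; returns the number of fields
scan_bed_fields <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- lengths(strsplit(lines[keep], "[ \t]+"))
  bad <- which(keep)[fields < 6L]
  if (length(bad))
    abort(sprintf("malformed BED line %d in %s: fewer than 6 fields",
                  bad[1L], path))
  starts <- vapply(strsplit(lines[keep], "[ \t]+"), `[`, "", 2L)
  ends <- vapply(strsplit(lines[keep], "[ \t]+"), `[`, "", 3L)
  bad <- which(keep)[is.na(suppressWarnings(as.numeric(starts))) |
                     is.na(suppressWarnings(as.numeric(ends)))]
  if (length(bad))
    abort(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                  bad[1L], path))
  min(fields)
}

#' Read gene models from GTF or BED12
#'
#' GTF coordinates (1-based closed) are converted to the internal 0-based
#' half-open convention on read; BED is native. When a GTF contains several
#' transcripts per gene, the isoform with the largest summed exon length is
#' kept (logged). Records with unknown strand are dropped with a warning.
#'
#' @param path annotation file.
#' @param format `"gtf"` or `"bed12"`; inferred from the extension if omitted.
#' @return `GeneModels`.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "bed12") read_gene_models_bed(path) else read_gene_models_gtf(path)
}

read_gene_models_bed <- function(path) {
  nfields <- scan_bed_fields(path)
  gr <- rtracklayer::import(path, format = "bed")
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st == "*")) {
    warning(sum(st == "*"), " record(s) with unknown strand dropped")
    gr <- gr[st != "*"]
    st <- st[st != "*"]
  }
  bstart <- BiocGenerics::start(gr) - 1L
  bend <- BiocGenerics::end(gr)
  exons <- vector("list", length(gr))
  cds <- vector("list", length(gr))
  if (nfields >= 12L) {
    blocks <- gr$blocks  # block ranges are relative to the feature start
    for (i in seq_along(gr)) {
      b <- blocks[[i]]
      exons[[i]] <- cbind(bstart[i] + BiocGenerics::start(b) - 1L,
                          bstart[i] + BiocGenerics::end(b))
    }
    th <- gr$thick  # zero-width thick (thickStart == thickEnd) means non-coding
    for (i in seq_along(gr)) {
      if (IRanges::width(th)[i] > 0L)
        cds[[i]] <- c(BiocGenerics::start(th)[i] - 1L, BiocGenerics::end(th)[i])
    }
  } else {
    for (i in seq_along(gr)) exons[[i]] <- cbind(bstart[i], bend[i])
  }
  name <- if (!is.null(gr$name)) gr$name else paste0("gene_", seq_along(gr))
  gene_models(gene_id = name,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              strand = st,
              tss = ifelse(st == "+", bstart, bend),
              tes = ifelse(st == "+", bend, bstart),
              exons = exons, cds = cds)
}

read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$gene_id)) abort("GTF lacks required attribute 'gene_id'")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (!length(gr)) abort("GTF contains no exon records")
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st == "*")) {
    warning(sum(st == "*"), " record(s) with unknown strand dropped")
    gr <- gr[st != "*"]
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = as.character(gr$type),
                   gene_id = gr$gene_id,
                   stringsAsFactors = FALSE)
  df$tx <- if (!is.null(gr$transcript_id)) gr$transcript_id else df$gene_id
  out <- list()
  n_multi <- 0L
  for (gid in unique(df$gene_id)) {
    g <- df[df$gene_id == gid, ]
    txs <- unique(g$tx)
    if (length(txs) > 1L) {
      n_multi <- n_multi + 1L
      span <- vapply(txs, function(t) {
        e <- g[g$tx == t & g$type == "exon", ]
        sum(e$end - e$start)
      }, 0)
      g <- g[g$tx == txs[which.max(span)], ]
    }
    ex <- g[g$type == "exon", ]
    if (!nrow(ex)) next
    ex <- ex[order(ex$start), ]
    cd <- g[g$type == "CDS", ]
    bstart <- min(ex$start); bend <- max(ex$end)
    st1 <- ex$strand[1L]
    out[[gid]] <- list(
      gene_id = gid, chrom = ex$chrom[1L], strand = st1,
      tss = if (st1 == "+") bstart else bend,
      tes = if (st1 == "+") bend else bstart,
      exons = cbind(ex$start, ex$end),
      cds = if (nrow(cd)) c(min(cd$start), max(cd$end)) else NULL)
  }
  if (n_multi) message(n_multi, " gene(s) had multiple transcripts; ",
                       "longest exonic isoform kept")
  gene_models(gene_id = vapply(out, `[[`, "", "gene_id"),
              chrom = vapply(out, `[[`, "", "chrom"),
              strand = vapply(out, `[[`, "", "strand"),
              tss = vapply(out, `[[`, 0, "tss"),
              tes = vapply(out, `[[`, 0, "tes"),
              exons = lapply(out, `[[`, "exons"),
              cds = lapply(out, `[[`, "cds"))
}

# internal: clip a 2-col interval matrix to [lo, hi), dropping empty pieces
clip_intervals <- function(mat, lo, hi) {
  if (is.null(mat) || nrow(mat) == 0L) return(matrix(numeric(), 0L, 2L))
  s <- pmax(mat[, 1L], lo); e <- pmin(mat[, 2L], hi)
  keep <- s < e
  cbind(s[keep], e[keep])
}

# internal: complement of sorted non-overlapping intervals within [lo, hi)
gap_intervals <- function(mat, lo, hi) {
  edges <- c(lo, t(mat), hi)
  s <- edges[seq(1L, length(edges), by = 2L)]
  e <- edges[seq(2L, length(edges), by = 2L)]
  keep <- s < e
  cbind(s[keep], e[keep])
}

# internal: candidate feature intervals for one gene (list class -> matrix),
# 0-based half-open, not yet clipped to the chromosome
gene_feature_candidates <- function(gene_id, strand, tss, tes, exons, cds,
                                    promoter_bp, downstream_bp) {
  bstart <- min(tss, tes); bend <- max(tss, tes)
  if (strand == "+") {
    promoter <- cbind(tss - promoter_bp, tss)
    downstream <- cbind(tes, tes + downstream_bp)
  } else {
    promoter <- cbind(tss, tss + promoter_bp)
    downstream <- cbind(tes - downstream_bp, tes)
  }
  if (is.null(cds)) {
    # non-coding gene: whole exonic sequence kept in the cds bucket so the
    # partition stays a fixed seven-class scheme
    utr5 <- matrix(numeric(), 0L, 2L)
    utr3 <- matrix(numeric(), 0L, 2L)
    cdscls <- exons
  } else {
    cdscls <- clip_intervals(exons, cds[1L], cds[2L])
    if (strand == "+") {
      utr5 <- clip_intervals(exons, bstart, cds[1L])
      utr3 <- clip_intervals(exons, cds[2L], bend)
    } else {
      utr5 <- clip_intervals(exons, cds[2L], bend)
      utr3 <- clip_intervals(exons, bstart, cds[1L])
    }
  }
  list(promoter = promoter, utr5 = utr5, cds = cdscls, utr3 = utr3,
       downstream = downstream, intron = gap_intervals(exons, bstart, bend))
}

#' Build the seven-class genome partition
#'
#' Labels every base of every chromosome with exactly one of the seven feature
#' classes. Per gene, the candidate labels are: promoter = the `promoter_bp`
#' bases upstream of the TSS (strand-aware, clipped at the chromosome edge),
#' downstream = `downstream_bp` bases past the TES, 5'UTR/CDS/3'UTR from the
#' exon and CDS structure, intron = gene body minus exons. Where candidates
#' from overlapping genes (or from one gene's own structure) collide, the
#' label earlier in `priority` wins; every base claimed by no gene is
#' intergenic. Exons of genes without an annotated CDS are counted in the
#' `cds` bucket (logged), keeping the class set fixed.
#'
#' @param genes `GeneModels`.
#' @param sizes `ChromSizes` covering every chromosome in `genes`.
#' @param promoter_bp,downstream_bp flank widths in bases (default 2000).
#' @param priority label precedence among the six gene-derived classes.
#' @return a `RegionPartition`: list with `intervals` (data frame chrom,
#'   start, end, class; half-open, sorted, disjoint, covering each chromosome),
#'   `base_counts` (named total bases per class) and `sizes`.
#' @export
build_partition <- function(genes, sizes, promoter_bp = 2000,
                            downstream_bp = 2000,
                            priority = default_priority()) {
  check_positive_scalar(promoter_bp, "promoter_bp")
  check_positive_scalar(downstream_bp, "downstream_bp")
  if (!setequal(priority, default_priority()))
    abort("priority must order exactly the six gene-derived classes")
  missing <- setdiff(unique(genes$chrom), names(sizes))
  if (length(missing))
    abort("chromosome(s) absent from sizes: ", paste(missing, collapse = ", "))
  n_noncoding <- sum(vapply(genes$cds, is.null, TRUE)) * (nrow(genes) > 0L)
  if (nrow(genes) && n_noncoding)
    message(n_noncoding, " gene(s) without CDS: exons counted as 'cds'")

  # gather candidate intervals per chromosome and class
  cand <- lapply(stats::setNames(nm = names(sizes)), function(ch)
    lapply(stats::setNames(nm = priority), function(cl) list()))
  for (i in seq_len(nrow(genes))) {
    fc <- gene_feature_candidates(genes$gene_id[i], genes$strand[i],
                                  genes$tss[i], genes$tes[i],
                                  genes$exons[[i]], genes$cds[[i]],
                                  promoter_bp, downstream_bp)
    ch <- genes$chrom[i]
    for (cl in priority)
      if (nrow(fc[[cl]]))
        cand[[ch]][[cl]][[length(cand[[ch]][[cl]]) + 1L]] <- fc[[cl]]
  }

  pieces <- vector("list", length(sizes))
  counts <- stats::setNames(numeric(7L), feature_classes())
  for (ci in seq_along(sizes)) {
    ch <- names(sizes)[ci]; L <- sizes[[ci]]
    claimed <- IRanges::IRanges()
    rows <- list()
    for (cl in priority) {
      mats <- cand[[ch]][[cl]]
      if (!length(mats)) next
      m <- do.call(rbind, mats)
      m <- clip_intervals(m, 0, L)  # chromosome-edge clipping
      if (!nrow(m)) next
      ir <- IRanges::reduce(IRanges::IRanges(m[, 1L] + 1L, m[, 2L]))
      ir <- IRanges::setdiff(ir, claimed)
      if (length(ir)) {
        rows[[cl]] <- data.frame(chrom = ch,
                                 start = BiocGenerics::start(ir) - 1L,
                                 end = BiocGenerics::end(ir),
                                 class = cl, stringsAsFactors = FALSE)
        claimed <- IRanges::union(claimed, ir)
      }
    }
    inter <- IRanges::setdiff(IRanges::IRanges(1L, L), claimed)
    if (length(inter))
      rows[["intergenic"]] <- data.frame(chrom = ch,
                                         start = BiocGenerics::start(inter) - 1L,
                                         end = BiocGenerics::end(inter),
                                         class = "intergenic",
                                         stringsAsFactors = FALSE)
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$start), , drop = FALSE]
    pieces[[ci]] <- tab
  }
  intervals <- do.call(rbind, pieces)
  rownames(intervals) <- NULL
  w <- intervals$end - intervals$start
  for (cl in feature_classes())
    counts[cl] <- sum(w[intervals$class == cl])
  structure(list(intervals = intervals, base_counts = counts,
                 sizes = sizes),
            class = "RegionPartition")
}

#' @export
print.RegionPartition <- function(x, ...) {
  cat("RegionPartition over", length(x$sizes), "chromosome(s),",
      format(sum(x$sizes), big.mark = ","), "bases\n")
  print(x$base_counts)
  invisible(x)
}

#' Look up the feature class at genomic positions
#'
#' @param partition `RegionPartition`.
#' @param chrom,pos parallel vectors of chromosome names and 0-based positions
#'   (`chrom` is recycled to the length of `pos`).
#' @return character vector of feature classes.
#' @export
partition_class_at <- function(partition, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  out <- character(length(pos))
  iv <- partition$intervals
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    L <- partition$sizes[[ch]]
    if (is.null(L)) abort("chromosome not in partition: ", ch)
    p <- pos[idx]
    if (any(p < 0 | p >= L))
      abort("position outside chromosome bounds on ", ch)
    sub <- iv[iv$chrom == ch, ]
    out[idx] <- sub$class[findInterval(p, sub$start)]
  }
  out
}

#' Write a partition as BED (class in the name column) and base counts as TSV
#'
#' @param partition `RegionPartition`.
#' @param bed_path output BED path.
#' @param counts_path optional TSV path for the per-class base counts.
#' @return invisibly, the paths written.
#' @export
write_partition <- function(partition, bed_path, counts_path = NULL) {
  iv <- partition$intervals
  utils::write.table(
    data.frame(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
               format(iv$end, scientific = FALSE, trim = TRUE), iv$class),
    bed_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(counts_path))
    utils::write.table(
      data.frame(class = names(partition$base_counts),
                 bases = format(partition$base_counts, scientific = FALSE,
                                trim = TRUE)),
      counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed_path, counts_path))
}
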