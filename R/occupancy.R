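#' Genes occupied by at least one peak
#'
#' A gene is occupied when at least one peak interval overlaps, by one base or
#' more, the union of its strand-aware promoter (the `promoter_bp` bases
#' upstream of the TSS) and its gene body (TSS to TES including introns).
#' Because the promoter abuts the body, that union is a single interval.
#'
#' @param peaks `PeakSet`.
#' @param genes `GeneModels`.
#' @param promoter_bp promoter width in bases (default 2000).
#' @return sorted character vector of occupied gene ids.
#' @export
occupied_genes <- function(peaks, genes, promoter_bp = 2000) {
  check_positive_scalar(promoter_bp, "promoter_bp")
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(character())
  bstart <- pmin(genes$tss, genes$tes)
  bend <- pmax(genes$tss, genes$tes)
  rs <- ifelse(genes$strand == "+", bstart - promoter_bp, bstart)
  re <- ifelse(genes$strand == "+", bend, bend + promoter_bp)
  occ <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0L) next
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(rs[gi] + 1L, re[gi]),
      IRanges::IRanges(pk$start + 1L, pk$end))
    occ[gi] <- hit
  }
  sort(genes$gene_id[occ])
}

#' Three-way occupied-gene set decomposition (Venn regions)
#'
#' @param sets named list of exactly three character vectors of gene ids;
#'   names must be unique sample ids.
#' @return named numeric vector with the seven Venn region counts: one
#'   `<id>_only` per sample, one `<id1>_<id2>` per pair (genes in exactly
#'   those two) and `all_three`.
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3L) abort("venn_counts needs exactly 3 sets")
  ids <- names(sets)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    abort("sets must carry unique non-empty sample ids")
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets, use.names = FALSE))
  inA <- u %in% sets[[1L]]; inB <- u %in% sets[[2L]]; inC <- u %in% sets[[3L]]
  out <- c(sum(inA & !inB & !inC), sum(!inA & inB & !inC),
           sum(!inA & !inB & inC), sum(inA & inB & !inC),
           sum(inA & !inB & inC), sum(!inA & inB & inC),
           sum(inA & inB & inC))
  names(out) <- c(paste0(ids, "_only"),
                  paste(ids[1L], ids[2L], sep = "_"),
                  paste(ids[1L], ids[3L], sep = "_"),
                  paste(ids[2L], ids[3L], sep = "_"),
                  "all_three")
  out
}

#' Write per-sample occupied-gene lists
#'
#' @param occupancy named list sample id -> character vector of gene ids.
#' @param out_dir output directory (created if needed).
#' @return invisibly, named vector of file paths written.
#' @export
sample_gene_lists <- function(occupancy, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in names(occupancy)) {
    p <- file.path(out_dir, paste0(id, "_occupied_genes.tsv"))
    writeLines(sort(unique(occupancy[[id]])), p)
    message(id, ": ", length(unique(occupancy[[id]])), " occupied genes -> ", p)
    paths[id] <- p
  }
  invisible(paths)
}
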