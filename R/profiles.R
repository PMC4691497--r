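#' Per-base normalized coverage of extended tags over a region
#'
#' Every tag is extended from its 5' end to `extension` bases in the 3'
#' direction; coverage counts the extended fragments overlapping each base and
#' is scaled to reads per million (1e6 / library size).
#'
#' @param tags `TagSet`.
#' @param chrom chromosome.
#' @param start,end half-open region (0-based); `start < end`.
#' @param extension fragment extension in bases.
#' @return numeric vector of length `end - start` (RPM per base).
#' @export
coverage_vector <- function(tags, chrom, start, end, extension = 150) {
  if (start >= end) abort("inverted interval: start must be < end")
  pos <- tags$positions[[chrom]]
  if (is.null(pos))
    return(numeric(end - start))
  strand <- tags$strands[[chrom]]
  lo <- findInterval(start - extension - 0.5, pos) + 1L
  hi <- findInterval(end + extension - 0.5, pos)
  idx <- if (lo <= hi) lo:hi else integer()
  extended_pileup(pos[idx], strand[idx], start, end, extension) *
    1e6 / tags$library_size
}

#' Composite (metagene) coverage profile anchored at TSS or TES
#'
#' For every gene the `[anchor - flank, anchor + flank)` region is extracted,
#' oriented 5'→3' relative to the gene strand (minus-strand regions are
#' reversed), averaged within consecutive windows, and the per-window values
#' are averaged over genes. Genes whose region crosses a chromosome boundary
#' are excluded and counted in a message.
#'
#' @param tags `TagSet`.
#' @param genes `GeneModels`.
#' @param sizes `ChromSizes`.
#' @param anchor `"TSS"` or `"TES"`.
#' @param flank bases on each side of the anchor (default 5000).
#' @param window window width in bases (default 200); must divide `flank`.
#' @param extension tag extension for the pileup.
#' @return a `ProfileCurve`: list with `anchor`, `flank`, `window`, `values`
#'   (mean RPM per window, length `2 * flank / window`), `offsets` (window
#'   midpoints relative to the anchor) and `n_genes` included.
#' @export
composite_profile <- function(tags, genes, sizes, anchor = c("TSS", "TES"),
                              flank = 5000, window = 200, extension = 150) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0L) abort("no genes supplied")
  if (flank %% window != 0) abort("flank must be divisible by window")
  nwin <- 2L * flank / window
  acc <- numeric(2L * flank)
  n_used <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    a <- if (anchor == "TSS") genes$tss[i] else genes$tes[i]
    ch <- genes$chrom[i]
    L <- sizes[[ch]]
    if (is.null(L)) abort("chromosome absent from sizes: ", ch)
    rs <- a - flank; re <- a + flank
    if (rs < 0 || re > L) { n_skipped <- n_skipped + 1L; next }
    cv <- coverage_vector(tags, ch, rs, re, extension)
    if (genes$strand[i] == "-") cv <- rev(cv)
    acc <- acc + cv
    n_used <- n_used + 1L
  }
  if (n_used == 0L) abort("no gene region fits inside its chromosome")
  if (n_skipped) message(n_skipped, " gene(s) excluded: region crosses a ",
                         "chromosome boundary")
  mean_cov <- acc / n_used
  values <- colMeans(matrix(mean_cov, nrow = window, ncol = nwin))
  structure(list(anchor = anchor, flank = flank, window = window,
                 values = values,
                 offsets = seq(-flank + window / 2, flank - window / 2,
                               by = window),
                 n_genes = n_used),
            class = "ProfileCurve")
}

#' @export
print.ProfileCurve <- function(x, ...) {
  cat("ProfileCurve at", x$anchor, "+/-", x$flank, "bp,",
      length(x$values), "windows of", x$window, "bp, n_genes =", x$n_genes,
      "\n")
  invisible(x)
}

#' Anchor-window statistics of a composite profile
#'
#' Summarizes the bimodality of a composite curve around its anchor: the value
#' of the anchor window (the window containing the anchor position, i.e. the
#' first window on its 3' side) and the maximum over the windows strictly
#' upstream / downstream of it.
#'
#' @param curve a `ProfileCurve`.
#' @return list with `anchor_value`, `left_max`, `right_max`.
#' @export
profile_anchor_stats <- function(curve) {
  v <- curve$values
  i <- length(v) / 2 + 1L  # window covering [anchor, anchor + window)
  list(anchor_value = v[i],
       left_max = max(v[seq_len(i - 1L)]),
       right_max = max(v[seq(i + 1L, length(v))]))
}

#' Stratify genes into expression classes
#'
#' Genes are ranked by decreasing expression (ties broken by gene id, so the
#' split is deterministic) and cut into `n_classes` contiguous blocks of
#' near-equal size; when the count does not divide evenly the extra genes go
#' to the highest-expression classes. With the default four classes the labels
#' are high, middle, low, lowest.
#'
#' @param expr data frame with columns `gene_id` and `expression`
#'   (non-negative).
#' @param n_classes number of classes (default 4).
#' @return named factor: gene id -> class, levels ordered high to low.
#' @export
stratify_by_expression <- function(expr, n_classes = 4) {
  if (nrow(expr) < n_classes)
    abort("need at least as many genes as classes")
  if (any(expr$expression < 0)) abort("expression values must be non-negative")
  labels <- if (n_classes == 4) c("high", "middle", "low", "lowest")
            else paste0("class", seq_len(n_classes))
  o <- order(-expr$expression, expr$gene_id)
  n <- nrow(expr)
  size <- rep(n %/% n_classes, n_classes)
  rem <- n %% n_classes
  if (rem) size[seq_len(rem)] <- size[seq_len(rem)] + 1L
  cls <- factor(rep(labels, times = size), levels = labels)
  stats::setNames(cls, expr$gene_id[o])
}

#' Expression-stratified composite profiles
#'
#' @param tags `TagSet`.
#' @param genes `GeneModels`.
#' @param sizes `ChromSizes`.
#' @param expr expression table (`gene_id`, `expression`) covering the genes.
#' @param n_classes number of expression classes.
#' @param ... passed to [composite_profile()].
#' @return named list class -> `ProfileCurve`, ordered high to low expression.
#' @export
stratified_profiles <- function(tags, genes, sizes, expr, n_classes = 4, ...) {
  cls <- stratify_by_expression(expr, n_classes)
  out <- list()
  for (lv in levels(cls)) {
    ids <- names(cls)[cls == lv]
    sub <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L)
      abort("expression class '", lv, "' contains no annotated gene")
    out[[lv]] <- composite_profile(tags, sub, sizes, ...)
  }
  out
}

#' Write one or more profile curves as a TSV matrix
#'
#' @param profiles a `ProfileCurve` or named list of them (same geometry).
#' @param path output TSV; first column is the window midpoint offset from the
#'   anchor, remaining columns one per curve.
#' @return invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "ProfileCurve")) profiles <- list(profile = profiles)
  tab <- data.frame(offset = profiles[[1L]]$offsets)
  for (nm in names(profiles)) tab[[nm]] <- profiles[[nm]]$values
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
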