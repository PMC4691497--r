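#' Construct a tag set
#'
#' A `TagSet` holds the 5' positions and strands of aligned ChIP tags for one
#' sample, sorted per chromosome. The 5' position of a plus-strand tag is its
#' leftmost base; of a minus-strand tag its rightmost.
#'
#' @param sample_id sample label.
#' @param positions named list, per chromosome, of 0-based 5' positions.
#' @param strands named list parallel to `positions` with `"+"`/`"-"`.
#' @param read_length sequenced read length in bases.
#' @return a `TagSet`.
#' @export
tag_set <- function(sample_id, positions, strands, read_length = 49) {
  if (!identical(names(positions), names(strands)))
    abort("positions and strands must cover the same chromosomes")
  for (ch in names(positions)) {
    if (length(positions[[ch]]) != length(strands[[ch]]))
      abort("positions/strands length mismatch on ", ch)
    o <- order(positions[[ch]])
    positions[[ch]] <- as.numeric(positions[[ch]][o])
    strands[[ch]] <- strands[[ch]][o]
    if (!all(strands[[ch]] %in% c("+", "-")))
      abort("strands must be '+' or '-'")
  }
  structure(list(sample_id = sample_id, positions = positions,
                 strands = strands,
                 library_size = sum(lengths(positions)),
                 read_length = read_length),
            class = "TagSet")
}

#' @export
print.TagSet <- function(x, ...) {
  cat("TagSet", x$sample_id, "-", format(x$library_size, big.mark = ","),
      "tags on", length(x$positions), "chromosome(s)\n")
  invisible(x)
}

#' Read aligned tags from a BED-like file
#'
#' Expects at least six tab-separated columns (chrom, start, end, name, score,
#' strand); the tag 5' position is the start for plus-strand records and
#' end − 1 for minus-strand records.
#'
#' @param path tag file.
#' @param sample_id sample label.
#' @param sizes optional `ChromSizes`; when given, tags on unknown
#'   chromosomes are an error.
#' @param read_length read length recorded on the `TagSet`.
#' @return a `TagSet`.
#' @export
read_tags <- function(path, sample_id, sizes = NULL, read_length = 49) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1L))
  if (ncol(dt) < 6L) abort("tag file needs >= 6 BED columns: ", path)
  data.table::setnames(dt, 1:6, c("chrom", "start", "end", "name", "score",
                                  "strand"))
  if (!all(dt$strand %in% c("+", "-")))
    abort("tag file has records without '+'/'-' strand")
  if (!is.null(sizes)) {
    unknown <- setdiff(unique(dt$chrom), names(sizes))
    if (length(unknown))
      abort("tags on chromosome(s) absent from sizes: ",
            paste(unknown, collapse = ", "))
  }
  pos <- ifelse(dt$strand == "+", dt$start, dt$end - 1L)
  tag_set(sample_id,
          positions = split(pos, dt$chrom),
          strands = split(dt$strand, dt$chrom),
          read_length = read_length)
}

#' Write a tag set as BED6
#'
#' @param tags `TagSet`.
#' @param path output path.
#' @param read_span span written per record (end − start); cosmetic only, the
#'   5' convention round-trips regardless.
#' @return invisibly, `path`.
#' @export
write_tags <- function(tags, path, read_span = tags$read_length) {
  parts <- lapply(names(tags$positions), function(ch) {
    p <- tags$positions[[ch]]; s <- tags$strands[[ch]]
    start <- ifelse(s == "+", p, p - read_span + 1L)
    data.table::data.table(chrom = ch, start = start, end = start + read_span,
                           name = "tag", score = 0L, strand = s)
  })
  dt <- data.table::rbindlist(parts)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Peak-caller parameters
#'
#' Defaults follow the published MACS run this caller stands in for: Poisson
#' p-value threshold 1e-4 and 300 bp band width. `mfold` is accepted for
#' interface compatibility with that run but is unused here: the caller does
#' not build a shift model and instead extends every tag by a fixed
#' `extension` (a note is logged when a non-default mfold is supplied).
#'
#' @param p_threshold upper-tail Poisson p-value cutoff.
#' @param bandwidth band width in bases; windows are `2 * bandwidth` wide and
#'   slide by `bandwidth / 2`.
#' @param mfold accepted, unused (no shift-model building).
#' @param extension fragment extension of each tag 5' end, in bases.
#' @return a `PeakCallParams` list.
#' @export
peak_call_params <- function(p_threshold = 1e-4, bandwidth = 300,
                             mfold = 32, extension = 150) {
  if (!(p_threshold > 0 && p_threshold < 1)) abort("p_threshold must be in (0,1)")
  check_positive_scalar(bandwidth, "bandwidth")
  check_positive_scalar(extension, "extension")
  if (!identical(mfold, 32) && !identical(mfold, 32L))
    message("mfold = ", mfold, " accepted but unused (fixed-extension caller)")
  structure(list(p_threshold = p_threshold, bandwidth = bandwidth,
                 mfold = mfold, extension = extension),
            class = "PeakCallParams")
}

# internal: pileup of extension-extended tags over [rstart, rend), 0-based
# half-open; returns integer coverage of length rend - rstart
extended_pileup <- function(pos, strand, rstart, rend, extension) {
  fs <- ifelse(strand == "+", pos, pos - extension + 1)
  fe <- fs + extension
  s <- pmax(fs, rstart); e <- pmin(fe, rend)
  keep <- s < e
  n <- rend - rstart
  if (!any(keep)) return(numeric(n))
  si <- s[keep] - rstart + 1L; ei <- e[keep] - rstart + 1L
  delta <- tabulate(si, nbins = n + 1L) - tabulate(ei, nbins = n + 1L)
  cumsum(delta)[seq_len(n)]
}

#' Call enriched intervals with a Poisson sliding window
#'
#' A deliberately simple genome-wide-background caller: the background rate is
#' `library_size / genome_length` tags per base; windows of width
#' `2 * bandwidth` slide by `bandwidth / 2`; a window with `k` tag 5' ends is
#' significant when the Poisson upper tail P(X >= k) at the window expectation
#' falls below `p_threshold`; significant windows separated by at most
#' `bandwidth` are merged; within each merged region the summit is the maximum
#' of the extended-tag pileup and the score is −log10 of the best constituent
#' window p-value. No local-lambda correction and no control subtraction are
#' performed.
#'
#' @param tags `TagSet` with `library_size > 0`.
#' @param sizes `ChromSizes`.
#' @param params `PeakCallParams`.
#' @return data frame of class `PeakSet` with columns chrom, start, end
#'   (half-open), summit, tag_count, score; sorted by position. Scan
#'   diagnostics are attached as attributes `lambda_bg`, `n_windows` and
#'   `n_significant`.
#' @export
call_peaks <- function(tags, sizes, params = peak_call_params()) {
  if (tags$library_size <= 0) abort("empty TagSet: no tags to call peaks on")
  genome_length <- sum(sizes)
  if (genome_length <= 0) abort("genome length must be positive")
  lambda_bg <- tags$library_size / genome_length
  width <- 2 * params$bandwidth
  step <- params$bandwidth / 2
  log10_thr <- log10(params$p_threshold)
  out <- list()
  n_windows <- 0
  n_significant <- 0
  for (ch in names(tags$positions)) {
    L <- sizes[[ch]]
    if (is.null(L) || is.na(L)) abort("chromosome absent from sizes: ", ch)
    pos <- tags$positions[[ch]]
    if (!length(pos)) next
    starts <- if (L <= width) 0 else seq(0, L - width, by = step)
    w <- pmin(starts + width, L) - starts
    n_windows <- n_windows + length(starts)
    k <- findInterval(starts + w - 0.5, pos) - findInterval(starts - 0.5, pos)
    mu <- lambda_bg * w
    log10p <- stats::ppois(k - 1, mu, lower.tail = FALSE, log.p = TRUE) / log(10)
    sig <- which(log10p < log10_thr)
    n_significant <- n_significant + length(sig)
    if (!length(sig)) next
    # merge significant windows whose gap is <= bandwidth
    ws <- starts[sig]; we <- starts[sig] + w[sig]; wp <- log10p[sig]
    brk <- c(TRUE, ws[-1L] - we[-length(we)] > params$bandwidth)
    grp <- cumsum(brk)
    strand <- tags$strands[[ch]]
    peaks <- lapply(split(seq_along(grp), grp), function(ix) {
      rstart <- ws[ix[1L]]; rend <- max(we[ix])
      lo <- findInterval(rstart - params$extension - 0.5, pos) + 1L
      hi <- findInterval(rend + params$extension - 0.5, pos)
      idx <- if (lo <= hi) lo:hi else integer()
      cov <- extended_pileup(pos[idx], strand[idx], rstart, rend,
                             params$extension)
      n_in <- findInterval(rend - 0.5, pos) - findInterval(rstart - 0.5, pos)
      data.frame(chrom = ch, start = rstart, end = rend,
                 summit = rstart + which.max(cov) - 1L,
                 tag_count = n_in, score = -min(wp[ix]),
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, peaks)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               summit = numeric(), tag_count = numeric(), score = numeric())
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("PeakSet", "data.frame")
  attr(res, "lambda_bg") <- lambda_bg
  attr(res, "n_windows") <- n_windows
  attr(res, "n_significant") <- n_significant
  res
}

#' Summarize called peaks (counts and length statistics)
#'
#' @param peaks `PeakSet` (or any data frame with start/end), non-empty.
#' @return list with `n_peaks`, `total_length`, `mean_length` (rounded
#'   half-up to integer) and `median_length` (midpoint of the two middle
#'   values for even counts).
#' @export
summarize_peaks <- function(peaks) {
  if (nrow(peaks) == 0L) abort("cannot summarize an empty peak list")
  len <- peaks$end - peaks$start
  total <- sum(len)
  list(n_peaks = nrow(peaks), total_length = total,
       mean_length = round_half_up(total / nrow(peaks)),
       median_length = stats::median(len))
}

#' Summarize a sequencing library (report-table arithmetic)
#'
#' @param total_reads total clean reads.
#' @param read_length read length in bases.
#' @param mapped_reads reads mapped to the genome.
#' @param unique_mapped_reads reads mapped to a unique location.
#' @return list with `output_bases = total_reads * read_length` and mapped /
#'   unique percentages (100 x count / total_reads, rounded half-up to two
#'   decimals).
#' @export
summarize_library <- function(total_reads, read_length, mapped_reads,
                              unique_mapped_reads) {
  check_positive_scalar(total_reads, "total_reads")
  check_positive_scalar(read_length, "read_length")
  if (!(unique_mapped_reads >= 0 && unique_mapped_reads <= mapped_reads &&
        mapped_reads <= total_reads))
    abort("need 0 <= unique_mapped_reads <= mapped_reads <= total_reads")
  list(total_reads = total_reads, read_length = read_length,
       output_bases = total_reads * read_length,
       mapped_reads = mapped_reads,
       unique_mapped_reads = unique_mapped_reads,
       mapped_pct = round_half_up(100 * mapped_reads / total_reads, 2),
       unique_pct = round_half_up(100 * unique_mapped_reads / total_reads, 2))
}

#' Write / read peaks as BED6+2
#'
#' Columns: chrom, start, end, name, score (−log10 p, 4 decimals), strand
#' (`.`), summit offset from start, tag count. `read_peaks(write_peaks(x))`
#' reproduces `x` with scores equal to within 1e-4.
#'
#' @param peaks `PeakSet`.
#' @param path file path.
#' @return `write_peaks`: invisibly `path`; `read_peaks`: a `PeakSet`.
#' @export
write_peaks <- function(peaks, path) {
  dt <- data.table::data.table(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = sprintf("%.4f", peaks$score), strand = ".",
    summit_offset = peaks$summit - peaks$start, tag_count = peaks$tag_count)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1L, 4L, 6L)))
  if (ncol(dt) != 8L) abort("malformed peak file (expected 8 columns): ", path)
  res <- data.frame(chrom = dt$V1, start = dt$V2, end = dt$V3,
                    summit = dt$V2 + dt$V7, tag_count = dt$V8,
                    score = as.numeric(dt$V5), stringsAsFactors = FALSE)
  bad <- which(res$start >= res$end | res$summit < res$start |
               res$summit >= res$end)
  if (length(bad))
    abort("invalid peak record(s) at row ", bad[1L],
          ": need start < end and start <= summit < end")
  class(res) <- c("PeakSet", "data.frame")
  res
}
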