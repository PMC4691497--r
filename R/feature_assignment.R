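#' Assign peaks to feature classes by summit position
#'
#' Each peak is assigned to exactly one of the seven classes: the class of the
#' partition interval containing its summit. Summit assignment (rather than
#' midpoint or any-overlap multi-counting) keeps class fractions summing to 1.
#'
#' @param peaks `PeakSet`.
#' @param partition `RegionPartition`.
#' @return character vector of feature classes, one per peak.
#' @export
assign_peak <- function(peaks, partition) {
  if (nrow(peaks) == 0L) return(character())
  partition_class_at(partition, peaks$chrom, peaks$summit)
}

#' Peak distribution over the seven feature classes
#'
#' @param peaks non-empty `PeakSet`.
#' @param partition `RegionPartition`.
#' @return data frame with one row per class (all seven always present):
#'   `class`, `peak_count`, `peak_fraction`.
#' @export
peak_distribution <- function(peaks, partition) {
  if (nrow(peaks) == 0L) abort("cannot compute a distribution of zero peaks")
  cls <- factor(assign_peak(peaks, partition), levels = feature_classes())
  counts <- as.vector(table(cls))
  data.frame(class = feature_classes(), peak_count = counts,
             peak_fraction = counts / nrow(peaks), stringsAsFactors = FALSE)
}

#' Relative enrichment of peaks per feature class
#'
#' For each class, relative enrichment is (fraction of peaks whose summit
#' falls in the class) / (fraction of genomic bases the class covers). A value
#' of 1 means no preference; the base-fraction-weighted mean of the ratios is
#' always exactly 1.
#'
#' @param dist distribution table from [peak_distribution()].
#' @param partition `RegionPartition`.
#' @return data frame `class`, `peak_count`, `peak_fraction`, `base_fraction`,
#'   `relative_enrichment`. Classes with zero bases and zero peaks are
#'   omitted; a class with peaks but zero bases is an error (impossible under
#'   a complete partition).
#' @export
relative_enrichment <- function(dist, partition) {
  bases <- partition$base_counts[dist$class]
  total_bases <- sum(partition$base_counts)
  impossible <- dist$peak_count > 0 & bases == 0
  if (any(impossible))
    abort("peaks assigned to class(es) with zero bases: ",
          paste(dist$class[impossible], collapse = ", "))
  keep <- bases > 0
  out <- dist[keep, , drop = FALSE]
  out$base_fraction <- bases[keep] / total_bases
  out$relative_enrichment <- out$peak_fraction / out$base_fraction
  rownames(out) <- NULL
  out
}

#' Write the per-sample feature distribution / enrichment table
#'
#' @param enr table from [relative_enrichment()].
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_enrichment <- function(enr, path) {
  utils::write.table(enr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
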