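#' Read a pipeline run configuration from YAML
#'
#' Required keys: `samples` (list of `{id, tags}`), `annotation`, `sizes`,
#' `out_dir`. Optional: `expression`, `seed`, and a `params` block overriding
#' any of p_threshold, bandwidth, extension, promoter_bp, downstream_bp,
#' flank, window, n_classes.
#'
#' @param path YAML file.
#' @return a `RunConfig` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(samples = cfg$samples, annotation = cfg$annotation,
             sizes = cfg$sizes, out_dir = cfg$out_dir,
             expression = cfg$expression, seed = cfg$seed %||% 1,
             params = cfg$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a pipeline run configuration
#'
#' @param samples list of `list(id =, tags = path)` entries.
#' @param annotation gene annotation path (GTF or BED12).
#' @param sizes chromosome sizes TSV path.
#' @param out_dir output directory.
#' @param expression optional expression TSV (`gene_id`, `expression`).
#' @param seed integer seed recorded in the report.
#' @param params named list of parameter overrides (see [read_run_config()]).
#' @return a `RunConfig` list.
#' @export
run_config <- function(samples, annotation, sizes, out_dir,
                       expression = NULL, seed = 1, params = list()) {
  ids <- vapply(samples, `[[`, "", "id")
  if (anyDuplicated(ids)) abort("sample ids must be unique")
  defaults <- list(p_threshold = 1e-4, bandwidth = 300, extension = 150,
                   promoter_bp = 2000, downstream_bp = 2000,
                   flank = 5000, window = 200, n_classes = 4)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    abort("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  for (p in c(annotation, sizes, expression,
              vapply(samples, `[[`, "", "tags")))
    if (!file.exists(p)) abort("input path does not exist: ", p)
  structure(list(samples = samples, annotation = annotation, sizes = sizes,
                 expression = expression, out_dir = out_dir,
                 seed = as.integer(seed), params = defaults),
            class = "RunConfig")
}

# internal: run one stage, aborting with the stage name on error
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full occupancy analysis pipeline
#'
#' Tags -> peaks -> feature distribution and relative enrichment -> TSS/TES
#' composite profiles (expression-stratified when an expression table is
#' configured) -> occupied-gene sets (with the three-way Venn decomposition
#' when exactly three samples are given). Every intermediate is written under
#' `out_dir` and the returned report (also written as `report.json`) lists the
#' summary numbers plus each file with its md5 checksum, so a re-run on
#' identical inputs is byte-verifiable.
#'
#' @param config `RunConfig` from [run_config()] or [read_run_config()].
#' @return the run report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prm <- config$params
  sizes <- run_stage("read_sizes", read_chrom_sizes(config$sizes))
  genes <- run_stage("read_annotation", read_gene_models(config$annotation))
  expr <- if (!is.null(config$expression))
    run_stage("read_expression",
              utils::read.delim(config$expression,
                                colClasses = c("character", "numeric")))
  partition <- run_stage("build_partition",
                         build_partition(genes, sizes, prm$promoter_bp,
                                         prm$downstream_bp))
  files <- character(0)
  emit <- function(key, path) files[key] <<- path
  emit("partition", write_partition(partition,
                                    file.path(config$out_dir, "partition.bed"),
                                    file.path(config$out_dir,
                                              "base_counts.tsv"))[1L])
  emit("base_counts", file.path(config$out_dir, "base_counts.tsv"))

  report <- list(seed = config$seed, params = prm,
                 n_genes = nrow(genes),
                 genome_length = sum(sizes),
                 base_counts = as.list(partition$base_counts),
                 samples = list())
  occupancy <- list()
  pcp <- peak_call_params(p_threshold = prm$p_threshold,
                          bandwidth = prm$bandwidth,
                          extension = prm$extension)
  for (s in config$samples) {
    id <- s$id
    tags <- run_stage(paste0("read_tags:", id),
                      read_tags(s$tags, id, sizes))
    peaks <- run_stage(paste0("call_peaks:", id),
                       call_peaks(tags, sizes, pcp))
    pk_path <- file.path(config$out_dir, paste0("peaks_", id, ".bed"))
    write_peaks(peaks, pk_path); emit(paste0("peaks_", id), pk_path)
    smp <- list(library_size = tags$library_size)
    if (nrow(peaks)) {
      smp$peaks <- summarize_peaks(peaks)
      dist <- peak_distribution(peaks, partition)
      enr <- relative_enrichment(dist, partition)
      enr_path <- file.path(config$out_dir, paste0("enrichment_", id, ".tsv"))
      write_enrichment(enr, enr_path); emit(paste0("enrichment_", id), enr_path)
      smp$distribution <- stats::setNames(as.list(dist$peak_fraction),
                                          dist$class)
      smp$relative_enrichment <-
        stats::setNames(as.list(enr$relative_enrichment), enr$class)
      occupancy[[id]] <- occupied_genes(peaks, genes, prm$promoter_bp)
      smp$n_occupied_genes <- length(occupancy[[id]])
    } else {
      smp$peaks <- list(n_peaks = 0)
      occupancy[[id]] <- character()
      smp$n_occupied_genes <- 0L
    }
    profs <- list(
      TSS = run_stage(paste0("profile_tss:", id),
                      composite_profile(tags, genes, sizes, "TSS", prm$flank,
                                        prm$window, prm$extension)),
      TES = run_stage(paste0("profile_tes:", id),
                      composite_profile(tags, genes, sizes, "TES", prm$flank,
                                        prm$window, prm$extension)))
    pr_path <- file.path(config$out_dir, paste0("profiles_", id, ".tsv"))
    write_profiles(profs, pr_path); emit(paste0("profiles_", id), pr_path)
    if (!is.null(expr)) {
      strat <- run_stage(paste0("stratified_profiles:", id),
                         stratified_profiles(tags, genes, sizes, expr,
                                             prm$n_classes, anchor = "TSS",
                                             flank = prm$flank,
                                             window = prm$window,
                                             extension = prm$extension))
      st_path <- file.path(config$out_dir,
                           paste0("profiles_by_expression_", id, ".tsv"))
      write_profiles(strat, st_path)
      emit(paste0("profiles_by_expression_", id), st_path)
      smp$max_profile_by_class <- lapply(strat, function(p) max(p$values))
    } else {
      smp$stratified_profiles <- "skipped: no expression table configured"
    }
    report$samples[[id]] <- smp
  }
  gl <- sample_gene_lists(occupancy, file.path(config$out_dir, "occupancy"))
  for (id in names(gl)) emit(paste0("occupied_", id), gl[id])
  if (length(occupancy) == 3L) {
    vc <- venn_counts(occupancy)
    report$venn <- as.list(vc)
    vc_path <- file.path(config$out_dir, "venn_counts.json")
    jsonlite::write_json(as.list(vc), vc_path, auto_unbox = TRUE, digits = NA)
    emit("venn", vc_path)
  }
  report$files <- lapply(stats::setNames(nm = names(files)), function(k)
    list(path = unname(files[k]),
         md5 = unname(tools::md5sum(files[k]))))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
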