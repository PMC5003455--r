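#' Map genes into CNV regions
#'
#' A gene is assigned to a region when it overlaps it by at least 1 bp,
#' so both partially and fully included genes are reported.
#'
#' @param regions data.frame of regions (`chrom`, `start`, `end`; extra
#'   columns carried through by row index).
#' @param genes Gene annotation data.frame (see [read_genes()]).
#' @return data.frame with one row per (region, gene) pair: `region_idx`
#'   (row index into `regions`), `chrom`, `start`, `end` of the region,
#'   `gene`, `synonyms`. Zero rows when nothing overlaps.
#' @export
map_genes <- function(regions, genes) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- genes$chrom == r$chrom &
      overlap_bp(r$start, r$end, genes$start, genes$end) >= 1
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        region_idx = i, chrom = r$chrom, start = r$start, end = r$end,
        gene = genes$name[hit], synonyms = genes$synonyms[hit],
        stringsAsFactors = FALSE
      )
  }
  if (length(out) == 0L)
    return(data.frame(region_idx = integer(), chrom = character(),
                      start = numeric(), end = numeric(), gene = character(),
                      synonyms = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag mapped genes present in a candidate-gene list
#'
#' Matching is case-insensitive on the gene name and on any of its
#' synonyms (so a list entry `ARNTL` flags an annotation row named
#' `ARNTL` as well as one whose synonyms include `BMAL1` only if the name
#' or a synonym matches). Duplicate list entries are deduplicated with a
#' warning.
#'
#' @param gene_map data.frame from [map_genes()].
#' @param candidates Character vector of candidate gene symbols.
#' @return `gene_map` with a logical `candidate` column appended.
#' @export
intersect_candidates <- function(gene_map, candidates) {
  if (anyDuplicated(toupper(candidates))) {
    warning("duplicate names in candidate list; deduplicated", call. = FALSE)
  }
  cand <- unique(toupper(candidates))
  gene_map$candidate <- vapply(seq_len(nrow(gene_map)), function(i) {
    names_i <- toupper(c(gene_map$gene[i],
                         .status_set(gene_map$synonyms[i])))
    any(names_i %in% cand)
  }, TRUE)
  gene_map
}

#' Write the report bundle for a pipeline run
#'
#' Emits deterministic TSV/JSON reports for every stage: the QC report,
#' calls and regions (BED-like), the classified-region table, the burden
#' table, per-region signal tests, the gene map, and a run log carrying
#' the seed, a config hash and the stage counts. Region lengths are
#' printed at 2 decimals in the signal-test table and 3 decimals in the
#' region tables. Writing the same results twice produces byte-identical
#' files.
#'
#' @param results Named list of stage outputs as assembled by
#'   [run_pipeline()]; missing elements are skipped.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
emit_reports <- function(results, outdir) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(outdir), sprintf("cannot create output directory %s", outdir))
  written <- character()
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    written <<- c(written, path)
  }
  if (!is.null(results$qc_report))
    emit("qc_report.json", function(p)
      jsonlite::write_json(unclass(results$qc_report), p, auto_unbox = TRUE))
  if (!is.null(results$calls))
    emit("calls.bed.tsv", function(p) write_bedlike(results$calls, p))
  if (!is.null(results$regions)) {
    reg <- results$regions
    reg$length_kb <- format_kb(reg$start, reg$end, digits = 3L)
    emit("regions.bed.tsv", function(p) write_bedlike(reg, p))
  }
  if (!is.null(results$classified)) {
    cl <- results$classified
    cl$length_kb <- format_kb(cl$start, cl$end, digits = 3L)
    emit("classified_regions.tsv", function(p)
      utils::write.table(cl, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if (!is.null(results$category_summary)) {
    emit("category_summary.tsv", function(p)
      utils::write.table(results$category_summary$table, p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
    emit("category_summary.json", function(p)
      jsonlite::write_json(list(
        n_informative = results$category_summary$n_informative,
        table = results$category_summary$table), p, auto_unbox = TRUE,
        dataframe = "rows", na = "null"))
  }
  if (!is.null(results$burden))
    emit("burden.tsv", function(p)
      utils::write.table(results$burden, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  if (!is.null(results$signal_tests)) {
    st <- results$signal_tests
    st$length_kb <- format_kb(st$start, st$end, digits = 2L)
    emit("signal_tests.tsv", function(p)
      utils::write.table(st, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if (!is.null(results$gene_map))
    emit("gene_map.tsv", function(p)
      utils::write.table(results$gene_map, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  emit("run_log.txt", function(p) {
    lines <- c(
      sprintf("seed\t%s", results$seed %||% NA),
      sprintf("config_hash\t%s", results$config_hash %||% NA),
      sprintf("n_markers_input\t%s", results$qc_report$n_input %||% NA),
      sprintf("n_markers_retained\t%s", results$qc_report$n_retained %||% NA),
      sprintf("n_calls\t%s", if (is.null(results$calls)) NA else nrow(results$calls)),
      sprintf("n_regions\t%s", if (is.null(results$regions)) NA else nrow(results$regions)),
      sprintf("n_informative\t%s",
              results$category_summary$n_informative %||% NA)
    )
    writeLines(lines, p)
  })
  invisible(written)
}

# Stable hash of a configuration list, for the run log.
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(.de_class(config), auto_unbox = TRUE,
                              force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.de_class <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), .de_class))
  x
}
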