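#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's parameters. Input data come either from a
#' simulation config (`sim`) or from a dataset directory on disk
#' (`dataset_path`); the reference CNV map, gene annotation and candidate
#' list are optional file paths (stages needing them are skipped when
#' absent).
#'
#' @param sim A [sim_config()] object, or `NULL` to read from
#'   `dataset_path`.
#' @param dataset_path Directory holding `signals.tsv` / `pools.tsv` /
#'   `truth.bed` (see [read_dataset()]).
#' @param refmap_path BED-like reference CNV map file, or `NULL`.
#' @param genes_path BED-like gene annotation file, or `NULL`.
#' @param candidates_path Candidate-gene list file, or `NULL`.
#' @param qc A [qc_thresholds()] object.
#' @param hmm An [hmm_params()] object.
#' @param region_filters A [region_filter_params()] object.
#' @param freq_diff_threshold Enrichment threshold for
#'   [classify_region()].
#' @param burden_size_min_kb Size strata (kb) for [burden_analysis()].
#' @param p_screen Screening p-value threshold used to flag top-priority
#'   regions in the signal-test report (default 0.2).
#' @param p_significant Significance threshold (default 0.05).
#' @param outdir Report directory, or `NULL` to skip writing.
#' @param seed Seed recorded in the run log and used when `sim` carries
#'   no explicit seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, dataset_path = NULL,
                            refmap_path = NULL, genes_path = NULL,
                            candidates_path = NULL,
                            qc = qc_thresholds(), hmm = hmm_params(),
                            region_filters = region_filter_params(),
                            freq_diff_threshold = 3L,
                            burden_size_min_kb = c(100, 500),
                            p_screen = 0.2, p_significant = 0.05,
                            outdir = NULL, seed = 1L) {
  .assert(!is.null(sim) || !is.null(dataset_path),
          "provide either 'sim' or 'dataset_path'")
  .assert_prob(p_screen, "p_screen")
  .assert_prob(p_significant, "p_significant")
  structure(list(sim = sim, dataset_path = dataset_path,
                 refmap_path = refmap_path, genes_path = genes_path,
                 candidates_path = candidates_path, qc = qc, hmm = hmm,
                 region_filters = region_filters,
                 freq_diff_threshold = freq_diff_threshold,
                 burden_size_min_kb = burden_size_min_kb,
                 p_screen = p_screen, p_significant = p_significant,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping whose keys mirror the [pipeline_config()]
#' arguments; nested mappings `sim`, `qc`, `hmm` and `region_filters`
#' are passed to the respective constructors. Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  if (!is.null(y$sim$events))
    y$sim$events <- lapply(y$sim$events, function(e) {
      if (is.list(e$carriers)) e$carriers <- unlist(e$carriers)
      do.call(cnv_event, e)
    })
  args <- list(
    sim = if (!is.null(y$sim)) do.call(sim_config, y$sim),
    dataset_path = resolve(y$dataset_path),
    refmap_path = resolve(y$refmap_path),
    genes_path = resolve(y$genes_path),
    candidates_path = resolve(y$candidates_path),
    qc = if (is.null(y$qc)) qc_thresholds() else do.call(qc_thresholds, y$qc),
    hmm = if (is.null(y$hmm)) hmm_params() else {
      if (!is.null(y$hmm$emission_means))
        y$hmm$emission_means <- unlist(y$hmm$emission_means)
      do.call(hmm_params, y$hmm)
    },
    region_filters = if (is.null(y$region_filters)) region_filter_params()
      else do.call(region_filter_params, y$region_filters),
    outdir = resolve(y$outdir)
  )
  for (k in c("freq_diff_threshold", "burden_size_min_kb", "p_screen",
              "p_significant", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args[!vapply(args, is.null, TRUE)])
}

#' Run the pooled-CNV discovery pipeline end to end
#'
#' Executes, in order: simulation (or dataset loading), marker QC, per-pool
#' HMM segmentation, the minimum-marker and gain-quality call filters, the
#' gap-ratio merge, the cross-pool region union, classification against the
#' reference CNV map, the burden analysis, per-region pooled-signal tests
#' for informative regions (restricted to regions containing a
#' candidate-list gene when a candidate list and gene annotation are
#' configured), gene mapping, and report emission. The run is deterministic
#' for a fixed seed; a failing stage raises an error naming the stage.
#'
#' @param config A [pipeline_config()] object.
#' @return An object of class `poolcnv_run`: a list with the dataset, QC
#'   report, calls, regions, classified regions, category summary, burden
#'   table, signal-test table, gene map and run metadata.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "'config' must be a pipeline_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ds <- stage("input", {
    if (!is.null(config$sim)) simulate_dataset(config$sim)
    else read_dataset(config$dataset_path)
  })
  qc <- stage("qc", run_qc(ds, config$qc))
  calls <- stage("call", call_all_pools(qc$dataset, config$hmm))
  calls <- stage("regions", {
    k <- filter_min_markers(calls, config$region_filters)
    k <- filter_gain_quality(k, config$region_filters)
    merge_gaps(k, config$region_filters)
  })
  regions <- stage("union", union_regions(calls, ds$pools))
  refmap <- if (is.null(config$refmap_path)) {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               status = character(), source = character(),
               stringsAsFactors = FALSE)
  } else {
    stage("refmap", read_reference_map(config$refmap_path))
  }
  classified <- stage("classify",
                      classify_regions(regions, refmap,
                                       config$freq_diff_threshold))
  summary_tab <- summarize_categories(classified)
  burden <- stage("associate",
                  burden_analysis(calls, ds$pools,
                                  size_min_kb = config$burden_size_min_kb))

  informative <- classified[classified$category != "uninformative", ,
                            drop = FALSE]
  gene_map <- NULL
  test_set <- informative
  if (!is.null(config$genes_path)) {
    genes <- stage("annotate", read_genes(config$genes_path))
    gene_map <- map_genes(informative, genes)
    if (!is.null(config$candidates_path)) {
      cand <- read_candidate_genes(config$candidates_path)
      gene_map <- intersect_candidates(gene_map, cand)
      keep_idx <- unique(gene_map$region_idx[gene_map$candidate])
      test_set <- informative[keep_idx, , drop = FALSE]
    }
  }
  signal_tests <- stage("associate", {
    if (nrow(test_set) == 0L) NULL else {
      rows <- lapply(seq_len(nrow(test_set)), function(i) {
        r <- test_set[i, ]
        st <- region_signal_test(r, qc$dataset, ds$pools)
        data.frame(chrom = r$chrom, start = r$start, end = r$end,
                   category = r$category,
                   case_count = r$case_count, control_count = r$control_count,
                   p_t = st$p_t, p_wilcoxon = st$p_wilcoxon,
                   stringsAsFactors = FALSE)
      })
      st <- do.call(rbind, rows)
      pmin_na <- pmin(ifelse(is.na(st$p_t), Inf, st$p_t),
                      ifelse(is.na(st$p_wilcoxon), Inf, st$p_wilcoxon))
      st$top_priority <- pmin_na < config$p_screen
      st$significant <- pmin_na < config$p_significant
      st
    }
  })

  run <- structure(list(
    dataset = ds, qc_report = qc$report, qc_dataset = qc$dataset,
    calls = calls, regions = regions, classified = classified,
    category_summary = summary_tab, burden = burden,
    signal_tests = signal_tests, gene_map = gene_map,
    seed = config$seed, config = config,
    # hash covers the analysis parameters, not the output location
    config_hash = .config_hash(unclass(config)[setdiff(names(config), "outdir")])
  ), class = "poolcnv_run")
  if (!is.null(config$outdir))
    stage("report", emit_reports(run, config$outdir))
  run
}

#' @export
print.poolcnv_run <- function(x, ...) {
  cat("Pooled-CNV pipeline run\n")
  cat(sprintf("  seed %d, config hash %s\n", x$seed, x$config_hash))
  cat(sprintf("  markers: %d in, %d retained after QC\n",
              x$qc_report$n_input, x$qc_report$n_retained))
  cat(sprintf("  calls after filtering/merging: %d\n", nrow(x$calls)))
  cat(sprintf("  unioned regions: %d (informative: %d)\n",
              nrow(x$regions), x$category_summary$n_informative))
  if (!is.null(x$signal_tests))
    cat(sprintf("  signal tests: %d regions, %d significant\n",
                nrow(x$signal_tests), sum(x$signal_tests$significant)))
  invisible(x)
}

#' @export
summary.poolcnv_run <- function(object, ...) {
  print(object)
  cat("\nCategory summary:\n")
  print(object$category_summary$table, row.names = FALSE)
  cat("\nBurden analysis:\n")
  print(object$burden, row.names = FALSE)
  invisible(object)
}
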