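#' Marker quality-control thresholds
#'
#' @param max_gc_zero_pools Markers whose GC (genotype confidence) score is
#'   exactly zero in more than this many pools are removed (default 3, i.e.
#'   "more than three pools" fail).
#' @param median_lrr_upper,median_lrr_lower Markers whose median Log R
#'   ratio across all pools is strictly above the upper bound or strictly
#'   below the lower bound are removed (defaults +1 and -5; such extreme
#'   intensities are array artifacts, not copy-number signal).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_gc_zero_pools = 3L, median_lrr_upper = 1,
                          median_lrr_lower = -5) {
  .assert_count(max_gc_zero_pools, "max_gc_zero_pools", min = 0L)
  .assert(median_lrr_lower < median_lrr_upper,
          "'median_lrr_lower' must be below 'median_lrr_upper'")
  structure(list(max_gc_zero_pools = as.integer(max_gc_zero_pools),
                 median_lrr_upper = median_lrr_upper,
                 median_lrr_lower = median_lrr_lower),
            class = "qc_thresholds")
}

.subset_markers <- function(ds, keep) {
  ds$markers <- ds$markers[keep, , drop = FALSE]
  rownames(ds$markers) <- NULL
  ds$lrr <- ds$lrr[keep, , drop = FALSE]
  ds$baf <- ds$baf[keep, , drop = FALSE]
  ds$gc <- ds$gc[keep, , drop = FALSE]
  ds
}

#' Marker QC filters
#'
#' Three marker-level filters applied before CNV calling, each returning
#' the filtered dataset:
#'
#' * `filter_missing_and_sex()` removes markers with a missing signal
#'   (LRR, BAF or GC score) in any pool, and markers on the sex
#'   chromosomes (labels X/Y, with or without a "chr" prefix).
#' * `filter_gc_zero()` removes markers whose GC score is exactly zero in
#'   more than `max_gc_zero_pools` pools.
#' * `filter_median_lrr()` removes markers whose median LRR across all
#'   pools (cases and controls jointly; the median of an even count is the
#'   mean of the two central order statistics) is strictly greater than
#'   `median_lrr_upper` or strictly less than `median_lrr_lower`. Markers
#'   sitting exactly on a bound are retained.
#'
#' Each filter is a projection: its output is a subset of its input and
#' applying it twice equals applying it once.
#'
#' @param ds A `pooled_dataset`.
#' @param thresholds A [qc_thresholds()] object.
#' @return The filtered `pooled_dataset`.
#' @export
filter_missing_and_sex <- function(ds) {
  missing_any <- rowSums(is.na(ds$lrr)) > 0 | rowSums(is.na(ds$baf)) > 0 |
    rowSums(is.na(ds$gc)) > 0
  keep <- !missing_any & !.is_sex_chrom(ds$markers$chrom)
  .subset_markers(ds, keep)
}

#' @rdname filter_missing_and_sex
#' @export
filter_gc_zero <- function(ds, thresholds = qc_thresholds()) {
  n_zero <- rowSums(ds$gc == 0, na.rm = TRUE)
  .subset_markers(ds, n_zero <= thresholds$max_gc_zero_pools)
}

#' @rdname filter_missing_and_sex
#' @export
filter_median_lrr <- function(ds, thresholds = qc_thresholds()) {
  .assert(ncol(ds$lrr) >= 1L, "dataset has no pools")
  med <- apply(ds$lrr, 1L, stats::median, na.rm = TRUE)
  keep <- !is.na(med) & med <= thresholds$median_lrr_upper &
    med >= thresholds$median_lrr_lower
  .subset_markers(ds, keep)
}

#' Run the full marker QC pipeline
#'
#' Applies the three marker filters in order — missing-signal/sex-chromosome
#' removal, GC-zero-count filter, median-LRR filter — each to the survivors
#' of the previous one, and reports how many markers each rule removed. A
#' marker failing several rules is counted under the first rule that
#' removed it, so the report's removal counts are additive:
#' `n_retained = n_input - n_removed_missing - n_removed_sex -
#' n_removed_gc - n_removed_median_lrr`.
#'
#' @param ds A `pooled_dataset`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with elements `dataset` (the QC-passed `pooled_dataset`)
#'   and `report` (class `qc_report`).
#' @export
run_qc <- function(ds, thresholds = qc_thresholds()) {
  n_input <- nrow(ds$markers)
  missing_any <- rowSums(is.na(ds$lrr)) > 0 | rowSums(is.na(ds$baf)) > 0 |
    rowSums(is.na(ds$gc)) > 0
  n_removed_missing <- sum(missing_any)
  sex <- .is_sex_chrom(ds$markers$chrom) & !missing_any
  n_removed_sex <- sum(sex)
  ds1 <- filter_missing_and_sex(ds)

  ds2 <- filter_gc_zero(ds1, thresholds)
  n_removed_gc <- nrow(ds1$markers) - nrow(ds2$markers)

  ds3 <- filter_median_lrr(ds2, thresholds)
  n_removed_median <- nrow(ds2$markers) - nrow(ds3$markers)

  report <- structure(list(
    n_input = n_input,
    n_removed_missing = n_removed_missing,
    n_removed_sex = n_removed_sex,
    n_removed_gc = n_removed_gc,
    n_removed_median_lrr = n_removed_median,
    n_retained = nrow(ds3$markers)
  ), class = "qc_report")
  list(dataset = ds3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC report\n")
  cat(sprintf("  input markers:           %d\n", x$n_input))
  cat(sprintf("  removed, missing signal: %d\n", x$n_removed_missing))
  cat(sprintf("  removed, sex chromosome: %d\n", x$n_removed_sex))
  cat(sprintf("  removed, GC score zero:  %d\n", x$n_removed_gc))
  cat(sprintf("  removed, median LRR:     %d\n", x$n_removed_median_lrr))
  cat(sprintf("  retained:                %d\n", x$n_retained))
  invisible(x)
}
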