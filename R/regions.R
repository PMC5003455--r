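#' Region-level filter and merge parameters
#'
#' @param min_markers Calls spanning fewer than this many markers are
#'   dropped (default 20; short calls from HMM segmentation are enriched
#'   for false positives).
#' @param gain_min_mean_lrr Gain calls whose mean LRR is below this value
#'   are dropped (default 0.02; an intensity that close to zero most
#'   likely reflects the diploid state).
#' @param gain_max_sd_lrr Gain calls whose LRR standard deviation exceeds
#'   this value are dropped (default 0.2, a standard sample-quality cut).
#' @param merge_gap_ratio Two neighbouring same-status calls are merged
#'   when `gap / (len_A + len_B)` is strictly below this ratio
#'   (default 0.2). Must be in (0, 1).
#' @return An object of class `region_filter_params`.
#' @export
region_filter_params <- function(min_markers = 20L, gain_min_mean_lrr = 0.02,
                                 gain_max_sd_lrr = 0.2, merge_gap_ratio = 0.2) {
  .assert_count(min_markers, "min_markers")
  .assert(merge_gap_ratio > 0 && merge_gap_ratio < 1,
          "'merge_gap_ratio' must be in (0, 1)")
  structure(list(min_markers = as.integer(min_markers),
                 gain_min_mean_lrr = gain_min_mean_lrr,
                 gain_max_sd_lrr = gain_max_sd_lrr,
                 merge_gap_ratio = merge_gap_ratio),
            class = "region_filter_params")
}

#' Interval length in kilobases
#'
#' Length of a 1-based inclusive interval, `(end - start + 1) / 1000`,
#' unrounded. Report tables round to 2 or 3 decimals depending on dialect
#' (see [format_kb()]).
#'
#' @param start,end 1-based inclusive bounds (vectorised).
#' @return Numeric length(s) in kb.
#' @examples
#' region_length_kb(24193894, 24282139)  # 88.246
#' @export
region_length_kb <- function(start, end) {
  .assert(all(start <= end), "'start' must be <= 'end'")
  (end - start + 1) / 1000
}

#' @rdname region_length_kb
#' @param digits Decimal places for the printed length (2 or 3 in report
#'   tables).
#' @return `format_kb()`: character, fixed decimal places.
#' @export
format_kb <- function(start, end, digits = 2L) {
  sprintf(paste0("%.", digits, "f"), region_length_kb(start, end))
}

#' Overlap of two intervals in bp
#'
#' Inclusive-coordinate overlap: `max(0, min(end) - max(start) + 1)`.
#' Abutting intervals overlap by 0.
#'
#' @param start1,end1,start2,end2 1-based inclusive bounds (vectorised).
#' @return Overlap in bp (0 when disjoint).
#' @export
overlap_bp <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2) + 1)
}

#' Region-level call filters
#'
#' `filter_min_markers()` keeps calls with at least `min_markers` markers.
#' `filter_gain_quality()` applies the gain-specific intensity filters:
#' gain calls with `mean_lrr < gain_min_mean_lrr` or
#' `sd_lrr > gain_max_sd_lrr` are dropped; loss calls pass untouched.
#' Both are pointwise predicates, so they commute and are idempotent.
#'
#' @param calls data.frame of calls (as from [call_all_pools()]).
#' @param params A [region_filter_params()] object.
#' @return The filtered calls data.frame.
#' @export
filter_min_markers <- function(calls, params = region_filter_params()) {
  calls[calls$n_markers >= params$min_markers, , drop = FALSE]
}

#' @rdname filter_min_markers
#' @export
filter_gain_quality <- function(calls, params = region_filter_params()) {
  drop <- calls$status == "gain" &
    (calls$mean_lrr < params$gain_min_mean_lrr |
       calls$sd_lrr > params$gain_max_sd_lrr)
  calls[!drop, , drop = FALSE]
}

#' Merge neighbouring same-status calls across small gaps
#'
#' HMM segmentation tends to split one large CNV into several pieces.
#' Within each (pool, chromosome, status) track, a left-to-right sweep
#' joins adjacent calls A, B whenever the gap between them
#' (`start(B) - end(A) - 1`) divided by the sum of their lengths is
#' strictly below `merge_gap_ratio`. The merged call spans
#' `start(A)..end(B)`; its marker count, mean LRR and LRR SD are the
#' exact pooled moments of the two parts (markers in the gap do not
#' contribute), and it immediately participates in the comparison with the
#' next call, so chains of fragments collapse in one pass. Calls of
#' different status never merge. The operation is idempotent.
#'
#' @param calls data.frame of calls; within a (pool, chromosome, status)
#'   track the intervals must not overlap.
#' @param params A [region_filter_params()] object.
#' @return data.frame of merged calls.
#' @export
merge_gaps <- function(calls, params = region_filter_params()) {
  if (nrow(calls) == 0L) return(calls)
  key <- interaction(calls$pool_id, calls$chrom, calls$status, drop = TRUE)
  pieces <- lapply(split(calls, key), .merge_gaps_track, params = params)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$pool_id, out$chrom, out$start), , drop = FALSE]
}

.merge_gaps_track <- function(track, params) {
  track <- track[order(track$start), , drop = FALSE]
  if (nrow(track) > 1L &&
      any(track$start[-1L] <= track$end[-nrow(track)]))
    stop("overlapping calls within one pool/chromosome/status track",
         call. = FALSE)
  done <- list()
  acc <- track[1L, , drop = FALSE]
  for (i in seq_len(nrow(track))[-1L]) {
    b <- track[i, , drop = FALSE]
    gap <- b$start - acc$end - 1
    len_sum <- (acc$end - acc$start + 1) + (b$end - b$start + 1)
    if (gap / len_sum < params$merge_gap_ratio) {
      mom <- .pool_moments(acc$n_markers, acc$mean_lrr, acc$sd_lrr,
                           b$n_markers, b$mean_lrr, b$sd_lrr)
      acc$end <- b$end
      acc$n_markers <- mom$n
      acc$mean_lrr <- mom$mean
      acc$sd_lrr <- mom$sd
    } else {
      done[[length(done) + 1L]] <- acc
      acc <- b
    }
  }
  done[[length(done) + 1L]] <- acc
  do.call(rbind, done)
}

#' Union CNV calls across pools into comparable regions
#'
#' Clusters the calls of all pools on each chromosome by single linkage
#' under any-overlap (at least 1 bp): overlapping calls belong to one
#' cluster, and each cluster becomes one region spanning the minimum start
#' to the maximum end of its members. The region records, per pool, which
#' status(es) that pool contributed ("absent" when none), and counts how
#' many case and how many control pools carry it. Regions are disjoint by
#' construction and the result does not depend on the input row order.
#'
#' @param calls data.frame of filtered/merged calls.
#' @param manifest data.frame `pool_id`, `group` covering every pool that
#'   appears in `calls`.
#' @return data.frame of regions: `chrom`, `start`, `end`, `length_kb`,
#'   one status column per pool (named by pool id), `case_count`,
#'   `control_count`, `case_status`, `control_status` (comma-joined sorted
#'   status sets, "" when the group is absent).
#' @export
union_regions <- function(calls, manifest) {
  .assert(all(c("pool_id", "group") %in% names(manifest)), "malformed manifest")
  extra <- setdiff(unique(calls$pool_id), manifest$pool_id)
  .assert(length(extra) == 0L,
          sprintf("calls reference pools missing from manifest: %s",
                  paste(extra, collapse = ", ")))
  pool_ids <- manifest$pool_id
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length_kb = numeric(), stringsAsFactors = FALSE)
  for (p in pool_ids) empty[[p]] <- character()
  empty$case_count <- integer(); empty$control_count <- integer()
  empty$case_status <- character(); empty$control_status <- character()
  if (nrow(calls) == 0L) return(empty)

  out <- list()
  for (ch in sort(unique(calls$chrom))) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$start, cc$end), , drop = FALSE]
    # single-linkage sweep: a call starting at or before the running max
    # end (>= 1 bp overlap) joins the open cluster
    cluster <- cumsum(c(1L, as.integer(
      cc$start[-1L] > cummax(cc$end)[-nrow(cc)])))
    for (cl in unique(cluster)) {
      m <- cc[cluster == cl, , drop = FALSE]
      st <- min(m$start); en <- max(m$end)
      by_pool <- vapply(pool_ids, function(p) {
        s <- sort(unique(m$status[m$pool_id == p]))
        if (length(s) == 0L) "absent" else paste(s, collapse = ",")
      }, "")
      grp_status <- function(g) {
        s <- sort(unique(m$status[m$pool_id %in% pool_ids[manifest$group == g]]))
        paste(s, collapse = ",")
      }
      present <- by_pool != "absent"
      row <- data.frame(chrom = ch, start = st, end = en,
                        length_kb = region_length_kb(st, en),
                        stringsAsFactors = FALSE)
      for (p in pool_ids) row[[p]] <- by_pool[[p]]
      row$case_count <- sum(present[manifest$group == "case"])
      row$control_count <- sum(present[manifest$group == "control"])
      row$case_status <- grp_status("case")
      row$control_status <- grp_status("control")
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
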