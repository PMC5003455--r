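#' Is a region present in a reference CNV map?
#'
#' A region counts as "known" when any reference entry on the same
#' chromosome overlaps it by at least 1 bp.
#'
#' @param region A list or one-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param refmap Reference CNV map data.frame (see [read_reference_map()]);
#'   may have zero rows.
#' @return Logical scalar.
#' @export
in_reference_map <- function(region, refmap) {
  if (is.null(refmap) || nrow(refmap) == 0L) return(FALSE)
  same <- refmap$chrom == region$chrom
  any(overlap_bp(region$start, region$end,
                 refmap$start[same], refmap$end[same]) >= 1)
}

.status_set <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",", fixed = TRUE)[[1]]
}

#' Classify a unioned CNV region by its case/control pattern
#'
#' Assigns each region exactly one category using four selection criteria
#' against a population reference CNV map:
#'
#' * `different_status`: present in both groups with disjoint status sets
#'   (for example a gain in controls but a loss in cases);
#' * `important_in_cases`: present only in case pools and *not* in the
#'   reference map (novel, case-specific);
#' * `important_in_controls`: present only in control pools and *also* in
#'   the reference map (known population variation the cases lack);
#' * `enriched_in_cases` / `enriched_in_controls`: present in both groups
#'   with a pool-frequency difference of at least `freq_diff_threshold`
#'   (default 3), the sign giving the direction;
#' * `uninformative` otherwise.
#'
#' The status-conflict rule is evaluated first; the remaining criteria are
#' mutually exclusive by their count conditions.
#'
#' @param region One region (list or one-row data.frame) carrying `chrom`,
#'   `start`, `end`, `case_count`, `control_count`, `case_status`,
#'   `control_status` as produced by [union_regions()].
#' @param refmap Reference CNV map data.frame.
#' @param freq_diff_threshold Minimum absolute case/control pool-count
#'   difference for the enrichment categories.
#' @return A list with `category`, `in_reference` and `freq_diff`
#'   (`case_count - control_count`).
#' @export
classify_region <- function(region, refmap, freq_diff_threshold = 3L) {
  ca <- region$case_count
  co <- region$control_count
  .assert(ca + co >= 1L, "region present in no pool")
  in_ref <- in_reference_map(region, refmap)
  cs <- .status_set(region$case_status)
  os <- .status_set(region$control_status)
  category <-
    if (ca >= 1L && co >= 1L && length(intersect(cs, os)) == 0L) {
      "different_status"
    } else if (co == 0L && !in_ref) {
      "important_in_cases"
    } else if (ca == 0L && in_ref) {
      "important_in_controls"
    } else if (ca >= 1L && co >= 1L && abs(ca - co) >= freq_diff_threshold) {
      if (ca > co) "enriched_in_cases" else "enriched_in_controls"
    } else {
      "uninformative"
    }
  list(category = category, in_reference = in_ref,
       freq_diff = as.integer(ca - co))
}

#' @rdname classify_region
#' @param regions data.frame of regions from [union_regions()].
#' @return `classify_regions()`: the input data.frame with `category`,
#'   `in_reference` and `freq_diff` columns appended.
#' @export
classify_regions <- function(regions, refmap, freq_diff_threshold = 3L) {
  if (nrow(regions) == 0L) {
    regions$category <- character()
    regions$in_reference <- logical()
    regions$freq_diff <- integer()
    return(regions)
  }
  res <- lapply(seq_len(nrow(regions)), function(i)
    classify_region(regions[i, , drop = FALSE], refmap, freq_diff_threshold))
  regions$category <- vapply(res, `[[`, "", "category")
  regions$in_reference <- vapply(res, `[[`, TRUE, "in_reference")
  regions$freq_diff <- vapply(res, `[[`, 0L, "freq_diff")
  regions
}

.cnv_categories <- c("important_in_cases", "important_in_controls",
                     "enriched_in_cases", "enriched_in_controls",
                     "different_status")

#' Summarise classified regions by category
#'
#' Counts regions per informative category with a gain/loss breakdown
#' (regions whose pools carry both statuses count as "mixed") and the mean
#' region length in kb, plus a grand total of informative regions.
#'
#' @param classified data.frame from [classify_regions()].
#' @return A list with `table` (one row per category: `category`, `n`,
#'   `n_gain`, `n_loss`, `n_mixed`, `mean_length_kb`) and
#'   `n_informative`, the total across informative categories.
#' @export
summarize_categories <- function(classified) {
  all_status <- if (nrow(classified)) {
    mapply(function(a, b) {
      paste(sort(unique(c(.status_set(a), .status_set(b)))), collapse = ",")
    }, classified$case_status, classified$control_status, USE.NAMES = FALSE)
  } else {
    character()
  }
  rows <- lapply(.cnv_categories, function(cat) {
    sel <- classified$category == cat
    data.frame(
      category = cat, n = sum(sel),
      n_gain = sum(sel & all_status == "gain"),
      n_loss = sum(sel & all_status == "loss"),
      n_mixed = sum(sel & !all_status %in% c("gain", "loss")),
      mean_length_kb = if (any(sel)) mean(classified$length_kb[sel]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  list(table = tab, n_informative = sum(tab$n))
}
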