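#' Exact two-sided rank-sum test by full enumeration
#'
#' Mann-Whitney/Wilcoxon rank-sum test whose p-value is computed by
#' enumerating every assignment of the pooled observations to the two
#' groups — the appropriate choice for small pooled designs such as 8
#' case vs 8 control pools, where the C(16, 8) = 12870 assignments are
#' enumerated directly. Ties take mid-ranks and the enumeration conditions
#' on the observed (tied) rank vector, so the p-value remains exact under
#' ties. The two-sided p is the permutation fraction with
#' `|W - E(W)| >= |w_obs - E(W)|`, where W is the first group's rank sum;
#' the smallest attainable two-sided p for 8 vs 8 untied data is
#' 2/12870.
#'
#' @param x,y Numeric vectors (group 1 and group 2).
#' @return A list with `statistic` (rank sum of `x`) and `p.value`.
#' @export
wilcoxon_exact <- function(x, y) {
  .assert(length(x) >= 1L && length(y) >= 1L, "both groups must be non-empty")
  .assert(all(is.finite(c(x, y))), "inputs must be finite")
  n <- length(x); m <- length(y); N <- n + m
  .assert(choose(N, n) <= 2e6, "too many assignments for exact enumeration")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  idx <- .combn_cached(N, n)
  w_all <- colSums(matrix(r[idx], nrow = n))
  e_w <- n * (N + 1) / 2
  p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
  list(statistic = w_obs, p.value = p)
}

#' Welch t-test p-value with a degenerate-variance convention
#'
#' Two-sided Welch (unequal-variance) t-test; returns `NA` when both
#' groups have zero variance (the statistic is undefined).
#'
#' @param x,y Numeric vectors.
#' @return p-value (or `NA`).
#' @export
welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) return(NA_real_)
  tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
           error = function(e) NA_real_)
}

#' Case-control CNV burden analysis
#'
#' Compares the per-pool CNV load between case and control pools,
#' stratified by CNV status (both / gain / loss) and minimum length
#' (100 kb and 500 kb by default). Within each stratum the analysis
#' reports, per group, the number of unique CNV regions (the count of
#' within-group unioned regions) and the mean number of calls per pool,
#' and an exact two-sided rank-sum p-value comparing the per-pool call
#' counts between groups. The p-value is `NA` when no pool has any call
#' in the stratum.
#'
#' @param calls data.frame of post-filter, post-merge calls.
#' @param manifest Pool manifest data.frame (`pool_id`, `group`).
#' @param size_min_kb Numeric vector of minimum lengths (kb) defining the
#'   size strata.
#' @param types Character vector of status strata; "both" means any
#'   status.
#' @return data.frame with one row per stratum: `size_min_kb`, `type`,
#'   `n_unique_case`, `n_unique_control`, `mean_per_case_pool`,
#'   `mean_per_control_pool`, `p_wilcoxon`.
#' @export
burden_analysis <- function(calls, manifest, size_min_kb = c(100, 500),
                            types = c("both", "gain", "loss")) {
  n_case <- sum(manifest$group == "case")
  n_ctrl <- sum(manifest$group == "control")
  if (n_case != 8L || n_ctrl != 8L)
    warning(sprintf("expected 8 case and 8 control pools, got %d/%d",
                    n_case, n_ctrl), call. = FALSE)
  len_kb <- if (nrow(calls)) region_length_kb(calls$start, calls$end) else numeric()
  out <- list()
  for (smin in size_min_kb) for (ty in types) {
    sel <- len_kb >= smin & (ty == "both" | calls$status == ty)
    sub <- calls[sel, , drop = FALSE]
    per_pool <- vapply(manifest$pool_id,
                       function(p) sum(sub$pool_id == p), 0L)
    cases <- per_pool[manifest$group == "case"]
    ctrls <- per_pool[manifest$group == "control"]
    uniq <- function(g) {
      gc <- sub[sub$pool_id %in% manifest$pool_id[manifest$group == g], ,
                drop = FALSE]
      nrow(union_regions(gc, manifest[manifest$group == g, , drop = FALSE]))
    }
    p <- if (all(per_pool == 0L)) NA_real_ else
      wilcoxon_exact(cases, ctrls)$p.value
    out[[length(out) + 1L]] <- data.frame(
      size_min_kb = smin, type = ty,
      n_unique_case = uniq("case"), n_unique_control = uniq("control"),
      mean_per_case_pool = mean(cases), mean_per_control_pool = mean(ctrls),
      p_wilcoxon = p, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled-signal association test for one CNV region
#'
#' Summarises each pool by the median LRR of the QC-retained markers
#' inside the region, then compares the 8 case medians with the 8 control
#' medians by a two-sided Welch t-test and by the exact two-sided rank-sum
#' test ([wilcoxon_exact()]). The t-test is reported `NA` when every
#' median is identical (zero variance in both groups).
#'
#' @param region A list or one-row data.frame with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param ds The QC-passed `pooled_dataset`.
#' @param manifest Pool manifest; defaults to `ds$pools`.
#' @return A list with `case_medians`, `control_medians`, `n_markers`,
#'   `p_t` and `p_wilcoxon`.
#' @export
region_signal_test <- function(region, ds, manifest = ds$pools) {
  inside <- ds$markers$chrom == region$chrom &
    ds$markers$position >= region$start & ds$markers$position <= region$end
  .assert(any(inside), "no QC-retained markers inside the region")
  med <- apply(ds$lrr[inside, manifest$pool_id, drop = FALSE], 2L,
               stats::median, na.rm = TRUE)
  cases <- med[manifest$group == "case"]
  ctrls <- med[manifest$group == "control"]
  list(case_medians = cases, control_medians = ctrls,
       n_markers = sum(inside),
       p_t = welch_p(cases, ctrls),
       p_wilcoxon = wilcoxon_exact(cases, ctrls)$p.value)
}

#' Power of the two-sided two-sample t-test
#'
#' Analytic power via the noncentral t distribution, for equal group
#' sizes: with noncentrality `ncp = delta / (sd * sqrt(2 / n))` and
#' `df = 2n - 2`, power is `P(T < -t_crit) + P(T > t_crit)` for
#' `T ~ t(df, ncp)`. At `delta = 0` the power equals `alpha`.
#'
#' @param delta True difference in group means (same units as `sd`).
#' @param sd Common within-group standard deviation (> 0).
#' @param n_per_group Number of observations per group (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @return The power (a probability).
#' @export
power_two_sample_t <- function(delta, sd, n_per_group, alpha = 0.05) {
  .assert(sd > 0, "'sd' must be positive")
  .assert_count(n_per_group, "n_per_group", min = 2L)
  .assert(alpha > 0 && alpha < 1, "'alpha' must be in (0, 1)")
  df <- 2 * n_per_group - 2
  ncp <- delta / (sd * sqrt(2 / n_per_group))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp) + stats::pt(crit, df, ncp, lower.tail = FALSE)
}
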