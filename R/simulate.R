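#' Simulation settings for a pooled SNP-array experiment
#'
#' Describes the pooling design and signal model used by
#' [simulate_dataset()]. The defaults reproduce a design of eight case and
#' eight control pools of 25 subjects each, assayed on a SNP array whose
#' pool-level Log R ratio (LRR) at a marker equals `log2(cbar/2)` plus
#' Gaussian noise, where `cbar` is the mean copy number of the pool's
#' subjects at that position (2 for non-carriers). Under this model a single
#' duplication carrier (copy number 3) among 25 subjects shifts the pool LRR
#' by `log2(2.04/2) = 0.0286`, and a single hemizygous-deletion carrier by
#' `log2(1.96/2) = -0.0291`; the default pool-level noise SD of 0.15 places
#' such singleton events near the detection edge, which is the regime the
#' pooling design has to cope with.
#'
#' @param n_case_pools,n_control_pools Number of case / control pools.
#' @param pool_size Subjects per pool.
#' @param n_markers Total number of markers to simulate.
#' @param marker_spacing Mean inter-marker distance in bp (spacings are
#'   exponential with this mean, so positions form a Poisson-like process).
#' @param chroms Character vector of autosome labels over which markers are
#'   spread evenly.
#' @param n_sex_markers Number of extra markers placed on chromosomes X/Y
#'   (only useful to exercise the QC removal rule; 0 by default).
#' @param lrr_noise_sd Pool-level Gaussian noise SD on the LRR scale.
#' @param baf_jitter_sd SD of the Gaussian jitter added to the pooled
#'   B-allele frequency (truncated back to \[0, 1\]).
#' @param missing_rate Per marker-and-pool probability that the LRR/BAF
#'   signal pair is missing (`NA`).
#' @param gc_zero_rate Per marker-and-pool probability of a failed probe,
#'   i.e. a GC (genotype confidence) score of exactly 0.
#' @param artifact_rate Per-marker probability of an extreme-intensity
#'   artifact: all pools' LRR at that marker is replaced by a value outside
#'   the QC median bounds (above +1 or below -5).
#' @param events List of true CNV events created by [cnv_event()].
#' @param seed Integer seed; fixed seed gives byte-identical output files.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()], [cnv_event()]
#' @export
sim_config <- function(n_case_pools = 8L, n_control_pools = 8L,
                       pool_size = 25L, n_markers = 1000L,
                       marker_spacing = 2500, chroms = "1",
                       n_sex_markers = 0L,
                       lrr_noise_sd = 0.15, baf_jitter_sd = 0.01,
                       missing_rate = 0, gc_zero_rate = 0,
                       artifact_rate = 0, events = list(), seed = 1L) {
  .assert_count(n_case_pools, "n_case_pools")
  .assert_count(n_control_pools, "n_control_pools")
  .assert_count(pool_size, "pool_size")
  .assert_count(n_markers, "n_markers")
  .assert_count(n_sex_markers, "n_sex_markers", min = 0L)
  .assert(is.numeric(marker_spacing) && marker_spacing > 0,
          "'marker_spacing' must be positive")
  .assert(is.numeric(lrr_noise_sd) && lrr_noise_sd >= 0,
          "'lrr_noise_sd' must be >= 0")
  .assert_prob(missing_rate, "missing_rate")
  .assert_prob(gc_zero_rate, "gc_zero_rate")
  .assert_prob(artifact_rate, "artifact_rate")
  .assert(all(!.is_sex_chrom(chroms)), "'chroms' must be autosomes; use n_sex_markers for X/Y")
  .assert(is.list(events) && all(vapply(events, inherits, TRUE, "cnv_event")),
          "'events' must be a list of cnv_event objects")
  structure(list(
    n_case_pools = as.integer(n_case_pools),
    n_control_pools = as.integer(n_control_pools),
    pool_size = as.integer(pool_size), n_markers = as.integer(n_markers),
    marker_spacing = marker_spacing, chroms = as.character(chroms),
    n_sex_markers = as.integer(n_sex_markers),
    lrr_noise_sd = lrr_noise_sd, baf_jitter_sd = baf_jitter_sd,
    missing_rate = missing_rate, gc_zero_rate = gc_zero_rate,
    artifact_rate = artifact_rate, events = events, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Define a true CNV event for the simulator
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive bounds in bp.
#' @param copy_number Integer copy number of carriers: 0, 1 (losses) or
#'   3, 4 (gains); 2 is the diploid state and not an event.
#' @param carriers Either a named integer vector mapping pool ids to the
#'   number of carrier subjects in that pool, or a single unnamed count which
#'   is applied to every pool selected by `group`.
#' @param group Which pools an unnamed `carriers` count applies to
#'   (`"case"`, `"control"` or `"both"`). Ignored when `carriers` is named.
#' @return An object of class `cnv_event`.
#' @export
cnv_event <- function(chrom, start, end, copy_number, carriers,
                      group = c("case", "control", "both")) {
  group <- match.arg(group)
  .assert(start <= end, "'start' must be <= 'end'")
  .assert(copy_number %in% c(0L, 1L, 3L, 4L),
          "'copy_number' must be one of 0, 1, 3, 4")
  .assert(is.numeric(carriers) && all(carriers >= 0),
          "'carriers' must be non-negative counts")
  if (is.null(names(carriers)))
    .assert(length(carriers) == 1L,
            "unnamed 'carriers' must be a single count (applied per 'group')")
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), copy_number = as.integer(copy_number),
                 carriers = carriers, group = group),
            class = "cnv_event")
}

# Resolve an event's carriers to a named vector over all pool ids.
.event_carriers <- function(ev, pools) {
  out <- stats::setNames(integer(nrow(pools)), pools$pool_id)
  if (is.null(names(ev$carriers))) {
    sel <- if (ev$group == "both") rep(TRUE, nrow(pools)) else pools$group == ev$group
    out[sel] <- as.integer(ev$carriers)
  } else {
    .assert(all(names(ev$carriers) %in% pools$pool_id),
            "event names a pool id absent from the manifest")
    out[names(ev$carriers)] <- as.integer(ev$carriers)
  }
  out
}

#' Simulate a pooled SNP-array dataset with known truth
#'
#' Generates marker positions, per-pool Log R ratio (LRR), B-allele
#' frequency (BAF) and GC-score signals for a case/control pooling design,
#' embedding the configured CNV events.
#'
#' The signal model: at a marker inside an event region, a pool's mean copy
#' number is `cbar = 2 + k * (cn - 2) / pool_size` where `k` carriers of
#' copy number `cn` are in the pool; its expected LRR is `log2(cbar / 2)`,
#' plus Gaussian noise with SD `lrr_noise_sd`. The BAF is a binomial allele
#' proportion over the pool's chromosome count (adjusted for carrier
#' dosage) with a population B-allele frequency drawn uniformly on
#' (0.05, 0.95) per marker, plus small truncated Gaussian jitter. Missing
#' signals, failed probes (GC score 0) and extreme-intensity artifact
#' markers are injected at the configured rates.
#'
#' @param config A [sim_config()] object.
#' @return A `pooled_dataset`: a list with elements `markers` (data.frame
#'   `marker_id`, `chrom`, `position`, sorted by chromosome then position),
#'   `lrr`, `baf`, `gc` (marker-by-pool matrices, pool ids as column names),
#'   `pools` (data.frame `pool_id`, `group`) and `truth` (data.frame of the
#'   embedded events with serialised per-pool carrier counts).
#' @examples
#' ds <- simulate_dataset(sim_config(n_markers = 200, seed = 42))
#' dim(ds$lrr)
#' @export
simulate_dataset <- function(config) {
  .assert(inherits(config, "sim_config"), "'config' must be a sim_config")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  pools <- data.frame(
    pool_id = c(sprintf("case%02d", seq_len(config$n_case_pools)),
                sprintf("ctrl%02d", seq_len(config$n_control_pools))),
    group = c(rep("case", config$n_case_pools),
              rep("control", config$n_control_pools)),
    stringsAsFactors = FALSE
  )
  n_pools <- nrow(pools)

  carriers <- lapply(config$events, .event_carriers, pools = pools)
  .check_event_conflicts(config$events, carriers)

  # Marker coordinates: exponential spacings per chromosome.
  per_chrom <- .split_count(config$n_markers, length(config$chroms))
  chrom_lab <- rep(config$chroms, per_chrom)
  if (config$n_sex_markers > 0L) {
    chrom_lab <- c(chrom_lab, rep("X", config$n_sex_markers))
    per_chrom <- c(per_chrom, config$n_sex_markers)
  }
  position <- unlist(lapply(per_chrom, function(n) {
    cumsum(1 + round(stats::rexp(n, rate = 1 / config$marker_spacing)))
  }), use.names = FALSE)
  n <- length(chrom_lab)
  markers <- data.frame(
    marker_id = sprintf("m%06d", seq_len(n)),
    chrom = chrom_lab, position = as.numeric(position),
    stringsAsFactors = FALSE
  )
  ord <- order(markers$chrom, markers$position)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL

  # Mean pool copy number per marker/pool.
  cbar <- matrix(2, n, n_pools, dimnames = list(NULL, pools$pool_id))
  for (i in seq_along(config$events)) {
    ev <- config$events[[i]]
    hit <- markers$chrom == ev$chrom &
      markers$position >= ev$start & markers$position <= ev$end
    if (any(hit))
      cbar[hit, ] <- cbar[hit, ] +
        rep(carriers[[i]] * (ev$copy_number - 2) / config$pool_size,
            each = sum(hit))
  }

  lrr <- log2(cbar / 2) +
    matrix(stats::rnorm(n * n_pools, sd = config$lrr_noise_sd), n, n_pools)

  # Pooled BAF: binomial allele proportion over the pool's chromosomes.
  pop_freq <- stats::runif(n, 0.05, 0.95)
  n_chrom <- 2 * config$pool_size + (cbar - 2) * config$pool_size  # = pool_size * cbar
  bcount <- matrix(stats::rbinom(n * n_pools, size = as.integer(round(n_chrom)),
                                 prob = rep(pop_freq, times = n_pools)), n, n_pools)
  baf <- bcount / round(n_chrom) +
    matrix(stats::rnorm(n * n_pools, sd = config$baf_jitter_sd), n, n_pools)
  baf <- pmin(pmax(baf, 0), 1)

  gc <- matrix(stats::runif(n * n_pools, 0.15, 1), n, n_pools)
  dimnames(lrr) <- dimnames(baf) <- dimnames(gc) <- list(NULL, pools$pool_id)

  if (config$gc_zero_rate > 0) {
    z <- matrix(stats::runif(n * n_pools) < config$gc_zero_rate, n, n_pools)
    gc[z] <- 0
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * n_pools) < config$missing_rate, n, n_pools)
    lrr[miss] <- NA_real_
    baf[miss] <- NA_real_
  }
  if (config$artifact_rate > 0) {
    art <- stats::runif(n) < config$artifact_rate
    if (any(art)) {
      k <- sum(art)
      sign_up <- stats::runif(k) < 0.5
      level <- ifelse(sign_up, stats::runif(k, 1.5, 3), -stats::runif(k, 5.5, 8))
      lrr[art, ] <- rep(level, times = n_pools) +
        matrix(stats::rnorm(k * n_pools, sd = 0.05), k, n_pools)
    }
  }

  truth <- .events_to_truth(config$events, carriers)
  structure(list(markers = markers, lrr = lrr, baf = baf, gc = gc,
                 pools = pools, truth = truth,
                 pool_size = config$pool_size, seed = config$seed),
            class = "pooled_dataset")
}

# Overlapping events that put carriers of conflicting copy numbers in the
# same pool would make the mean-copy-number model ambiguous.
.check_event_conflicts <- function(events, carriers) {
  if (length(events) < 2L) return(invisible())
  for (i in seq_along(events)) for (j in seq_len(i - 1L)) {
    a <- events[[i]]; b <- events[[j]]
    if (a$chrom == b$chrom && a$start <= b$end && b$start <= a$end &&
        a$copy_number != b$copy_number &&
        any(carriers[[i]] > 0 & carriers[[j]] > 0))
      stop("overlapping events with conflicting copy numbers in the same pool",
           call. = FALSE)
  }
  invisible()
}

.split_count <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

.events_to_truth <- function(events, carriers) {
  if (length(events) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      copy_number = integer(), status = character(),
                      carriers = character(), stringsAsFactors = FALSE))
  data.frame(
    chrom = vapply(events, `[[`, "", "chrom"),
    start = vapply(events, `[[`, 0, "start"),
    end = vapply(events, `[[`, 0, "end"),
    copy_number = vapply(events, `[[`, 0L, "copy_number"),
    status = ifelse(vapply(events, `[[`, 0L, "copy_number") > 2, "gain", "loss"),
    carriers = vapply(carriers, function(cc) {
      cc <- cc[cc > 0]
      paste(sprintf("%s:%d", names(cc), cc), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' @export
print.pooled_dataset <- function(x, ...) {
  cat(sprintf("Pooled SNP-array dataset: %d markers x %d pools (%d case, %d control)\n",
              nrow(x$markers), nrow(x$pools),
              sum(x$pools$group == "case"), sum(x$pools$group == "control")))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$markers$chrom), collapse = ", ")))
  cat(sprintf("  truth events: %d\n", nrow(x$truth)))
  invisible(x)
}
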