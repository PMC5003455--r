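#' Parameters of the three-state pooled-LRR segmentation HMM
#'
#' The caller is a deliberately simple three-state (loss / normal / gain)
#' hidden Markov model over a pool's Log R ratio track, with Gaussian
#' emissions and a time-homogeneous transition matrix. It is a documented
#' simplified stand-in for full six-state, distance-dependent CNV callers
#' such as PennCNV: at pool level the only decision that matters downstream
#' is gain / normal / loss, and pooled BAF is nearly uninformative for
#' 1-in-25 carriers, so emissions use LRR only.
#'
#' @param emission_means Named numeric of per-state emission means on the
#'   LRR scale. The defaults (`loss = -0.03`, `normal = 0`, `gain = 0.03`)
#'   are pooled-scale values: a single copy-number-3 carrier among 25
#'   subjects shifts the pool LRR by about +0.029 and a single
#'   copy-number-1 carrier by about -0.029.
#' @param emission_sd Emission standard deviation, one value for all
#'   states; if `NULL` (default) it is estimated per pool from the data by
#'   a robust scale estimate (see [estimate_noise()]).
#' @param switch_prob Per-marker probability of switching into each of the
#'   other two states; every state keeps probability `1 - 2 * switch_prob`
#'   of staying. Must be in (0, 0.5).
#' @param min_state_prob Floor applied to emission densities for numerical
#'   stability in log space.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(emission_means = c(loss = -0.03, normal = 0, gain = 0.03),
                       emission_sd = NULL, switch_prob = 1e-4,
                       min_state_prob = 1e-300) {
  .assert(length(emission_means) == 3L &&
            all(c("loss", "normal", "gain") %in% names(emission_means)),
          "'emission_means' must name loss, normal and gain")
  em <- emission_means[c("loss", "normal", "gain")]
  .assert(em[["loss"]] < em[["normal"]] && em[["normal"]] < em[["gain"]],
          "emission means must be ordered loss < normal < gain")
  .assert(switch_prob > 0 && switch_prob < 0.5,
          "'switch_prob' must be in (0, 0.5)")
  .assert(is.null(emission_sd) || emission_sd > 0,
          "'emission_sd' must be positive (or NULL to estimate)")
  structure(list(emission_means = em, emission_sd = emission_sd,
                 switch_prob = switch_prob, min_state_prob = min_state_prob),
            class = "hmm_params")
}

#' Robust per-pool noise estimate
#'
#' Estimates the emission SD of a pool's LRR track as the median absolute
#' deviation scaled for normal consistency (the 1.4826 factor), which is
#' insensitive to the small fraction of markers inside true CNV segments
#' or artifact regions.
#'
#' @param ds A `pooled_dataset` (QC-passed).
#' @param pool Pool id (a column of `ds$lrr`).
#' @return The scale estimate (a single number).
#' @export
estimate_noise <- function(ds, pool) {
  .assert(pool %in% colnames(ds$lrr), sprintf("unknown pool '%s'", pool))
  x <- ds$lrr[, pool]
  x <- x[is.finite(x)]
  .assert(length(x) >= 10L, "need at least 10 markers to estimate noise")
  stats::mad(x)
}

# Viterbi decode of one numeric LRR vector; returns integer states
# 1 = loss, 2 = normal, 3 = gain.
.viterbi_states <- function(x, means, sd, switch_prob, floor_p = 1e-300) {
  n <- length(x)
  log_trans <- matrix(log(switch_prob), 3L, 3L)
  diag(log_trans) <- log(1 - 2 * switch_prob)
  # start in any state with the transition prior out of "normal"
  log_init <- log_trans[2L, ]
  emis <- vapply(means, function(m) {
    stats::dnorm(x, mean = m, sd = sd)
  }, numeric(n))
  log_emis <- log(pmax(matrix(emis, n, 3L), floor_p))

  delta <- matrix(-Inf, n, 3L)
  back <- matrix(1L, n, 3L)
  delta[1L, ] <- log_init + log_emis[1L, ]
  if (n > 1L) for (t in 2:n) {
    for (s in 1:3) {
      cand <- delta[t - 1L, ] + log_trans[, s]
      back[t, s] <- which.max(cand)
      delta[t, s] <- cand[back[t, s]] + log_emis[t, s]
    }
  }
  states <- integer(n)
  states[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) states[t] <- back[t + 1L, states[t + 1L]]
  states
}

#' Segment one pool's LRR track into gain/loss calls
#'
#' Runs the three-state Viterbi decode independently on each chromosome of
#' a pool's LRR track and emits each maximal run of a non-normal state as
#' one CNV call. Call coordinates are the positions of the first and last
#' marker in the run (1-based inclusive); the call carries the marker
#' count and the mean and SD of the pool's LRR over those markers (SD of a
#' single-marker call is 0).
#'
#' @param ds A `pooled_dataset` whose markers passed QC (no missing LRR).
#' @param pool Pool id.
#' @param params An [hmm_params()] object; a `NULL` `emission_sd` is filled
#'   in per pool via [estimate_noise()].
#' @return data.frame of calls: `pool_id`, `chrom`, `start`, `end`,
#'   `status` ("gain"/"loss"), `n_markers`, `mean_lrr`, `sd_lrr`.
#' @export
viterbi_segment <- function(ds, pool, params = hmm_params()) {
  .assert(inherits(params, "hmm_params"), "'params' must be hmm_params")
  .assert(pool %in% colnames(ds$lrr), sprintf("unknown pool '%s'", pool))
  x_all <- ds$lrr[, pool]
  .assert(all(is.finite(x_all)),
          "non-finite LRR values present; run QC before calling")
  sd_use <- params$emission_sd %||% estimate_noise(ds, pool)
  if (sd_use <= 0) sd_use <- 1e-6  # constant track: degenerate but decodable
  out <- list()
  for (ch in unique(ds$markers$chrom)) {
    idx <- which(ds$markers$chrom == ch)
    states <- .viterbi_states(x_all[idx], params$emission_means, sd_use,
                              params$switch_prob, params$min_state_prob)
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values != 2L)) {
      seg <- idx[starts[k]:ends[k]]
      lrr_seg <- x_all[seg]
      out[[length(out) + 1L]] <- data.frame(
        pool_id = pool, chrom = ch,
        start = ds$markers$position[seg[1L]],
        end = ds$markers$position[seg[length(seg)]],
        status = if (r$values[k] == 3L) "gain" else "loss",
        n_markers = length(seg),
        mean_lrr = mean(lrr_seg),
        sd_lrr = if (length(seg) > 1L) stats::sd(lrr_seg) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(.empty_calls())
  do.call(rbind, out)
}

.empty_calls <- function() {
  data.frame(pool_id = character(), chrom = character(), start = numeric(),
             end = numeric(), status = character(), n_markers = integer(),
             mean_lrr = numeric(), sd_lrr = numeric(), stringsAsFactors = FALSE)
}

#' Call CNV segments in every pool
#'
#' Applies [viterbi_segment()] to each pool of the dataset. Pools are
#' decoded independently, so the result does not depend on pool order.
#'
#' @param ds A QC-passed `pooled_dataset`.
#' @param params An [hmm_params()] object.
#' @return One data.frame of calls for all pools (possibly zero rows),
#'   in the column layout of [viterbi_segment()].
#' @export
call_all_pools <- function(ds, params = hmm_params()) {
  .assert(nrow(ds$pools) == ncol(ds$lrr) &&
            all(ds$pools$pool_id %in% colnames(ds$lrr)),
          "pool manifest does not match signal matrix")
  calls <- lapply(ds$pools$pool_id, function(p) viterbi_segment(ds, p, params))
  do.call(rbind, c(calls, list(.empty_calls())))
}
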