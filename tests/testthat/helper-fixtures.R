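# Fixture builders shared across test files. All datasets are built in
# code; nothing is read from disk except files the tests write themselves.

# Assemble a pooled_dataset from an explicit LRR matrix (markers x pools).
# The first n_case columns are case pools. Positions default to 1 kb
# spacing within each chromosome.
fixture_dataset <- function(lrr, chrom = rep("1", nrow(lrr)), position = NULL,
                            baf = NULL, gc = NULL, n_case = ncol(lrr) / 2) {
  n <- nrow(lrr)
  np <- ncol(lrr)
  pool_id <- c(sprintf("case%02d", seq_len(n_case)),
               sprintf("ctrl%02d", seq_len(np - n_case)))
  if (is.null(position)) {
    position <- stats::ave(seq_len(n), chrom, FUN = seq_along) * 1000
  }
  dimnames(lrr) <- list(NULL, pool_id)
  if (is.null(baf)) baf <- matrix(0.5, n, np)
  if (is.null(gc)) gc <- matrix(0.8, n, np)
  dimnames(baf) <- dimnames(gc) <- list(NULL, pool_id)
  markers <- data.frame(marker_id = sprintf("m%06d", seq_len(n)),
                        chrom = chrom, position = as.numeric(position),
                        stringsAsFactors = FALSE)
  ord <- order(markers$chrom, markers$position)
  structure(list(
    markers = markers[ord, ], lrr = lrr[ord, , drop = FALSE],
    baf = baf[ord, , drop = FALSE], gc = gc[ord, , drop = FALSE],
    pools = data.frame(pool_id = pool_id,
                       group = rep(c("case", "control"),
                                   c(n_case, np - n_case)),
                       stringsAsFactors = FALSE),
    truth = data.frame(chrom = character(), start = numeric(),
                       end = numeric(), copy_number = integer(),
                       status = character(), carriers = character(),
                       stringsAsFactors = FALSE),
    pool_size = 25L, seed = NA_integer_
  ), class = "pooled_dataset")
}

# One CNV call row, for region-op fixtures.
fixture_call <- function(pool_id = "case01", chrom = "1", start, end,
                         status = "gain", n_markers = 25L,
                         mean_lrr = 0.05, sd_lrr = 0.05) {
  data.frame(pool_id = pool_id, chrom = chrom, start = start, end = end,
             status = status, n_markers = as.integer(n_markers),
             mean_lrr = mean_lrr, sd_lrr = sd_lrr, stringsAsFactors = FALSE)
}

fixture_manifest <- function(n_case = 8L, n_ctrl = 8L) {
  data.frame(pool_id = c(sprintf("case%02d", seq_len(n_case)),
                         sprintf("ctrl%02d", seq_len(n_ctrl))),
             group = rep(c("case", "control"), c(n_case, n_ctrl)),
             stringsAsFactors = FALSE)
}

# A one-row region in the layout union_regions() produces, for
# classification tests (pool presence columns are not needed there).
fixture_region <- function(chrom = "1", start = 1e5, end = 2e5,
                           case_count = 0L, control_count = 0L,
                           case_status = "", control_status = "") {
  data.frame(chrom = chrom, start = start, end = end,
             length_kb = (end - start + 1) / 1000,
             case_count = as.integer(case_count),
             control_count = as.integer(control_count),
             case_status = case_status, control_status = control_status,
             stringsAsFactors = FALSE)
}

# ---- Independent oracles -------------------------------------------------

# Exhaustive Viterbi oracle: score every state path directly from the
# model definition (independent of the dynamic-programming code path).
oracle_best_path <- function(x, means, sd, switch_prob) {
  n <- length(x)
  states <- as.matrix(expand.grid(rep(list(1:3), n)))
  log_trans <- matrix(log(switch_prob), 3, 3)
  diag(log_trans) <- log(1 - 2 * switch_prob)
  log_init <- log_trans[2, ]
  score <- apply(states, 1, function(s) {
    lp <- log_init[s[1]] + sum(dnorm(x, mean = means[s], sd = sd, log = TRUE))
    if (n > 1) lp <- lp + sum(log_trans[cbind(s[-n], s[-1])])
    lp
  })
  states[which.max(score), ]
}

# Exact rank-sum oracle: enumerate group-1 memberships as bit patterns,
# a code path disjoint from the combn-based implementation.
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
  masks <- masks[rowSums(masks) == n, , drop = FALSE]
  w_all <- as.vector(masks %*% r)
  e_w <- n * (N + 1) / 2
  w_obs <- sum(r[seq_len(n)])
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# Brute-force single-linkage clustering by transitive closure on the
# pairwise overlap graph.
oracle_union_clusters <- function(calls) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- calls$chrom[i] == calls$chrom[j] &&
      overlap_bp(calls$start[i], calls$end[i],
                 calls$start[j], calls$end[j]) >= 1
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    nxt <- nxt + 1L
    comp[which(reach[i, ])] <- nxt
  }
  comp
}
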