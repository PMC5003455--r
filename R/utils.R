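# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.assert_count <- function(x, name, min = 1L) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min,
          sprintf("'%s' must be a single integer >= %d", name, min))
}

.assert_prob <- function(x, name) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1,
          sprintf("'%s' must be a probability in [0, 1]", name))
}

#' Strip any "chr" prefix and upper-case a chromosome label
#' @noRd
.norm_chrom <- function(chrom) {
  toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
}

.is_sex_chrom <- function(chrom) .norm_chrom(chrom) %in% c("X", "Y")

# Combine per-part (n, mean, sd) into pooled moments; sd uses the n-1
# denominator, matching stats::sd, and a 1-observation part contributes sd 0.
.pool_moments <- function(n1, m1, s1, n2, m2, s2) {
  n <- n1 + n2
  m <- (n1 * m1 + n2 * m2) / n
  ss <- (n1 - 1) * s1^2 + n1 * m1^2 + (n2 - 1) * s2^2 + n2 * m2^2
  v <- (ss - n * m^2) / (n - 1)
  list(n = n, mean = m, sd = sqrt(max(v, 0)))
}

# Cache of group-assignment matrices used by the exact rank-sum test.
.poolcnv_cache <- new.env(parent = emptyenv())

.combn_cached <- function(n, k) {
  key <- paste0("C", n, "_", k)
  got <- .poolcnv_cache[[key]]
  if (is.null(got)) {
    got <- utils::combn(n, k)
    .poolcnv_cache[[key]] <- got
  }
  got
}
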