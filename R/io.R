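# File formats
#
# Signal matrix: TSV with header `marker_id chrom position` then three
# columns per pool named `<pool>.lrr`, `<pool>.baf`, `<pool>.gc`; missing
# values are "NA". Pool manifest: TSV `pool_id  group` with group in
# {case, control}. Interval files (truth sets, reference CNV maps, gene
# annotations, regions) are BED-like: headerless TSV whose first three
# columns are chrom / start / end in the 0-based half-open BED dialect,
# followed by format-specific columns. All coordinates are converted to
# 1-based inclusive on read and back on write.

.bed_from_internal <- function(start, end) list(start = start - 1, end = end)
.bed_to_internal <- function(start, end) list(start = start + 1, end = end)

.read_tsv <- function(path, header) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  utils::read.delim(path, header = header, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "")
}

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Write / read a pooled dataset
#'
#' `write_dataset()` serialises a `pooled_dataset` to a directory of
#' plain-text files: `signals.tsv` (the marker signal matrix),
#' `pools.tsv` (the pool manifest) and `truth.bed` (the embedded CNV
#' events, BED dialect with copy-number and carrier columns).
#' `read_dataset()` inverts it; `read_dataset(write_dataset(ds))`
#' reproduces `ds` up to numeric print precision.
#'
#' @param ds A `pooled_dataset` from [simulate_dataset()].
#' @param path Directory to write into (created if needed) / read from.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `pooled_dataset`.
#' @export
write_dataset <- function(ds, path) {
  .assert(inherits(ds, "pooled_dataset"), "'ds' must be a pooled_dataset")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sig <- ds$markers
  for (p in ds$pools$pool_id) {
    sig[[paste0(p, ".lrr")]] <- ds$lrr[, p]
    sig[[paste0(p, ".baf")]] <- ds$baf[, p]
    sig[[paste0(p, ".gc")]]  <- ds$gc[, p]
  }
  utils::write.table(sig, file.path(path, "signals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$pools, file.path(path, "pools.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- ds$truth
  bed <- data.frame(chrom = tr$chrom, start = tr$start - 1, end = tr$end,
                    name = if (nrow(tr)) sprintf("event%03d", seq_len(nrow(tr))) else character(),
                    status = tr$status, copy_number = tr$copy_number,
                    carriers = tr$carriers, stringsAsFactors = FALSE)
  utils::write.table(bed, file.path(path, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  sig_path <- file.path(path, "signals.tsv")
  sig <- .read_tsv(sig_path, header = TRUE)
  need <- c("marker_id", "chrom", "position")
  .assert(all(need %in% names(sig)),
          sprintf("%s: missing required columns %s", sig_path,
                  paste(setdiff(need, names(sig)), collapse = ", ")))
  sig$chrom <- as.character(sig$chrom)
  # positions must be strictly increasing within each chromosome block
  for (ch in unique(sig$chrom)) {
    idx <- which(sig$chrom == ch)
    bad <- idx[which(diff(sig$position[idx]) <= 0) + 1L]
    if (length(bad))
      .parse_error(sig_path, bad[1L] + 1L,  # +1 for the header row
                   sprintf("non-monotone position for marker '%s' on chromosome %s",
                           sig$marker_id[bad[1L]], ch))
  }
  pools <- .read_tsv(file.path(path, "pools.tsv"), header = TRUE)
  .assert(all(c("pool_id", "group") %in% names(pools)), "malformed pool manifest")
  .assert(all(pools$group %in% c("case", "control")),
          "pool manifest group must be 'case' or 'control'")

  pull <- function(suffix) {
    cols <- paste0(pools$pool_id, ".", suffix)
    missing <- setdiff(cols, names(sig))
    .assert(length(missing) == 0L,
            sprintf("%s: missing signal columns: %s", sig_path,
                    paste(missing, collapse = ", ")))
    m <- as.matrix(sig[, cols, drop = FALSE])
    colnames(m) <- pools$pool_id
    m
  }
  truth_path <- file.path(path, "truth.bed")
  truth <- if (file.exists(truth_path) && file.size(truth_path) > 0) {
    tb <- .read_tsv(truth_path, header = FALSE)
    .assert(ncol(tb) >= 7L, sprintf("%s: expected 7 columns", truth_path))
    names(tb) <- c("chrom", "start", "end", "name", "status", "copy_number", "carriers")
    data.frame(chrom = as.character(tb$chrom), start = tb$start + 1,
               end = tb$end, copy_number = as.integer(tb$copy_number),
               status = tb$status, carriers = as.character(tb$carriers),
               stringsAsFactors = FALSE)
  } else {
    .events_to_truth(list(), list())
  }
  structure(list(
    markers = data.frame(marker_id = as.character(sig$marker_id),
                         chrom = sig$chrom, position = as.numeric(sig$position),
                         stringsAsFactors = FALSE),
    lrr = pull("lrr"), baf = pull("baf"), gc = pull("gc"),
    pools = data.frame(pool_id = as.character(pools$pool_id),
                       group = as.character(pools$group),
                       stringsAsFactors = FALSE),
    truth = truth, pool_size = NA_integer_, seed = NA_integer_
  ), class = "pooled_dataset")
}

#' Read a reference CNV map
#'
#' Reads a population CNV catalogue (for example a Han Chinese CNV map
#' assembled from HapMap CHB calls and published maps) from a BED-like
#' file: `chrom  start  end  name  status  [source]`, BED 0-based
#' half-open coordinates, `status` one of gain/loss/unknown.
#'
#' @param path Path to the BED-like file.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `status`, `source`.
#' @export
read_reference_map <- function(path) {
  b <- .read_tsv(path, header = FALSE)
  .assert(ncol(b) >= 3L, sprintf("%s: expected at least 3 columns", path))
  bad <- which(b[[2]] >= b[[3]])
  if (length(bad))
    .parse_error(path, bad[1L], "start must be < end (BED half-open)")
  data.frame(
    chrom = as.character(b[[1]]), start = b[[2]] + 1, end = b[[3]],
    status = if (ncol(b) >= 5L) as.character(b[[5]]) else "unknown",
    source = if (ncol(b) >= 6L) as.character(b[[6]]) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Read a gene annotation
#'
#' BED-like file `chrom  start  end  name  [synonyms]`, where `synonyms`
#' is a comma-separated list of alternative symbols (for example
#' `BMAL1,MOP3` for *ARNTL*).
#'
#' @param path Path to the BED-like gene file.
#' @return data.frame `name`, `chrom`, `start`, `end` (1-based inclusive),
#'   `synonyms` (comma-separated, possibly empty).
#' @export
read_genes <- function(path) {
  b <- .read_tsv(path, header = FALSE)
  .assert(ncol(b) >= 4L, sprintf("%s: expected at least 4 columns", path))
  dup <- duplicated(b[[4]])
  .assert(!any(dup), sprintf("%s: duplicate gene name '%s'", path, b[[4]][dup][1]))
  data.frame(
    name = as.character(b[[4]]), chrom = as.character(b[[1]]),
    start = b[[2]] + 1, end = b[[3]],
    synonyms = if (ncol(b) >= 5L) as.character(b[[5]]) else "",
    stringsAsFactors = FALSE
  )
}

#' Read a candidate-gene list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored; duplicates are dropped with a warning.
#'
#' @param path Path to the list file.
#' @return Character vector of unique gene symbols.
#' @export
read_candidate_genes <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) {
    warning("duplicate names in candidate list; deduplicated", call. = FALSE)
    x <- unique(x)
  }
  x
}

#' Write CNV calls or regions as BED-like TSV
#'
#' Coordinates are converted to the BED 0-based half-open dialect on disk;
#' all remaining columns are carried through unchanged.
#'
#' @param x data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   plus any extra columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedlike <- function(x, path) {
  .assert(all(c("chrom", "start", "end") %in% names(x)),
          "'x' needs chrom/start/end columns")
  out <- x
  out$start <- out$start - 1
  first <- c("chrom", "start", "end")
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
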