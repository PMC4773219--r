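# Genomic interval primitives shared by every stage of the pipeline.
#
# All coordinates are 0-based half-open internally; length = end - start.
# Dialect-specific conversions (1-based inclusive on disk for rawcnv/DGV
# style files) happen only at the I/O boundary.

.CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY")
.AUTOSOMES <- paste0("chr", 1:22)
.SEX_CHROMS <- c("chrX", "chrY")

#' Normalize chromosome labels to the canonical "chr*" set
#'
#' Accepts bare labels ("1", "X") and prefixed labels ("chr1"); anything
#' outside chr1..chr22, chrX, chrY is rejected (or returned as NA when
#' `strict = FALSE`, for record-level error accounting in readers).
#'
#' @param x character vector of chromosome labels.
#' @param strict error on unknown labels (default) instead of returning NA.
#' @return character vector of canonical labels.
#' @export
normalize_chrom <- function(x, strict = TRUE) {
  x <- as.character(x)
  bare <- !startsWith(x, "chr")
  x[bare] <- paste0("chr", x[bare])
  bad <- !(x %in% .CHROMS) & !is.na(x)
  if (any(bad)) {
    if (strict) {
      stop("unknown chromosome label(s): ",
           paste(unique(x[bad]), collapse = ", "))
    }
    x[bad] <- NA_character_
  }
  x
}

#' Validate an interval table
#'
#' Checks the core interval invariants: known chromosome, integer-valued
#' coordinates, end > start.
#'
#' @param df data.frame with columns chrom, start, end.
#' @param what label used in error messages.
#' @return the input, invisibly, after validation.
#' @export
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(!df$chrom %in% .CHROMS)) {
    stop(what, ": unknown chromosome label(s): ",
         paste(unique(setdiff(df$chrom, .CHROMS)), collapse = ", "))
  }
  if (any(df$end <= df$start)) {
    stop(what, ": end must exceed start (0-based half-open)")
  }
  invisible(df)
}

#' Reciprocal overlap between two sets of intervals, pairwise
#'
#' For paired intervals a[i] and b[i], computes the intersection length and
#' the fraction of each interval covered by the intersection. Two intervals
#' overlap reciprocally at fraction f when the intersection covers at least
#' f of EACH interval's length. Intervals on different chromosomes overlap
#' by zero.
#'
#' @param a,b data.frames with columns chrom, start, end; recycled to a
#'   common length if one has a single row.
#' @return data.frame with columns overlap_bp, fraction_a, fraction_b.
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0
  data.frame(
    overlap_bp = ov,
    fraction_a = ov / (a$end - a$start),
    fraction_b = ov / (b$end - b$start)
  )
}

# Pairs of rows (i, j), i < j, whose reciprocal overlap is >= min_fraction,
# restricted to rows sharing the grouping key. Sweep over start-sorted rows:
# only pairs with positive intersection can reach a positive fraction, so
# for each row we scan forward while starts precede the running max end.
.linked_pairs <- function(df, min_fraction, key_cols) {
  n <- nrow(df)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  ord <- order(key, df$start, df$end)
  res_i <- integer(0); res_j <- integer(0)
  ko <- key[ord]; so <- df$start[ord]; eo <- df$end[ord]
  for (ii in seq_len(n - 1L)) {
    jj <- ii + 1L
    # rows are start-sorted within a group, so once so[jj] >= eo[ii]
    # no later row can intersect row ii
    while (jj <= n && ko[jj] == ko[ii] && so[jj] < eo[ii]) {
      ov <- min(eo[ii], eo[jj]) - max(so[ii], so[jj])
      if (ov > 0 &&
          ov >= min_fraction * (eo[ii] - so[ii]) &&
          ov >= min_fraction * (eo[jj] - so[jj])) {
        res_i <- c(res_i, ord[ii]); res_j <- c(res_j, ord[jj])
      }
      jj <- jj + 1L
    }
  }
  cbind(res_i, res_j, deparse.level = 0)
}

# Union-find with path compression; returns cluster id per row.
.components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Single-linkage clustering of calls by reciprocal overlap
#'
#' Rows whose reciprocal overlap reaches `min_fraction` are linked; clusters
#' are the transitive closure of those links (single linkage), computed
#' within groups defined by `key_cols` (e.g. sample + chromosome + CNV type
#' for consensus merging; chromosome + type for cross-sample occurrence).
#'
#' @param df interval data.frame.
#' @param min_fraction reciprocal-overlap linkage threshold in (0, 1].
#' @param key_cols columns defining groups inside which linkage is tested;
#'   must include "chrom".
#' @return integer vector of cluster ids (1..k), one per row of `df`.
#' @export
cluster_by_overlap <- function(df, min_fraction = 0.5,
                               key_cols = c("chrom")) {
  stopifnot("chrom" %in% key_cols)
  if (nrow(df) == 0) return(integer(0))
  pairs <- .linked_pairs(df, min_fraction, key_cols)
  cl <- .components(nrow(df), pairs)
  # stable ids: number clusters by first appearance in (key, start) order
  ord <- do.call(order, c(df[key_cols], list(df$start, df$end)))
  match(cl, unique(cl[ord]))
}

#' Count probes falling inside each interval
#'
#' A probe at internal 0-based position p supports the interval [start, end)
#' iff start <= p < end. On the 1-based disk convention this is the closed
#' count of probes with start+1 <= position <= end.
#'
#' @param calls interval data.frame (chrom, start, end).
#' @param manifest probe manifest as returned by [read_manifest()] (columns
#'   probe_id, chrom, pos with pos 0-based internal).
#' @return integer vector of probe counts per call.
#' @export
count_probes <- function(calls, manifest) {
  if (nrow(calls) == 0) return(integer(0))
  out <- integer(nrow(calls))
  missing_chroms <- character(0)
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    pos <- manifest$pos[manifest$chrom == ch]
    if (length(pos) == 0) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    pos <- sort(pos)
    # probes in [start, end): first index with pos >= start .. last < end
    out[idx] <- findInterval(calls$end[idx] - 1L, pos) -
      findInterval(calls$start[idx] - 1L, pos)
  }
  if (length(missing_chroms)) {
    warning("no manifest probes on: ",
            paste(missing_chroms, collapse = ", "),
            "; probe_count set to 0 there")
  }
  out
}

# Minimum gap (bp) from each call to the nearest interval in `features`
# on the same chromosome; 0 if overlapping or abutting, Inf if the
# chromosome has no feature.
.gap_to_nearest <- function(calls, features) {
  n <- nrow(calls)
  out <- rep(Inf, n)
  if (n == 0 || nrow(features) == 0) return(out)
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    f <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0) next
    for (i in idx) {
      gaps <- pmax(f$start - calls$end[i], calls$start[i] - f$end)
      out[i] <- max(0, min(gaps))
    }
  }
  out
}
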