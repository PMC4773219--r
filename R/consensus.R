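# Multi-algorithm consensus merging and CNV-level filtering.
#
# A "stringent" consensus call is one supported by at least 2 of the 3
# calling algorithms: within (sample, chromosome, type), calls from
# different algorithms are linked when they overlap reciprocally by at
# least the linkage fraction (default 50%), clusters are the single-linkage
# closure, and the consensus interval spans the cluster's outer bounds.

#' Merge per-algorithm call sets into consensus calls
#'
#' @param callsets either one calls data.frame with an `algorithm` column
#'   covering all algorithms, or a named list of per-algorithm calls
#'   data.frames (names supply missing algorithm labels).
#' @param min_support minimum number of distinct supporting algorithms for
#'   a consensus call (default 2).
#' @param link_fraction reciprocal-overlap linkage threshold (default 0.5).
#' @param boundary consensus interval rule: "outer" (default, union
#'   bounds), "inner" (intersection bounds) or "median" (member medians).
#' @return consensus data.frame sorted by (sample, chromosome, start):
#'   sample_id, chrom, start, end, type, n_algorithms, algorithms
#'   (comma-joined), n_members, probe_count (0 until annotated), plus a
#'   `members` list-column of member-call data.frames.
#' @export
merge_algorithm_calls <- function(callsets, min_support = 2L,
                                  link_fraction = 0.5,
                                  boundary = c("outer", "inner", "median")) {
  boundary <- match.arg(boundary)
  if (is.data.frame(callsets)) {
    calls <- callsets
  } else {
    for (nm in names(callsets)) {
      if (nrow(callsets[[nm]]) &&
          all(is.na(callsets[[nm]]$algorithm))) {
        callsets[[nm]]$algorithm <- nm
      }
    }
    calls <- do.call(rbind, c(callsets, list(make.row.names = FALSE)))
  }
  if (is.null(calls) || nrow(calls) == 0) return(.empty_consensus())
  stopifnot(!any(is.na(calls$algorithm)))
  .check_calls(calls)

  dup <- duplicated(calls[c("algorithm", "sample_id", "chrom",
                            "start", "end", "type")])
  if (any(dup)) {
    warning("collapsed ", sum(dup),
            " duplicate (algorithm, sample, interval) call(s)")
    calls <- calls[!dup, , drop = FALSE]
  }

  cl <- cluster_by_overlap(calls, link_fraction,
                           key_cols = c("sample_id", "chrom", "type"))
  groups <- split(seq_len(nrow(calls)), cl)
  rows <- lapply(groups, function(idx) {
    m <- calls[idx, , drop = FALSE]
    algos <- sort(unique(m$algorithm))
    bounds <- switch(boundary,
      outer = c(min(m$start), max(m$end)),
      inner = c(max(m$start), min(m$end)),
      median = c(stats::median(m$start), stats::median(m$end)))
    data.frame(sample_id = m$sample_id[1], chrom = m$chrom[1],
               start = as.integer(bounds[1]), end = as.integer(bounds[2]),
               type = m$type[1], n_algorithms = length(algos),
               algorithms = paste(algos, collapse = ","),
               n_members = nrow(m), probe_count = 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(groups, function(idx) calls[idx, , drop = FALSE])
  out <- out[out$n_algorithms >= min_support, , drop = FALSE]
  ord <- order(out$sample_id, match(out$chrom, .CHROMS), out$start, out$end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_consensus <- function() {
  out <- data.frame(sample_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    type = character(0), n_algorithms = integer(0),
                    algorithms = character(0), n_members = integer(0),
                    probe_count = integer(0), stringsAsFactors = FALSE)
  out$members <- list()
  out
}

#' Annotate calls with manifest probe counts
#'
#' @param calls interval data.frame (consensus or raw calls).
#' @param manifest probe manifest (see [read_manifest()]).
#' @return `calls` with probe_count refreshed from the manifest.
#' @export
annotate_probe_counts <- function(calls, manifest) {
  calls$probe_count <- count_probes(calls, manifest)
  calls
}

#' Default CNV filter parameters
#' @param min_probes minimum probe support (default 5; fewer excluded).
#' @param max_gc maximum length-weighted mean GC fraction (default 0.70;
#'   above excluded).
#' @param centrotelo_margin_bp minimum distance from centromere/telomere
#'   intervals (default 30000; nearer excluded).
#' @param min_length_bp minimum call length (default 1000; shorter
#'   excluded).
#' @param exclude_sex_chroms drop chrX/chrY calls (default TRUE).
#' @param large_call_bp review-flag threshold for very large calls
#'   (default 1e6); flagged, not excluded.
#' @param large_call_cap optional hard cap in bp; calls longer than this
#'   are excluded as LARGE (default Inf = no cap, mirroring the fact that
#'   visual curation cannot be automated).
#' @return named list of parameters.
#' @export
cnv_filter_params <- function(min_probes = 5L, max_gc = 0.70,
                              centrotelo_margin_bp = 30000L,
                              min_length_bp = 1000L,
                              exclude_sex_chroms = TRUE,
                              large_call_bp = 1e6, large_call_cap = Inf) {
  list(min_probes = min_probes, max_gc = max_gc,
       centrotelo_margin_bp = centrotelo_margin_bp,
       min_length_bp = min_length_bp,
       exclude_sex_chroms = exclude_sex_chroms,
       large_call_bp = large_call_bp, large_call_cap = large_call_cap)
}

# Length-weighted mean GC of the track windows each call overlaps;
# NA where the call touches no window.
.call_gc <- function(calls, gc_track) {
  n <- nrow(calls)
  out <- rep(NA_real_, n)
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    g <- gc_track[gc_track$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    for (i in idx) {
      ov <- pmax(0, pmin(g$end, calls$end[i]) - pmax(g$start, calls$start[i]))
      w <- ov > 0
      if (any(w)) out[i] <- sum(g$gc[w] * ov[w]) / sum(ov[w])
    }
  }
  out
}

#' Apply the CNV-level filters to consensus calls
#'
#' Exclusion reasons, each per its quoted rule with the documented boundary
#' semantics:
#' \itemize{
#'   \item FEW_PROBES: probe_count < 5 (exactly 5 passes);
#'   \item HIGH_GC: length-weighted mean GC of overlapped windows > 0.70
#'     (exactly 0.70 passes);
#'   \item CENTROTELO: gap to the nearest centromere/telomere interval
#'     < 30,000 bp (exactly 30,000 passes);
#'   \item TOO_SMALL: length < 1,000 bp (exactly 1,000 passes);
#'   \item SEX_CHROM: chrX or chrY.
#' }
#' Calls longer than `large_call_bp` receive review_flag = "LARGE_CALL" but
#' are not excluded unless `large_call_cap` is finite and exceeded.
#'
#' @param consensus consensus calls with probe counts annotated.
#' @param annotation genome annotation (see [read_annotation()]).
#' @param params see [cnv_filter_params()].
#' @return list: `outcomes` (consensus columns + retained, reasons,
#'   review_flag, gc), `retained` (the surviving calls) and `tally`
#'   (data.frame reason/n: input, per-reason exclusion counts, total
#'   excluded calls, retained).
#' @export
apply_cnv_filters <- function(consensus, annotation,
                              params = cnv_filter_params()) {
  n <- nrow(consensus)
  len <- consensus$end - consensus$start
  reasons <- vector("list", n)
  if (n > 0) for (i in seq_len(n)) reasons[[i]] <- character(0)

  add <- function(hit, code) {
    for (i in which(hit)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  add(consensus$probe_count < params$min_probes, "FEW_PROBES")

  if (is.null(annotation$gc) || nrow(annotation$gc) == 0) {
    warning("no GC track in annotation: HIGH_GC filter skipped")
    gc <- rep(NA_real_, n)
  } else {
    gc <- .call_gc(consensus, annotation$gc)
    add(!is.na(gc) & gc > params$max_gc, "HIGH_GC")
  }

  features <- rbind(annotation$centromeres, annotation$telomeres)
  gap <- .gap_to_nearest(consensus, features)
  add(gap < params$centrotelo_margin_bp, "CENTROTELO")

  add(len < params$min_length_bp, "TOO_SMALL")
  if (params$exclude_sex_chroms) {
    add(consensus$chrom %in% .SEX_CHROMS, "SEX_CHROM")
  }
  if (is.finite(params$large_call_cap)) {
    add(len > params$large_call_cap, "LARGE")
  }

  outcomes <- consensus
  outcomes$members <- NULL
  outcomes$gc <- gc
  outcomes$retained <- lengths(reasons) == 0
  outcomes$reasons <- vapply(reasons, paste, character(1), collapse = ",")
  outcomes$review_flag <- ifelse(len > params$large_call_bp,
                                 "LARGE_CALL", "none")

  reason_levels <- c("FEW_PROBES", "HIGH_GC", "CENTROTELO", "TOO_SMALL",
                     "SEX_CHROM", "LARGE")
  tally <- data.frame(
    reason = c("input", reason_levels, "excluded", "retained"),
    n = c(n,
          vapply(reason_levels,
                 function(r) sum(vapply(reasons, function(x) r %in% x,
                                        logical(1))),
                 integer(1)),
          sum(!outcomes$retained), sum(outcomes$retained)),
    stringsAsFactors = FALSE)

  list(outcomes = outcomes,
       retained = consensus[outcomes$retained, , drop = FALSE],
       tally = tally)
}
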