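# Rarity and novelty assessment, case/control specificity, recurrence,
# gene annotation and burden statistics.
#
# A filtered consensus call is "rare or novel" when it (i) does not overlap
# any known copy number polymorphism with population frequency > 1%,
# (ii) has < 50% reciprocal overlap (by length) with every variant in the
# reference sets, and (iii) occurs as a singleton in the cohort. Rules are
# applied in that order and each exclusion is recorded separately so the
# stage tallies are auditable. Case/control specificity is assessed on the
# calls surviving rules (i) and (ii); singleton status is carried along so
# recurrent case-specific loci (>= 2 case carriers at the same locus) can
# be reported, matching the study bookkeeping that counts them among the
# case-specific set.

#' Flag calls overlapping known copy-number polymorphisms
#'
#' A call is `known_cnp` when it overlaps — by at least one base in the
#' default `any_overlap` mode — a reference variant whose frequency exceeds
#' `freq_threshold` (default 1%).
#'
#' @param calls interval data.frame.
#' @param cnp_set reference set with frequencies (see
#'   [read_reference_set()]).
#' @param freq_threshold population-frequency cutoff (default 0.01,
#'   strict: frequency must exceed it).
#' @param mode "any_overlap" (>= 1 bp) or "reciprocal" (>= 50% reciprocal).
#' @return data.frame: known_cnp (logical), cnp_ids (comma-joined matches).
#' @export
filter_known_cnp <- function(calls, cnp_set, freq_threshold = 0.01,
                             mode = c("any_overlap", "reciprocal")) {
  mode <- match.arg(mode)
  ref <- cnp_set[!is.na(cnp_set$frequency) &
                 cnp_set$frequency > freq_threshold, , drop = FALSE]
  hits <- .match_reference(calls, ref,
                           f = if (mode == "any_overlap") 0 else 0.5,
                           type_aware = TRUE)
  data.frame(known_cnp = lengths(hits) > 0,
             cnp_ids = vapply(hits, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

# Per-call reference ids matching at reciprocal fraction >= f (f = 0 means
# any overlap >= 1 bp). Reference rows of type "any" match both call types.
.match_reference <- function(calls, ref, f, type_aware = TRUE) {
  n <- nrow(calls)
  hits <- replicate(n, character(0), simplify = FALSE)
  if (n == 0 || nrow(ref) == 0) return(hits)
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    r <- ref[ref$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0) next
    for (i in idx) {
      ov <- pmax(0, pmin(r$end, calls$end[i]) - pmax(r$start, calls$start[i]))
      ok <- ov > 0
      if (f > 0) {
        ok <- ok & ov >= f * (calls$end[i] - calls$start[i]) &
                   ov >= f * (r$end - r$start)
      }
      if (type_aware && "type" %in% names(calls)) {
        ok <- ok & (r$type == "any" | r$type == calls$type[i])
      }
      if (any(ok)) hits[[i]] <- r$id[ok]
    }
  }
  hits
}

#' Flag calls known to reference variant catalogues by reciprocal overlap
#'
#' A call is `known_reference` when some variant in any of the supplied
#' reference sets overlaps it reciprocally at fraction >= `f` (default 0.5;
#' a call retaining < 50% reciprocal overlap with every catalogued variant
#' is putatively novel). Exactly 50% counts as known. Sets are checked
#' sequentially with per-set match records.
#'
#' @param calls interval data.frame.
#' @param reference_sets one reference set or a list of them (DGV-like,
#'   HapMap3-like, SGVP-like, ...).
#' @param f reciprocal-overlap exclusion threshold (default 0.5).
#' @return data.frame: known_reference (logical), one `matches_<set>`
#'   column per set with comma-joined variant ids.
#' @export
filter_reference_overlap <- function(calls, reference_sets, f = 0.5) {
  if (is.data.frame(reference_sets)) {
    reference_sets <- list(reference_sets)
  }
  nms <- names(reference_sets)
  if (is.null(nms)) nms <- rep("", length(reference_sets))
  out <- data.frame(known_reference = rep(FALSE, nrow(calls)))
  for (k in seq_along(reference_sets)) {
    ref <- reference_sets[[k]]
    nm <- if (nzchar(nms[k])) nms[k]
          else if (!is.null(attr(ref, "set_name"))) attr(ref, "set_name")
          else paste0("set", k)
    hits <- .match_reference(calls, ref, f = f, type_aware = TRUE)
    out[[paste0("matches_", nm)]] <-
      vapply(hits, paste, character(1), collapse = ",")
    out$known_reference <- out$known_reference | lengths(hits) > 0
  }
  out
}

#' Identify singleton versus multi-sample CNV loci in a cohort
#'
#' Calls of the same type are linked across samples at reciprocal overlap
#' >= `link_fraction` (single linkage). Calls in occurrence clusters
#' spanning two or more distinct samples are non-singletons.
#'
#' @param calls cohort calls (must carry sample_id).
#' @param link_fraction reciprocal-overlap linkage (default 0.5).
#' @return data.frame: occurrence_cluster (integer id), n_samples (distinct
#'   samples in the call's cluster), singleton (logical).
#' @export
find_singletons <- function(calls, link_fraction = 0.5) {
  cl <- cluster_by_overlap(calls, link_fraction,
                           key_cols = c("chrom", "type"))
  ns <- vapply(split(calls$sample_id, cl),
               function(s) length(unique(s)), integer(1))
  n_samples <- unname(ns[as.character(cl)])
  data.frame(occurrence_cluster = cl, n_samples = n_samples,
             singleton = n_samples == 1)
}

#' Split calls into case-specific and control-specific sets
#'
#' A call from a case sample is case-specific iff no call from any control
#' sample, of the same CNV type, links to it at reciprocal overlap >=
#' `link_fraction`; control-specificity is symmetric. Calls at loci shared
#' between the groups belong to neither set.
#'
#' @param calls calls surviving the rarity rules (sample_id required).
#' @param groups named character vector mapping sample_id to
#'   "case"/"control", or a cohort data.frame with those columns.
#' @param link_fraction reciprocal-overlap linkage (default 0.5).
#' @return list: `case_specific` and `control_specific` call data.frames,
#'   each with gain/loss tallies in attribute "tally", and `shared` for the
#'   remainder.
#' @export
case_control_specific <- function(calls, groups, link_fraction = 0.5) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  grp <- unname(groups[calls$sample_id])
  if (any(is.na(grp))) stop("group label missing for some sample(s)")
  cl <- cluster_by_overlap(calls, link_fraction,
                           key_cols = c("chrom", "type"))
  has_case <- vapply(split(grp == "case", cl), any, logical(1))
  has_ctrl <- vapply(split(grp == "control", cl), any, logical(1))
  key <- as.character(cl)
  case_specific <- grp == "case" & !unname(has_ctrl[key])
  ctrl_specific <- grp == "control" & !unname(has_case[key])
  tally <- function(df) {
    c(total = nrow(df), gain = sum(df$type == "gain"),
      loss = sum(df$type == "loss"))
  }
  cs <- calls[case_specific, , drop = FALSE]
  ct <- calls[ctrl_specific, , drop = FALSE]
  attr(cs, "tally") <- tally(cs)
  attr(ct, "tally") <- tally(ct)
  list(case_specific = cs, control_specific = ct,
       shared = calls[!case_specific & !ctrl_specific, , drop = FALSE])
}

#' Find recurrent loci among case-specific calls
#'
#' Case-specific calls are clustered across samples (same type, reciprocal
#' overlap >= `link_fraction`, single linkage); clusters carried by at
#' least `min_samples` distinct samples are reported as recurrent loci with
#' outer-bound coordinates and, when gene models are supplied, the genes
#' they disrupt.
#'
#' @param calls case-specific calls.
#' @param min_samples minimum distinct carriers (default 2).
#' @param link_fraction reciprocal-overlap linkage (default 0.5).
#' @param genes optional gene-model data.frame (chrom, start, end, gene).
#' @return data.frame: chrom, start, end, type, n_samples, sample_ids
#'   (comma-joined), genes (comma-joined or "-").
#' @export
find_recurrent <- function(calls, min_samples = 2L, link_fraction = 0.5,
                           genes = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      n_samples = integer(0), sample_ids = character(0),
                      genes = character(0), stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  cl <- cluster_by_overlap(calls, link_fraction,
                           key_cols = c("chrom", "type"))
  rows <- lapply(split(seq_len(nrow(calls)), cl), function(idx) {
    m <- calls[idx, , drop = FALSE]
    ids <- sort(unique(m$sample_id))
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               type = m$type[1], n_samples = length(ids),
               sample_ids = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  ann <- annotate_genes(out, if (is.null(genes)) .empty_gene_models()
                             else genes)
  out$genes <- ann
  out <- out[order(match(out$chrom, .CHROMS), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_gene_models <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             gene = character(0), stringsAsFactors = FALSE)
}

#' List genes intersecting each call
#'
#' A gene is reported when it intersects the call by at least one base
#' (`mode = "any"`, default) or only when fully contained
#' (`mode = "contained"`). Calls touching no gene are rendered "-".
#'
#' @param calls interval data.frame.
#' @param genes gene models (chrom, start, end, gene).
#' @param mode "any" or "contained".
#' @return character vector of comma-joined gene symbols ("-" when none).
#' @export
annotate_genes <- function(calls, genes, mode = c("any", "contained")) {
  mode <- match.arg(mode)
  n <- nrow(calls)
  out <- rep("-", n)
  if (n == 0 || nrow(genes) == 0) return(out)
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    for (i in idx) {
      hit <- if (mode == "any") {
        pmin(g$end, calls$end[i]) - pmax(g$start, calls$start[i]) > 0
      } else {
        g$start >= calls$start[i] & g$end <= calls$end[i]
      }
      if (any(hit)) out[i] <- paste(sort(unique(g$gene[hit])),
                                    collapse = ",")
    }
  }
  out
}

#' Burden report for case and control CNV sets
#'
#' Per-group totals with gain/loss split, per-genome means, length mean and
#' median, a size-bin percentage histogram, and a two-sample comparison of
#' call lengths (Welch's t-test by default, Wilcoxon rank-sum optional).
#'
#' @param case_calls,control_calls call data.frames.
#' @param n_case_genomes,n_control_genomes genome counts (> 0).
#' @param size_bins bin edges in bp for the length histogram (default
#'   1 kb / 10 kb / 100 kb / 1 Mb decades).
#' @param length_test "welch" (default) or "wilcoxon".
#' @return list: `summary` (per-group data.frame), `histogram` (bin,
#'   case_pct, control_pct), `length_test` (statistic, p_value, method).
#' @export
burden_report <- function(case_calls, control_calls, n_case_genomes,
                          n_control_genomes,
                          size_bins = c(0, 1e3, 1e4, 1e5, 1e6, Inf),
                          length_test = c("welch", "wilcoxon")) {
  length_test <- match.arg(length_test)
  stopifnot(n_case_genomes > 0, n_control_genomes > 0)
  one <- function(df, n_genomes, label) {
    len <- df$end - df$start
    data.frame(group = label, n_cnv = nrow(df),
               gains = sum(df$type == "gain"),
               losses = sum(df$type == "loss"),
               n_genomes = n_genomes,
               per_genome = nrow(df) / n_genomes,
               mean_length = if (nrow(df)) mean(len) else 0,
               median_length = if (nrow(df)) stats::median(len) else 0,
               stringsAsFactors = FALSE)
  }
  if (nrow(case_calls) == 0 || nrow(control_calls) == 0) {
    warning("empty call set for one group; comparison statistics are zero")
  }
  summary <- rbind(one(case_calls, n_case_genomes, "case"),
                   one(control_calls, n_control_genomes, "control"))

  bin_label <- paste0("[", utils::head(size_bins, -1), ",",
                      utils::tail(size_bins, -1), ")")
  pct <- function(df) {
    if (nrow(df) == 0) return(rep(0, length(bin_label)))
    len <- df$end - df$start
    counts <- table(cut(len, size_bins, right = FALSE,
                        labels = bin_label))
    100 * as.numeric(counts) / nrow(df)
  }
  histogram <- data.frame(bin = bin_label, case_pct = pct(case_calls),
                          control_pct = pct(control_calls),
                          stringsAsFactors = FALSE)

  lc <- case_calls$end - case_calls$start
  lt <- control_calls$end - control_calls$start
  test <- if (length(lc) >= 2 && length(lt) >= 2 &&
              (stats::sd(lc) > 0 || stats::sd(lt) > 0)) {
    if (length_test == "welch") {
      tt <- stats::t.test(lc, lt)
      list(statistic = unname(tt$statistic), p_value = tt$p.value,
           method = "welch")
    } else {
      wt <- stats::wilcox.test(lc, lt, exact = FALSE)
      list(statistic = unname(wt$statistic), p_value = wt$p.value,
           method = "wilcoxon")
    }
  } else {
    list(statistic = 0, p_value = 1, method = length_test)
  }
  list(summary = summary, histogram = histogram, length_test = test)
}
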