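# Per-sample SNP-array quality control.
#
# Exclusion thresholds (strict, boundary passes):
#   call rate < 0.99; LRR SD > 0.35; BAF SD > 0.13 (heterozygous band);
#   batch-normalized intensity-ratio SD > 0.27.
# After consensus calling, samples that are upper outliers with respect to
# aggregate CNV length (Tukey fence Q3 + 3*IQR) are additionally excluded.

#' Default QC thresholds
#' @param min_call_rate minimum genotype call rate (default 0.99).
#' @param max_lrr_sd maximum autosomal LRR standard deviation (0.35).
#' @param max_baf_sd maximum heterozygous-band BAF standard deviation (0.13).
#' @param max_batch_ratio_sd maximum batch-normalized ratio SD (0.27).
#' @param length_fence_iqr multiplier k in the aggregate-length upper fence
#'   Q3 + k*IQR (default 3).
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(min_call_rate = 0.99, max_lrr_sd = 0.35,
                          max_baf_sd = 0.13, max_batch_ratio_sd = 0.27,
                          length_fence_iqr = 3) {
  stopifnot(min_call_rate > 0, max_lrr_sd > 0, max_baf_sd > 0,
            max_batch_ratio_sd > 0, length_fence_iqr > 0)
  list(min_call_rate = min_call_rate, max_lrr_sd = max_lrr_sd,
       max_baf_sd = max_baf_sd, max_batch_ratio_sd = max_batch_ratio_sd,
       length_fence_iqr = length_fence_iqr)
}

#' Compute per-sample array QC metrics from probe-level signals
#'
#' All matrices are probes x samples, treated as one batch.
#' - call_rate: fraction of probes with a genotype call.
#' - lrr_sd: SD of the LRR values (pass autosomal probes only).
#' - baf_sd: SD of BAF over probes in the heterozygous band [0.25, 0.75];
#'   the full-range SD is dominated by the homozygous clusters and would
#'   defeat the 0.13 threshold.
#' - batch_ratio_sd: SD of the per-probe intensity ratio to the batch
#'   median profile. When `intensity` is not supplied it is derived from
#'   LRR as 2^LRR (the normalized total-intensity ratio).
#'
#' @param lrr numeric matrix of log R ratios (probes x samples).
#' @param baf numeric matrix of B allele frequencies, same shape.
#' @param called logical matrix of genotype-call flags, same shape.
#' @param intensity optional matrix of raw intensity ratios.
#' @param het_band BAF band treated as heterozygous (default c(0.25, 0.75)).
#' @return data.frame: sample_id, call_rate, lrr_sd, baf_sd, batch_ratio_sd.
#' @export
compute_qc_metrics <- function(lrr, baf, called, intensity = NULL,
                               het_band = c(0.25, 0.75)) {
  stopifnot(is.matrix(lrr), is.matrix(baf), is.matrix(called),
            all(dim(lrr) == dim(baf)), all(dim(lrr) == dim(called)))
  if (nrow(lrr) == 0) stop("empty signal matrices")
  if (is.null(intensity)) intensity <- 2^lrr
  ids <- colnames(lrr)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(ncol(lrr)))
  med_profile <- apply(intensity, 1, stats::median)
  ratio <- intensity / med_profile
  baf_sd <- vapply(seq_len(ncol(baf)), function(j) {
    b <- baf[, j]
    het <- b >= het_band[1] & b <= het_band[2]
    if (sum(het) < 2) return(0)
    stats::sd(b[het])
  }, numeric(1))
  data.frame(
    sample_id = ids,
    call_rate = colMeans(called),
    lrr_sd = apply(lrr, 2, stats::sd),
    baf_sd = baf_sd,
    batch_ratio_sd = apply(ratio, 2, stats::sd),
    stringsAsFactors = FALSE)
}

#' Apply sample-level QC thresholds
#'
#' Directions are strict, matching the quoted criteria: a sample fails iff
#' call_rate < 0.99, lrr_sd > 0.35, baf_sd > 0.13 or batch_ratio_sd > 0.27;
#' metrics exactly at a bound pass.
#'
#' @param metrics data.frame from [compute_qc_metrics()].
#' @param thresholds see [qc_thresholds()].
#' @return data.frame: sample_id, kept, reasons (comma-joined codes among
#'   CALL_RATE, LRR_SD, BAF_SD, BATCH_RATIO_SD).
#' @export
apply_sample_qc <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(all(metrics$call_rate >= 0 & metrics$call_rate <= 1),
            all(metrics$lrr_sd >= 0), all(metrics$baf_sd >= 0),
            all(metrics$batch_ratio_sd >= 0))
  reasons <- mapply(function(cr, lsd, bsd, rsd) {
    r <- character(0)
    if (cr < thresholds$min_call_rate) r <- c(r, "CALL_RATE")
    if (lsd > thresholds$max_lrr_sd) r <- c(r, "LRR_SD")
    if (bsd > thresholds$max_baf_sd) r <- c(r, "BAF_SD")
    if (rsd > thresholds$max_batch_ratio_sd) r <- c(r, "BATCH_RATIO_SD")
    paste(r, collapse = ",")
  }, metrics$call_rate, metrics$lrr_sd, metrics$baf_sd,
     metrics$batch_ratio_sd)
  data.frame(sample_id = metrics$sample_id,
             kept = !nzchar(reasons),
             reasons = unname(reasons),
             stringsAsFactors = FALSE)
}

#' Flag aggregate-CNV-length outlier samples
#'
#' Among currently kept samples, flags those whose aggregate CNV length
#' exceeds the Tukey upper fence Q3 + k*IQR (quartiles type 7, k from the
#' thresholds). With fewer than 4 kept samples no test is run (warning).
#' A sample with no calls has aggregate length 0 and is never an upper
#' outlier.
#'
#' @param decisions data.frame from [apply_sample_qc()].
#' @param aggregate_lengths named numeric vector, bp per sample_id; absent
#'   samples count as 0.
#' @param thresholds see [qc_thresholds()].
#' @return updated decisions with LENGTH_OUTLIER appended to reasons and an
#'   aggregate_cnv_length column.
#' @export
exclude_length_outliers <- function(decisions, aggregate_lengths,
                                    thresholds = qc_thresholds()) {
  agg <- aggregate_lengths[decisions$sample_id]
  agg[is.na(agg)] <- 0
  decisions$aggregate_cnv_length <- unname(agg)
  kept <- decisions$kept
  if (sum(kept) < 4) {
    warning("fewer than 4 kept samples; aggregate-length outlier test skipped")
    return(decisions)
  }
  q <- stats::quantile(agg[kept], c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + thresholds$length_fence_iqr * (q[2] - q[1])
  out <- kept & agg > fence
  if (any(out)) {
    decisions$kept[out] <- FALSE
    decisions$reasons[out] <- ifelse(
      nzchar(decisions$reasons[out]),
      paste(decisions$reasons[out], "LENGTH_OUTLIER", sep = ","),
      "LENGTH_OUTLIER")
  }
  decisions
}
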