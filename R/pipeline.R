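# End-to-end orchestration: sample QC -> consensus merge -> aggregate-length
# outliers -> CNV filters -> rarity -> specificity -> recurrence -> burden,
# with a stage-by-stage run manifest whose counts conserve.

#' Bundle of all pipeline parameters with study defaults
#'
#' @param qc see [qc_thresholds()].
#' @param filters see [cnv_filter_params()].
#' @param lvh see [lvh_thresholds()].
#' @param min_support minimum supporting algorithms for a consensus call.
#' @param link_fraction reciprocal-overlap linkage used for merging,
#'   occurrence, specificity and recurrence.
#' @param cnp_freq_threshold population-frequency cutoff for the known-CNP
#'   rule (frequency must exceed it).
#' @param reference_fraction reciprocal-overlap threshold for the
#'   reference-novelty rule (>= excludes).
#' @param recurrent_min_samples distinct carriers defining recurrence.
#' @return named list with class "pipeline_params".
#' @export
pipeline_params <- function(qc = qc_thresholds(),
                            filters = cnv_filter_params(),
                            lvh = lvh_thresholds(),
                            min_support = 2L, link_fraction = 0.5,
                            cnp_freq_threshold = 0.01,
                            reference_fraction = 0.5,
                            recurrent_min_samples = 2L) {
  out <- list(qc = qc, filters = filters, lvh = lvh,
              min_support = min_support, link_fraction = link_fraction,
              cnp_freq_threshold = cnp_freq_threshold,
              reference_fraction = reference_fraction,
              recurrent_min_samples = recurrent_min_samples)
  class(out) <- "pipeline_params"
  out
}

#' Run the full rare-CNV discovery pipeline
#'
#' Stages, in study order:
#' \enumerate{
#'   \item sample QC on array metrics (call rate, LRR SD, BAF SD,
#'     batch-ratio SD), dropping failing samples and their calls;
#'   \item consensus merge of the per-algorithm call sets (>= min_support
#'     of 3 algorithms, reciprocal-overlap single linkage);
#'   \item aggregate-CNV-length outlier exclusion (Tukey upper fence),
#'     dropping flagged samples and their consensus calls;
#'   \item CNV-level filters (probe support, GC, centromere/telomere
#'     margin, size, sex chromosomes);
#'   \item rarity rules in order: known CNP (any overlap, frequency > 1%)
#'     then reference catalogues (>= 50% reciprocal overlap) then
#'     cohort singleton status;
#'   \item case/control specificity on the calls surviving the CNP and
#'     reference rules (singleton status is recorded; recurrent
#'     case-specific loci are retained and reported);
#'   \item recurrence among case-specific calls; gene annotation;
#'   \item burden report (per-genome means, gain/loss split, length
#'     comparison, size histogram).
#' }
#'
#' @param callsets named list of per-algorithm call data.frames.
#' @param samples cohort data.frame (sample_id, group, sex, ...).
#' @param manifest probe manifest.
#' @param annotation genome annotation.
#' @param references named list of reference sets; the CNP rule uses the
#'   frequencies of all sets, the novelty rule their intervals.
#' @param qc_metrics per-sample metrics data.frame (see
#'   [compute_qc_metrics()]), or NULL to skip signal-level QC.
#' @param params see [pipeline_params()].
#' @return list with every stage's output: qc_decisions, consensus,
#'   filter (outcomes/retained/tally), rarity (per-call statuses),
#'   specificity (case/control/shared), recurrent, burden, manifest
#'   (stage-count data.frame), kept_samples.
#' @export
run_pipeline <- function(callsets, samples, manifest, annotation,
                         references, qc_metrics = NULL,
                         params = pipeline_params()) {
  stages <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, detail = detail,
      stringsAsFactors = FALSE)
  }

  # 1. sample QC
  if (!is.null(qc_metrics)) {
    qc <- apply_sample_qc(qc_metrics, params$qc)
  } else {
    qc <- data.frame(sample_id = samples$sample_id, kept = TRUE,
                     reasons = "", stringsAsFactors = FALSE)
  }
  kept <- qc$sample_id[qc$kept]
  note("sample_qc", nrow(qc), length(kept),
       paste0("excluded=", sum(!qc$kept)))

  callsets_kept <- lapply(callsets, function(df) {
    df[df$sample_id %in% kept, , drop = FALSE]
  })
  n_raw <- sum(vapply(callsets_kept, nrow, integer(1)))

  # 2. consensus merge
  consensus <- merge_algorithm_calls(callsets_kept,
                                     min_support = params$min_support,
                                     link_fraction = params$link_fraction)
  note("consensus_merge", n_raw, nrow(consensus),
       paste0("min_support=", params$min_support))

  # 3. aggregate-length outliers
  agg <- tapply(consensus$end - consensus$start, consensus$sample_id, sum)
  qc <- exclude_length_outliers(qc, agg, params$qc)
  kept <- qc$sample_id[qc$kept]
  n_before <- nrow(consensus)
  consensus <- consensus[consensus$sample_id %in% kept, , drop = FALSE]
  note("length_outliers", n_before, nrow(consensus),
       paste0("samples_kept=", length(kept)))

  # 4. CNV-level filters
  consensus <- annotate_probe_counts(consensus, manifest)
  filt <- apply_cnv_filters(consensus, annotation, params$filters)
  filtered <- filt$retained
  note("cnv_filters", nrow(consensus), nrow(filtered),
       paste(filt$tally$reason, filt$tally$n, sep = "=", collapse = ","))

  # 5. rarity rules, in order
  cnp <- filter_known_cnp(filtered, .pool_references(references),
                          freq_threshold = params$cnp_freq_threshold)
  ref <- filter_reference_overlap(filtered, references,
                                  f = params$reference_fraction)
  status <- ifelse(cnp$known_cnp, "known_cnp",
                   ifelse(ref$known_reference, "known_reference", "novel"))
  novel <- filtered[status == "novel", , drop = FALSE]
  singles <- find_singletons(novel, params$link_fraction)
  rarity <- filtered
  rarity$members <- NULL
  rarity$status <- status
  rarity$cnp_ids <- cnp$cnp_ids
  rarity$known_reference <- ref$known_reference
  rarity$singleton <- NA
  rarity$singleton[status == "novel"] <- singles$singleton
  note("rarity", nrow(filtered), nrow(novel),
       paste0("known_cnp=", sum(status == "known_cnp"),
              ",known_reference=", sum(status == "known_reference")))

  # 6. case/control specificity (singletons and recurrent loci both kept)
  spec <- case_control_specific(novel, samples, params$link_fraction)
  note("specificity", nrow(novel),
       nrow(spec$case_specific) + nrow(spec$control_specific),
       paste0("case=", nrow(spec$case_specific),
              ",control=", nrow(spec$control_specific),
              ",shared=", nrow(spec$shared)))

  # 7. recurrence + gene annotation
  recurrent <- find_recurrent(spec$case_specific,
                              min_samples = params$recurrent_min_samples,
                              link_fraction = params$link_fraction,
                              genes = annotation$genes)
  note("recurrence", nrow(spec$case_specific), nrow(recurrent), "")
  spec$case_specific$genes <-
    annotate_genes(spec$case_specific, annotation$genes)
  spec$control_specific$genes <-
    annotate_genes(spec$control_specific, annotation$genes)

  # 8. burden
  n_case <- sum(samples$group == "case" & samples$sample_id %in% kept)
  n_ctrl <- sum(samples$group == "control" & samples$sample_id %in% kept)
  burden <- if (nrow(spec$case_specific) && nrow(spec$control_specific)) {
    burden_report(spec$case_specific, spec$control_specific,
                  n_case, n_ctrl)
  } else {
    suppressWarnings(burden_report(spec$case_specific,
                                   spec$control_specific,
                                   max(n_case, 1), max(n_ctrl, 1)))
  }

  list(qc_decisions = qc, kept_samples = kept, consensus = consensus,
       filter = filt, rarity = rarity, novel = novel,
       specificity = spec, recurrent = recurrent, burden = burden,
       manifest = do.call(rbind, stages))
}

# All reference variants with a frequency, pooled for the CNP rule.
.pool_references <- function(references) {
  if (is.data.frame(references)) return(references)
  pooled <- do.call(rbind, lapply(references, function(r) {
    as.data.frame(r)[!is.na(r$frequency),
                     c("id", "chrom", "start", "end", "type", "frequency"),
                     drop = FALSE]
  }))
  rownames(pooled) <- NULL
  pooled
}

#' Write the pipeline's report files
#'
#' Emits the stage manifest, QC report, consensus calls, filter tally,
#' rarity statuses, case/control-specific calls, recurrence table and
#' burden summary as TSVs under `dir`.
#'
#' @param result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    df <- as.data.frame(df)
    df$members <- NULL
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  w(result$manifest, "run_manifest.tsv")
  w(result$qc_decisions, "sample_qc.tsv")
  w(result$consensus, "consensus_calls.tsv")
  w(result$filter$outcomes, "filter_outcomes.tsv")
  w(result$filter$tally, "filter_tally.tsv")
  w(result$rarity, "rarity_status.tsv")
  w(result$specificity$case_specific, "case_specific.tsv")
  w(result$specificity$control_specific, "control_specific.tsv")
  w(result$recurrent, "recurrent_loci.tsv")
  w(result$burden$summary, "burden_summary.tsv")
  w(result$burden$histogram, "length_histogram.tsv")
  invisible(dir)
}
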