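#!/usr/bin/env Rscript
# Stage 3 — per-sample array QC against the exclusion thresholds:
# call rate < 99%, LRR SD > 0.35, heterozygous-band BAF SD > 0.13,
# batch-normalized ratio SD > 0.27. (The aggregate-CNV-length outlier
# rule needs consensus calls and is applied in stage 4.)

suppressPackageStartupMessages(library(rarecnv))

metrics <- read.delim("results/simulated/qc_metrics.tsv")
decisions <- apply_sample_qc(metrics)
write.table(decisions, "results/sample_qc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("samples: %d in, %d kept, %d excluded\n", nrow(decisions),
            sum(decisions$kept), sum(!decisions$kept)))
if (any(!decisions$kept)) {
  bad <- decisions[!decisions$kept, ]
  cat("exclusions:\n")
  cat(sprintf("  %s: %s\n", bad$sample_id, bad$reasons), sep = "")
} else {
  cat("no sample exceeded any QC threshold\n")
}
cat(sprintf("metric ranges: call_rate %.4f-%.4f, lrr_sd %.3f-%.3f, baf_sd %.3f-%.3f, batch_ratio_sd %.3f-%.3f\n",
            min(metrics$call_rate), max(metrics$call_rate),
            min(metrics$lrr_sd), max(metrics$lrr_sd),
            min(metrics$baf_sd), max(metrics$baf_sd),
            min(metrics$batch_ratio_sd), max(metrics$batch_ratio_sd)))
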