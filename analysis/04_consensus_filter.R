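#!/usr/bin/env Rscript
# Stage 4 — stringent consensus calls and CNV-level filtering.
#
# Calls from the three algorithms are merged within (sample, chromosome,
# type) by 50% reciprocal-overlap single linkage; clusters supported by
# fewer than 2 algorithms are dropped. Samples that are upper outliers in
# aggregate CNV length are then excluded, and the five CNV filters are
# applied (probe support >= 5, GC <= 0.70, >= 30 kb from
# centromeres/telomeres, length >= 1 kb, autosomes only).

suppressPackageStartupMessages(library(rarecnv))

dirin <- "results/simulated"
algos <- sub("^calls_(.*)\\.tsv$", "\\1",
             list.files(dirin, pattern = "^calls_.*\\.tsv$"))
callsets <- lapply(algos, function(a) {
  read_calls(file.path(dirin, paste0("calls_", a, ".tsv")), "tsv")
})
names(callsets) <- algos
manifest <- read_manifest(file.path(dirin, "manifest.tsv"))
annotation <- read_annotation(file.path(dirin, "chrom_lengths.tsv"),
                              file.path(dirin, "regions.bed"),
                              file.path(dirin, "gc_track.tsv"),
                              file.path(dirin, "genes.bed"))
qc <- read.delim("results/sample_qc.tsv")
keep <- qc$sample_id[qc$kept]
callsets <- lapply(callsets, function(df) df[df$sample_id %in% keep, ])

consensus <- merge_algorithm_calls(callsets)
cat(sprintf("raw calls: %d; stringent consensus calls (>=2 of %d algorithms): %d\n",
            sum(vapply(callsets, nrow, integer(1))), length(callsets),
            nrow(consensus)))
cat(sprintf("consensus per genome: %.1f\n",
            nrow(consensus) / length(keep)))

agg <- tapply(consensus$end - consensus$start, consensus$sample_id, sum)
qc2 <- exclude_length_outliers(qc[c("sample_id", "kept", "reasons")], agg)
out_n <- sum(qc$kept) - sum(qc2$kept)
cat(sprintf("aggregate-length outliers excluded: %d\n", out_n))
consensus <- consensus[consensus$sample_id %in% qc2$sample_id[qc2$kept], ]

consensus <- annotate_probe_counts(consensus, manifest)
filt <- apply_cnv_filters(consensus, annotation)

write.table(qc2, "results/sample_qc_final.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
out <- filt$outcomes
write.table(out, "results/filter_outcomes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(filt$tally, "results/filter_tally.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
retained <- filt$retained
retained$members <- NULL
write.table(retained, "results/filtered_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tly <- stats::setNames(filt$tally$n, filt$tally$reason)
cat(sprintf("CNV filters: %d in, %d retained, %d excluded\n",
            tly[["input"]], tly[["retained"]], tly[["excluded"]]))
for (r in c("FEW_PROBES", "HIGH_GC", "CENTROTELO", "TOO_SMALL",
            "SEX_CHROM")) {
  if (tly[[r]] > 0) cat(sprintf("  %s: %d\n", r, tly[[r]]))
}
cat(sprintf("calls flagged for review (> 1 Mb): %d\n",
            sum(out$review_flag == "LARGE_CALL")))
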