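#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study and write every pipeline input.
#
# Emulates the study design: 116 hypertensive genomes (44 with left
# ventricular hypertrophy = cases, 72 without = controls) typed on a
# desk-scale array (three autosomes + chrX, ~36,000 probes), with three
# imperfect CNV-calling algorithms (95% sensitivity, 10% breakpoint
# jitter, 2 false positives per genome) and reference catalogues carrying
# every planted common polymorphism. The ground-truth ledger is kept for
# the recovery analysis in stage 5.

suppressPackageStartupMessages(library(rarecnv))

seed <- 20160301
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed)
sim <- simulate_study(cfg)

write_samples(sim$cohort, file.path(out, "samples.csv"))
write_manifest(sim$manifest, file.path(out, "manifest.tsv"))
for (a in names(sim$callsets)) {
  write_calls(sim$callsets[[a]], file.path(out, paste0("calls_", a, ".tsv")),
              "tsv")
}
for (r in names(sim$references)) {
  write_reference_set(sim$references[[r]],
                      file.path(out, paste0("ref_", r, ".tsv")))
}

# genome annotation in the formats read_annotation() consumes
ann <- sim$annotation
write.table(ann$chrom_lengths, file.path(out, "chrom_lengths.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
regions <- rbind(cbind(ann$centromeres, name = "centromere"),
                 cbind(ann$telomeres, name = "telomere"))
write.table(regions, file.path(out, "regions.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(ann$gc, file.path(out, "gc_track.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ann$genes, file.path(out, "genes.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

# probe-level QC signals summarized to the per-sample metric table
metrics <- compute_qc_metrics(sim$signals$lrr, sim$signals$baf,
                              sim$signals$called)
write.table(metrics, file.path(out, "qc_metrics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write.table(sim$planted$truth, file.path(out, "truth_ledger.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "")

n_calls <- vapply(sim$callsets, nrow, integer(1))
cat(sprintf("cohort: %d cases + %d controls\n",
            sum(sim$cohort$group == "case"),
            sum(sim$cohort$group == "control")))
cat(sprintf("planted loci: %d (%s)\n", nrow(sim$planted$loci),
            paste(names(table(sim$planted$loci$class)),
                  table(sim$planted$loci$class), sep = "=",
                  collapse = ", ")))
cat(sprintf("emitted calls: %s\n",
            paste(names(n_calls), n_calls, sep = "=", collapse = ", ")))
cat("inputs written under", out, "\n")
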