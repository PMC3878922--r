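#!/usr/bin/env Rscript
# Interval-context statistics for the combined call set: overlap with the
# known-CNV database and its permutation enrichment test (1000 reshuffles
# within chromosomes), segmental-duplication overlap summary, repeat-class
# fractions in and around calls, and gene annotation. Reads
# results/simulated/ and results/cnv_calls/, writes results/enrichment/.

suppressMessages(library(cloneCNV))

sim <- "results/simulated"
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- genome_def(c(chr2 = 110e6, chr19 = 55e6, chrX = 50e6))
cfg <- default_config(seed = 20130863)

calls <- do.call(rbind, lapply(c("clone-3", "clone-6"), function(id)
  read.delim(file.path("results/cnv_calls", paste0(id, "_calls.tsv")))))
query <- interval_set(
  data.frame(chrom = calls$chrom, start = calls$start - 1,
             end = calls$start - 1 + calls$length), genome)

cnv_db <- read_bed(file.path(sim, "track_cnv_db.bed"), genome)
sds <- read_bed(file.path(sim, "track_sd.bed"), genome)
repeats <- read_bed(file.path(sim, "track_repeats.bed"), genome)
genes <- read_bed(file.path(sim, "track_genes.bed"), genome)

ov <- count_overlaps(query, cnv_db)
cat(sprintf("known-CNV overlap: %d of %d calls (%.1f%%)\n",
            ov$count, nrow(query), 100 * ov$count / nrow(query)))
perm <- permutation_overlap_test(query, cnv_db, n_iter = cfg$n_perm,
                                 seed = cfg$seed + 4000)
cat(sprintf("permutation enrichment: observed %d, null mean %.2f, P %s\n",
            perm$observed, mean(perm$null_counts), perm$reported))

sd_sum <- sd_overlap_summary(query, sds)
cat(sprintf("SD overlap: %d calls, %.2f Mb (%.0f%% of total call length)\n",
            sd_sum$n_overlapping, sd_sum$total_overlapped_length / 1e6,
            100 * sd_sum$fraction_of_total_cnv_length))

prof <- repeat_fraction_profile(query, repeats)
write.table(prof, file.path(out, "repeat_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ann <- annotate_genes(query, genes)
calls$genes <- ann
write.table(calls, file.path(out, "calls_annotated.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

summary_df <- data.frame(
  metric = c("n_calls", "known_cnv_overlap", "enrichment_p_reported",
             "sd_overlap_n", "sd_overlap_length_fraction"),
  value = c(nrow(query), ov$count, perm$reported,
            sd_sum$n_overlapping,
            sprintf("%.3f", sd_sum$fraction_of_total_cnv_length)))
write.table(summary_df, file.path(out, "summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
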