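#!/usr/bin/env Rscript
# SNP-array stage: LRR quality control (SD < 0.24), allelic-imbalance
# segmentation of the B-allele track, and copy-neutral LOH detection.
# Reads results/simulated/, writes results/baf_loh/.

suppressMessages(library(cloneCNV))

sim <- "results/simulated"
out <- "results/baf_loh"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (id in c("clone-3", "clone-6")) {
  snps <- read_snp_table(file.path(sim, paste0(id, "_snp.tsv")))
  qc <- qc_lrr(snps, sample_id = id)
  cat(sprintf("%s: LRR SD %.4f -> QC %s\n", id, qc$lrr_sd,
              if (qc$pass) "pass" else "fail"))
  if (!qc$pass) next

  segs <- detect_allelic_imbalance(snps, seed = 1)
  imb <- segs[segs$state == "imbalanced", , drop = FALSE]
  if (nrow(imb)) {
    cat(sprintf("  allelic imbalance: %s:%d-%d, het modes %.3f / %.3f\n",
                imb$chrom, imb$start, imb$end, imb$mode_low, imb$mode_high))
  } else cat("  no allelic imbalance\n")
  write.table(segs, file.path(out, paste0(id, "_baf_segments.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  loh <- detect_cn_loh(snps)
  if (nrow(loh)) {
    cat(sprintf("  copy-neutral LOH: %s:%d-%d (%.1f Mb, %d SNPs, mean LRR %.3f)\n",
                loh$chrom, loh$start, loh$end, (loh$end - loh$start) / 1e6,
                loh$n_snps, loh$mean_lrr))
  } else cat("  no copy-neutral LOH\n")
  write.table(format_report_calls(loh),
              file.path(out, paste0(id, "_loh_calls.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote", out, "\n")
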