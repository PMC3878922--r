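#!/usr/bin/env Rscript
# Multi-point genomic qPCR validation of the CNV calls: simulate triplicate
# Ct assays at points inside and outside each call (true copy number taken
# from the truth events), compute 2^-ddCt fold changes against the donor
# calibrator, and classify each call validated / not_validated /
# indeterminate. Reads results/simulated/ and results/cnv_calls/, writes
# results/qpcr/.

suppressMessages(library(cloneCNV))

sim <- "results/simulated"
out <- "results/qpcr"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- genome_def(c(chr2 = 110e6, chr19 = 55e6, chrX = 50e6))
cfg <- default_config(seed = 20130863)

for (id in c("clone-3", "clone-6")) {
  calls_rep <- read.delim(file.path("results/cnv_calls", paste0(id, "_calls.tsv")))
  truth_iv <- read_bed(file.path(sim, paste0(id, "_truth.bed")), genome)
  truth <- truth_events(truth_iv$chrom, truth_iv$start, truth_iv$end,
                        truth_iv$name, as.integer(truth_iv$class), genome)
  if (nrow(calls_rep) == 0) { cat(id, ": no calls to validate\n"); next }

  rows <- list()
  for (i in seq_len(nrow(calls_rep))) {
    # back to internal coordinates (report: 1-based start, end = start + len)
    call <- data.frame(chrom = calls_rep$chrom[i],
                       start = calls_rep$start[i] - 1,
                       end = calls_rep$start[i] - 1 + calls_rep$length[i],
                       event = calls_rep$event[i])
    width <- call$end - call$start
    inside <- round(seq(call$start + 0.1 * width, call$end - 0.1 * width,
                        length.out = 4))
    outside <- c(max(0, call$start - 2 * width),
                 min(genome_length(genome, call$chrom) - 1, call$end + 2 * width))
    pos <- c(inside, outside)
    cn <- copy_number <- vapply(pos, function(p)
      cloneCNV:::copy_number_at(genome, truth, call$chrom, p), numeric(1))
    folds <- vapply(seq_along(pos), function(k) {
      assay <- simulate_qpcr(max(cn[k], 0.25), ct_noise_sd = cfg$qpcr_ct_noise_sd,
                             seed = cfg$seed + 3000 + 17 * i + k)
      ddct_fold_change(assay)$value
    }, numeric(1))
    assays <- data.frame(position = pos,
                         inside = c(rep(TRUE, 4), rep(FALSE, 2)),
                         fold = folds)
    v <- validate_boundaries(call, assays, cfg$qpcr_gain_thr, cfg$qpcr_loss_thr)
    cat(sprintf("%s %s:%d-%d [%s] -> %s (folds in: %s; out: %s)\n",
                id, call$chrom, call$start, call$end, call$event, v$verdict,
                paste(sprintf("%.2f", folds[1:4]), collapse = " "),
                paste(sprintf("%.2f", folds[5:6]), collapse = " ")))
    rows[[i]] <- cbind(calls_rep[i, c("chrom", "start", "end", "event")],
                       verdict = v$verdict, v$refined)
  }
  write.table(do.call(rbind, rows), file.path(out, paste0(id, "_verdicts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote", out, "\n")
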