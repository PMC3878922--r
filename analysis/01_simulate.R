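#!/usr/bin/env Rscript
# Build the synthetic study cohort: a donor genome, two clones carrying the
# de novo events under investigation (clone-3: a 5.2 Mb gain on X and a
# 338 kb gain on chr19; clone-6: a 36 kb loss and a 37 Mb terminal
# copy-neutral LOH on chr2), plus annotation tracks. Writes probe/SNP
# tables and truth BEDs under results/simulated/.
#
# The two large clone-3 gains reuse the published report-scale coordinates
# of the bundled catalog (converted to internal 0-based half-open); the
# chromosome lengths are synthetic, sized so every event fits.

suppressMessages(library(cloneCNV))

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- genome_def(c(chr2 = 110e6, chr19 = 55e6, chrX = 50e6))
catalog <- clone_cnv_catalog()

as_internal <- function(row) c(start = row$start - 1, end = row$start - 1 + row$length)
x19 <- as_internal(catalog[catalog$chrom == "chr19", ])
xX <- as_internal(catalog[catalog$chrom == "chrX", ])
x2 <- as_internal(catalog[catalog$chrom == "chr2", ])

clones <- list(
  "clone-3" = truth_events(c("chr19", "chrX"),
                           c(x19["start"], xX["start"]),
                           c(x19["end"], xX["end"]),
                           c("gain", "gain"), c(3L, 3L), genome),
  "clone-6" = truth_events(c("chr2", "chr2"),
                           c(x2["start"], 73e6),
                           c(x2["end"], 110e6),
                           c("loss", "cn_loh"), c(1L, NA), genome)
)

cfg <- default_config(seed = 20130863)

for (id in names(clones)) {
  ev <- clones[[id]]
  write_bed(data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                       name = ev$kind, class = ev$copy_number),
            file.path(out, paste0(id, "_truth.bed")))
  probes <- simulate_acgh(genome, ev, cfg$probe_spacing, cfg$acgh_noise_sd,
                          seed = cfg$seed + match(id, names(clones)))
  write_probe_table(probes, file.path(out, paste0(id, "_acgh.tsv")))
  snps <- simulate_snp_array(genome, ev, cfg$snp_spacing, cfg$het_rate,
                             cfg$lrr_noise_sd, cfg$baf_noise_sd,
                             seed = cfg$seed + 100 + match(id, names(clones)))
  write_snp_table(snps, file.path(out, paste0(id, "_snp.tsv")))
  cat(sprintf("%s: %d probes, %d SNPs, %d truth events\n",
              id, nrow(probes), nrow(snps), nrow(ev)))
}

tracks <- simulate_annotation_tracks(genome, seed = cfg$seed + 500)
for (tn in names(tracks))
  write_bed(tracks[[tn]], file.path(out, paste0("track_", tn, ".bed")))
cat("annotation tracks:",
    paste(sprintf("%s=%d", names(tracks), vapply(tracks, nrow, 1L)),
          collapse = ", "), "\n")
cat("wrote", out, "\n")
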