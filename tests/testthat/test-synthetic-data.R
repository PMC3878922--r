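test_that("noise-free aCGH probes reproduce exact segment means", {
  g <- tiny_genome()
  pt <- simulate_acgh(g, gain3_event(g), noise_sd = 0, seed = 1)
  ine <- pt$chrom == "chr1" & pt$pos >= 10e6 & pt$pos < 12e6
  expect_true(all(pt$log2_ratio[ine] == log2(3 / 2)))
  expect_true(all(pt$log2_ratio[!ine] == 0))

  # identity case: no events, all probes exactly zero
  pt0 <- simulate_acgh(g, noise_sd = 0, seed = 1)
  expect_true(all(pt0$log2_ratio == 0))

  # positions strictly increasing within chromosome
  for (ch in unique(pt$chrom))
    expect_false(is.unsorted(pt$pos[pt$chrom == ch], strictly = TRUE))
})

test_that("aCGH generator is seed-deterministic and noise obeys the CLT bound", {
  g <- tiny_genome()
  a <- simulate_acgh(g, gain3_event(g), noise_sd = 0.15, seed = 7)
  b <- simulate_acgh(g, gain3_event(g), noise_sd = 0.15, seed = 7)
  expect_identical(a, b)
  c_ <- simulate_acgh(g, gain3_event(g), noise_sd = 0.15, seed = 8)
  expect_false(identical(a$log2_ratio, c_$log2_ratio))

  # 3-copy gain spanning ~100 probes: sample mean within 3 sd / sqrt(n)
  g2 <- genome_def(c(c1 = 5e6))
  ev <- truth_events("c1", 1e6, 1e6 + 100 * 3300, "gain", 3L, g2)
  pt <- simulate_acgh(g2, ev, probe_spacing = 3300, noise_sd = 0.15, seed = 3)
  ine <- pt$pos >= 1e6 & pt$pos < 1e6 + 100 * 3300
  n <- sum(ine)
  expect_gt(n, 80)
  expect_lt(abs(mean(pt$log2_ratio[ine]) - log2(3 / 2)), 3 * 0.15 / sqrt(n))
})

test_that("events outside chromosome bounds or in conflict are rejected", {
  g <- tiny_genome()
  expect_error(truth_events("chr1", 30e6, 40e6, "gain", 3L, g), "bounds")
  expect_error(truth_events("chrZ", 0, 1e6, "gain", 3L, g), "unknown")
  expect_error(truth_events("chr1", c(1e6, 2e6), c(3e6, 4e6),
                            c("gain", "loss"), c(3L, 1L), g),
               "conflicting")
  # gain not above baseline, loss not below
  expect_error(truth_events("chr1", 1e6, 2e6, "gain", 2L, g), "baseline")
  expect_error(truth_events("chr1", 1e6, 2e6, "loss", 2L, g), "baseline")
})

test_that("dye swap negates the event signal with independent noise", {
  g <- tiny_genome()
  fwd0 <- simulate_acgh(g, gain3_event(g), noise_sd = 0, seed = 1)
  swp0 <- simulate_dye_swap(fwd0, noise_sd = 0, seed = 2)
  ine <- fwd0$chrom == "chr1" & fwd0$pos >= 10e6 & fwd0$pos < 12e6
  expect_true(all(swp0$log2_ratio[ine] == -log2(3 / 2)))
  expect_true(all(swp0$log2_ratio[!ine] == 0))
  expect_identical(fwd0[, c("probe_id", "chrom", "pos")],
                   swp0[, c("probe_id", "chrom", "pos")])

  # no events: both tables all zero
  f0 <- simulate_acgh(g, noise_sd = 0, seed = 1)
  expect_true(all(simulate_dye_swap(f0, noise_sd = 0, seed = 2)$log2_ratio == 0))

  # with noise: the pooled in-event probes carry heterogeneous signal (a
  # gain and a loss), so forward and swap correlate negatively there while
  # neutral probes carry independent noise only
  g2 <- genome_def(c(c1 = 40e6))
  ev <- truth_events(c("c1", "c1"), c(5e6, 25e6), c(15e6, 35e6),
                     c("gain", "loss"), c(3L, 1L), g2)
  fwd <- simulate_acgh(g2, ev, probe_spacing = 3300, noise_sd = 0.15, seed = 4)
  swp <- simulate_dye_swap(fwd, noise_sd = 0.15, seed = 5)
  ine2 <- (fwd$pos >= 5e6 & fwd$pos < 15e6) | (fwd$pos >= 25e6 & fwd$pos < 35e6)
  expect_lt(cor(fwd$log2_ratio[ine2], swp$log2_ratio[ine2]), -0.5)
  expect_lt(abs(cor(fwd$log2_ratio[!ine2], swp$log2_ratio[!ine2])), 0.1)
})

test_that("SNP-array BAF bands sit at allele-dosage ratios", {
  g <- tiny_genome()
  ev <- truth_events("chr1", 5e6, 15e6, "gain", 3L, g)
  sn <- simulate_snp_array(g, ev, het_rate = 0.4, lrr_noise_sd = 0,
                           baf_noise_sd = 0, seed = 2)
  ine <- sn$chrom == "chr1" & sn$pos >= 5e6 & sn$pos < 15e6
  het_in <- ine & sn$baf > 0 & sn$baf < 1
  expect_gt(sum(het_in), 50)
  expect_true(all(sn$baf[het_in] %in% c(1 / 3, 2 / 3)))
  expect_true(all(sn$lrr[ine] == log2(3 / 2)))
  # diploid hets sit exactly at 0.5
  het_out <- !ine & sn$baf > 0 & sn$baf < 1
  expect_true(all(sn$baf[het_out] == 0.5))
  expect_true(all(sn$baf >= 0 & sn$baf <= 1))
})

test_that("copy-neutral LOH removes the het band but keeps LRR neutral", {
  g <- tiny_genome()
  ev <- truth_events("chr1", 8e6, 30e6, "cn_loh", NA, g)
  sn <- simulate_snp_array(g, ev, seed = 3)
  ine <- sn$chrom == "chr1" & sn$pos >= 8e6 & sn$pos < 30e6
  expect_equal(sum(sn$baf[ine] > 0.2 & sn$baf[ine] < 0.8), 0)
  expect_lt(abs(mean(sn$lrr[ine])), 0.02)
  # het_rate 0 genome-wide is a degenerate but legal input
  sn0 <- simulate_snp_array(g, het_rate = 0, seed = 4)
  expect_equal(sum(sn0$baf > 0.2 & sn0$baf < 0.8), 0)
})

test_that("qPCR generator round-trips fold changes in the noise-free limit", {
  folds <- vapply(c(2, 3, 1), function(cn) {
    ddct_fold_change(simulate_qpcr(cn, ct_noise_sd = 0, seed = 1))$value
  }, numeric(1))
  expect_equal(folds, c(1.0, 1.5, 0.5))
})

test_that("annotation tracks are reproducible, in bounds, and empty when asked", {
  g <- tiny_genome()
  tr <- simulate_annotation_tracks(g, seed = 5)
  tr2 <- simulate_annotation_tracks(g, seed = 5)
  expect_identical(tr, tr2)
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(tr$repeats, f1); write_bed(tr2$repeats, f2)
  expect_identical(readLines(f1), readLines(f2))
  for (track in tr) {
    expect_true(all(track$start >= 0))
    expect_true(all(track$end <= genome_length(g, track$chrom)))
  }
  expect_true(all(tr$repeats$class %in% c("LINE", "SINE", "LTR")))
  # n_intervals = 0 gives an empty track and zero downstream overlap
  tr0 <- simulate_annotation_tracks(
    g, n_intervals = list(cnv_db = 0, sd = 0, repeats = 0, genes = 0), seed = 1)
  expect_equal(nrow(tr0$cnv_db), 0)
  q <- interval_set(data.frame(chrom = "chr1", start = 0, end = 1e6), g)
  expect_equal(count_overlaps(q, tr0$cnv_db)$count, 0)
})

test_that("microsatellite panel follows HWE and a copied donor genotype matches", {
  # single allele: every individual homozygous for it
  pan <- simulate_microsat_panel(list(L1 = c(A = 1)), 50, seed = 1)
  expect_true(all(pan$allele1 == "A" & pan$allele2 == "A"))
  # p = (0.5, 0.5): het fraction converges to 0.5
  pan2 <- simulate_microsat_panel(list(L1 = c(a = 0.5, b = 0.5)), 2e4, seed = 2)
  expect_lt(abs(mean(pan2$allele1 != pan2$allele2) - 0.5), 0.015)
  # invalid frequencies rejected
  expect_error(simulate_microsat_panel(list(L1 = c(0.5, 0.6)), 10), "sum")
  expect_error(simulate_microsat_panel(list(L1 = c(-0.1, 1.1)), 10), "negative")
  # clone generated by copying the donor matches at every locus
  freqs <- list(L1 = c(a = .5, b = .5), L2 = c(a = .2, b = .3, c = .5))
  pan3 <- simulate_microsat_panel(freqs, 1, seed = 3)
  donor <- pan3
  clone <- donor
  m <- genotype_match(donor, clone)
  expect_true(m$all_match)
  expect_true(all(m$per_locus$match))
})
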