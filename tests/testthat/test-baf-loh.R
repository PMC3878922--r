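test_that("LRR quality control thresholds dispersion correctly", {
  g <- genome_def(c(chr1 = 20e6))
  sn <- simulate_snp_array(g, lrr_noise_sd = 0, baf_noise_sd = 0, seed = 1)
  expect_true(qc_lrr(sn)$pass)
  expect_equal(qc_lrr(sn)$lrr_sd, 0)

  sn$lrr <- rnorm(nrow(sn), 0, 0.30)
  expect_false(qc_lrr(sn)$pass)
  sn$lrr <- rnorm(nrow(sn), 0, 0.10)
  expect_true(qc_lrr(sn)$pass)

  # too few autosomal SNPs: explicit failure reason
  few <- sn[1:50, ]
  res <- qc_lrr(few)
  expect_false(res$pass)
  expect_match(res$reason, "fewer than 100")
})

test_that("a 3-copy region is reported imbalanced with dosage modes", {
  g <- genome_def(c(chr1 = 30e6))
  ev <- truth_events("chr1", 10e6, 15e6, "gain", 3L, g)
  sn <- simulate_snp_array(g, ev, seed = 2)
  segs <- detect_allelic_imbalance(sn, seed = 3)
  imb <- segs[segs$state == "imbalanced", ]
  expect_equal(nrow(imb), 1)
  expect_lt(abs(imb$mode_low - 1 / 3), 2 * 0.03)
  expect_lt(abs(imb$mode_high - 2 / 3), 2 * 0.03)
  # mirror symmetry of the two modes about 0.5
  expect_lt(abs(imb$mode_low + imb$mode_high - 1), 2 * 0.03)
  # the imbalanced segment coincides with the truth gain
  ov <- min(imb$end, 15e6) - max(imb$start, 10e6)
  expect_gt(ov / 5e6, 0.9)
  expect_gt(ov / (imb$end - imb$start), 0.9)
})

test_that("diploid data yield no imbalanced segment", {
  g <- genome_def(c(chr1 = 30e6))
  sn <- simulate_snp_array(g, seed = 4)
  segs <- detect_allelic_imbalance(sn, seed = 5)
  expect_equal(sum(segs$state == "imbalanced"), 0)
})

test_that("regions too small for the band pattern come back indeterminate", {
  # a 3-copy region of ~3 SNPs at 13 kb spacing cannot be interpreted
  g <- genome_def(c(chr1 = 10e6))
  ev <- truth_events("chr1", 5e6, 5.04e6, "gain", 3L, g)
  sn <- simulate_snp_array(g, ev, seed = 6)
  segs <- detect_allelic_imbalance(sn, seed = 7)
  expect_equal(sum(segs$state == "imbalanced"), 0)
})

test_that("a terminal copy-neutral LOH is recovered as exactly one call", {
  g <- genome_def(c(chr2 = 90e6))
  ev <- truth_events("chr2", 53e6, 90e6, "cn_loh", NA, g)
  sn <- simulate_snp_array(g, ev, seed = 8)
  loh <- detect_cn_loh(sn)
  expect_equal(nrow(loh), 1)
  # the run boundary starts at the first homozygote, which precedes the true
  # boundary by a geometric run-in (~1/het_rate SNPs); allow ~15 SNP spacings
  expect_lt(abs(loh$start - 53e6), 2e5)
  expect_gt(loh$end, 89.9e6)
  expect_lt(abs(loh$mean_lrr), 0.1)
  expect_lt(loh$p_run, 1e-6)
})

test_that("event-free genomes produce zero LOH calls", {
  g <- genome_def(c(chr1 = 50e6, chr2 = 50e6))
  sn <- simulate_snp_array(g, seed = 9)
  expect_equal(nrow(detect_cn_loh(sn)), 0)
})

test_that("deletions are never reported as copy-neutral LOH", {
  # a 1-copy deletion also erases heterozygotes, but its LRR is depressed
  g <- genome_def(c(chr1 = 50e6))
  ev <- truth_events("chr1", 10e6, 20e6, "loss", 1L, g)
  sn <- simulate_snp_array(g, ev, seed = 10)
  loh <- detect_cn_loh(sn)
  in_del <- loh$start < 20e6 & loh$end > 10e6
  expect_equal(sum(in_del), 0)
})

test_that("LOH detection refuses a zero heterozygosity rate", {
  g <- genome_def(c(chr1 = 20e6))
  sn <- simulate_snp_array(g, het_rate = 0, seed = 11)
  expect_error(detect_cn_loh(sn), "undefinable")
})
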