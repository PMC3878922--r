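test_that("a noiseless step is split exactly at the change point", {
  pt <- step_probes(c(rep(0, 500), rep(log2(3 / 2), 500)))
  segs <- rank_segment(pt, cnv_params(), seed = 1)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_probes, c(500L, 500L))
  expect_equal(segs$mean_log2, c(0, log2(3 / 2)))
  # every probe in exactly one segment
  expect_equal(sum(segs$n_probes), nrow(pt))
})

test_that("an embedded noiseless plateau yields exactly three segments", {
  pt <- step_probes(c(rep(0, 400), rep(log2(3 / 2), 80), rep(0, 400)))
  segs <- rank_segment(pt, cnv_params(), seed = 1)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$n_probes[2], 80L)
  expect_equal(segs$mean_log2[2], log2(3 / 2))
})

test_that("probe gaps beyond max_gap force segment breaks regardless of signal", {
  pos <- c(seq(0, by = 1000, length.out = 100),
           seq(2.5e6, by = 1000, length.out = 100))
  pt <- data.frame(chrom = "c1", pos = pos, log2_ratio = rep(0, 200))
  segs <- rank_segment(pt, cnv_params(max_gap = 1e6), seed = 1)
  expect_equal(nrow(segs), 2)
  expect_equal(length(unique(segs$run_id)), 2)
})

test_that("boundary statistic agrees with the Wilcoxon rank-sum oracle", {
  # for a fixed prefix/suffix cut the split z must match wilcox.test's
  # normal-approximation statistic on the same two groups
  set.seed(42)
  x <- c(rnorm(60, 0, 0.15), rnorm(60, 0.585, 0.15))
  n <- length(x)
  r <- rank(x)
  C <- c(0, cumsum(r))
  vfac <- (n + 1)   # no ties in continuous data
  z_pkg <- (sum(r[1:60]) - 60 * (n + 1) / 2) / sqrt(60 * 60 / 12 * vfac)
  wt <- wilcox.test(x[1:60], x[61:120], exact = FALSE, correct = FALSE)
  z_oracle <- qnorm(wt$p.value / 2) * sign(z_pkg)
  expect_equal(abs(z_pkg), abs(z_oracle), tolerance = 1e-8)
})

test_that("calling on negated signal exchanges gains and losses exactly", {
  g <- genome_def(c(c1 = 33e6))
  ev <- truth_events(c("c1", "c1"), c(5e6, 20e6), c(7e6, 21e6),
                     c("gain", "gain"), c(3L, 4L), g)
  pt <- simulate_acgh(g, ev, noise_sd = 0.15, seed = 9)
  calls_fwd <- call_cnvs(rank_segment(pt, cnv_params(), seed = 1))
  neg <- pt
  neg$log2_ratio <- -neg$log2_ratio
  calls_neg <- call_cnvs(rank_segment(neg, cnv_params(), seed = 1))
  expect_equal(calls_fwd$start, calls_neg$start)
  expect_equal(calls_fwd$end, calls_neg$end)
  expect_equal(calls_fwd$event,
               c(gain = "loss", loss = "gain")[calls_neg$event],
               ignore_attr = TRUE)
})

test_that("a chromosome with too few probes becomes one unsegmentable segment", {
  pt <- step_probes(c(0, 1, 0))
  segs <- rank_segment(pt, cnv_params(min_probes = 5), seed = 1)
  expect_equal(nrow(segs), 1)
  expect_true(segs$unsegmentable)
})

test_that("sub-threshold segments are not called", {
  segs <- data.frame(chrom = "c1", start = 0, end = 1e6, n_probes = 100L,
                     mean_log2 = 0.15, split_p = NA, run_id = 1L,
                     unsegmentable = FALSE)
  expect_equal(nrow(call_cnvs(segs, cnv_params())), 0)
  # below min_probes not called either
  segs$mean_log2 <- 0.6; segs$n_probes <- 4L
  expect_equal(nrow(call_cnvs(segs, cnv_params(min_probes = 5))), 0)
})

test_that("event-free noise rarely produces spurious calls", {
  n_clean <- 0
  for (s in 1:10) {
    pt <- simulate_acgh(genome_def(c(c1 = 33e6)), noise_sd = 0.15, seed = s)
    calls <- call_cnvs(rank_segment(pt, cnv_params(), seed = s))
    if (nrow(calls) == 0) n_clean <- n_clean + 1
  }
  expect_gte(n_clean, 9)
})

test_that("embedded events are recovered with tight boundaries", {
  g <- genome_def(c(c1 = 33e6))
  ev <- truth_events(c("c1", "c1"), c(5e6, 20e6),
                     c(5e6 + 25 * 3300, 20e6 + 100 * 3300),
                     c("gain", "gain"), c(3L, 3L), g)
  errs <- c(); recalls <- c()
  for (s in 1:5) {
    pt <- simulate_acgh(g, ev, noise_sd = 0.15, seed = s)
    res <- evaluate_calls(call_cnvs(rank_segment(pt, cnv_params(), seed = s)),
                          ev, pt)
    recalls <- c(recalls, res$recall)
    errs <- c(errs, res$events$start_err_probes, res$events$end_err_probes)
  }
  expect_equal(mean(recalls), 1)
  expect_lte(median(errs, na.rm = TRUE), 2)
})

test_that("dye-swap concordance requires an inverted overlapping call", {
  fwd <- call_cnvs(rank_segment(
    step_probes(c(rep(0, 200), rep(0.585, 100), rep(0, 200))), cnv_params(),
    seed = 1))
  expect_equal(fwd$event, "gain")
  swap_ok <- fwd; swap_ok$event <- "loss"; swap_ok$mean_log2 <- -0.585
  expect_true(dye_swap_concordance(fwd, swap_ok)$dye_swap)
  # same-direction call at the same locus is not concordant
  expect_false(dye_swap_concordance(fwd, fwd)$dye_swap)
  # empty swap set: the experiment ran and showed nothing -> fail, not NA
  expect_false(dye_swap_concordance(fwd, empty_swap <- fwd[0, ])$dye_swap)
  # insufficient reciprocal overlap fails
  swap_off <- swap_ok
  swap_off$start <- swap_off$start + 0.8 * (swap_off$end - swap_off$start)
  expect_false(dye_swap_concordance(fwd, swap_off)$dye_swap)
})
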