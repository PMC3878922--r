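ov_genome <- function() genome_def(c(chr1 = 1e6, chr2 = 1e6))

iv <- function(chrom, start, end, g = ov_genome()) {
  interval_set(data.frame(chrom = chrom, start = start, end = end), g)
}

test_that("overlap counting follows the half-open >=1 bp convention", {
  g <- ov_genome()
  expect_equal(count_overlaps(iv("chr1", 100, 200), iv("chr1", 150, 300))$count, 1)
  # abutting half-open intervals share no base
  expect_equal(count_overlaps(iv("chr1", 100, 200), iv("chr1", 200, 300))$count, 0)
  # a query interval counts once no matter how many db entries it hits
  db <- iv("chr1", c(100, 120, 140), c(110, 130, 150))
  expect_equal(count_overlaps(iv("chr1", 0, 1000), db)$count, 1)
  # counting is per query interval, not symmetric
  expect_equal(count_overlaps(db, iv("chr1", 0, 1000))$count, 3)
  # mismatched genomes are rejected
  g2 <- genome_def(c(chrA = 1e6))
  expect_error(count_overlaps(iv("chr1", 0, 10),
                              interval_set(data.frame(chrom = "chrA", start = 0,
                                                      end = 10), g2)),
               "different genomes")
})

test_that("min_bp raises the overlap requirement", {
  q <- iv("chr1", 100, 200)
  db <- iv("chr1", 195, 300)    # 5 bp of overlap
  expect_equal(count_overlaps(q, db, min_bp = 5)$count, 1)
  expect_equal(count_overlaps(q, db, min_bp = 6)$count, 0)
})

test_that("permutation preserves per-chromosome counts and lengths exactly", {
  g <- genome_def(c(chr1 = 1e6, chr2 = 5e5))
  q <- interval_set(data.frame(chrom = c("chr1", "chr1", "chr2"),
                               start = c(0, 5e5, 100),
                               end = c(1e4, 6e5, 5e3)), g)
  for (s in 1:20) {
    p <- permute_intervals(q, seed = s)
    expect_identical(p$chrom, q$chrom)
    expect_identical(p$end - p$start, q$end - q$start)
    expect_true(all(p$start >= 0 & p$end <= genome_length(g, p$chrom)))
  }
  # an interval as long as its chromosome has a forced placement
  full <- interval_set(data.frame(chrom = "chr2", start = 0, end = 5e5), g)
  expect_identical(permute_intervals(full, seed = 1)$start, 0)
  too_big <- data.frame(chrom = "chr2", start = 0, end = 6e5)
  expect_error(interval_set(too_big, g), "bounds")
})

test_that("permuted starts are uniform on the admissible range", {
  g <- genome_def(c(chr1 = 1e6))
  q <- iv("chr1", 0, 1000, g)
  set.seed(99)
  starts <- replicate(5000, cloneCNV:::permute_intervals_norng(q)$start)
  ks <- suppressWarnings(ks.test(starts, "punif", 0, 999000))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation p-values use strict inequality and the reporting floor", {
  g <- ov_genome()
  # db covering the whole genome: every permutation ties, none is greater
  db_all <- iv(c("chr1", "chr2"), c(0, 0), c(1e6, 1e6))
  q <- iv("chr1", c(1000, 5000), c(2000, 9000))
  res <- permutation_overlap_test(q, db_all, n_iter = 1000, seed = 1)
  expect_equal(res$p_value, 0)
  expect_equal(res$reported, "< 0.001")
  # empty query is an explicit error
  expect_error(permutation_overlap_test(iv(character(), numeric(), numeric()),
                                        db_all, 10, 1),
               "empty query")
})

test_that("the fast permutation counter agrees with the general one", {
  g <- genome_def(c(chr1 = 2e5, chr2 = 3e5))
  set.seed(7)
  rnd <- function(n, g) {
    chrom <- sample(g$chrom, n, replace = TRUE)
    len <- sample.int(2e4, n)
    maxs <- genome_length(g, chrom) - len
    start <- floor(runif(n) * maxs)
    interval_set(data.frame(chrom = chrom, start = start, end = start + len), g)
  }
  db <- rnd(40, g)
  merged <- cloneCNV:::merged_db_index(db, g)
  for (i in 1:25) {
    q <- rnd(15, g)
    expect_equal(cloneCNV:::fast_overlap_count(q, merged),
                 count_overlaps(q, db)$count)
  }
})

test_that("segmental duplication overlap summary counts and lengths add up", {
  g <- ov_genome()
  cnvs <- iv("chr1", c(0, 2e5, 4e5), c(1e5, 3e5, 5e5))
  expect_equal(sd_overlap_summary(cnvs, iv("chr2", 0, 1e5))$n_overlapping, 0)
  res <- sd_overlap_summary(cnvs, iv("chr1", 0, 6e5))
  expect_equal(res$n_overlapping, 3)
  expect_equal(res$fraction_of_total_cnv_length, 1.0)
  res2 <- sd_overlap_summary(cnvs, iv("chr1", 50, 100))
  expect_equal(res2$n_overlapping, 1)
  expect_equal(res2$total_overlapped_length, 1e5)
})

test_that("repeat fractions are exact on engineered coverage", {
  g <- ov_genome()
  cnvs <- iv("chr1", 2e5, 3e5)
  reps <- interval_set(data.frame(chrom = "chr1", start = c(2e5, 0),
                                  end = c(3e5, 1e3),
                                  class = c("LINE", "SINE")), g)
  prof <- repeat_fraction_profile(cnvs, reps, flank_offsets = c(1e4))
  intra_line <- prof$fraction[prof$region == "intraCNV" & prof$class == "LINE"]
  expect_equal(intra_line, 1.0)
  intra_sine <- prof$fraction[prof$region == "intraCNV" & prof$class == "SINE"]
  expect_equal(intra_sine, 0.0)
  expect_true(all(prof$fraction >= 0 & prof$fraction <= 1))
  # flank region excludes the CNV itself
  fl <- prof[prof$region == "flank@10000", ]
  expect_true(all(fl$region_bp == 2e4))
})

test_that("flank windows are disjoint annuli clipped at chromosome ends", {
  g <- ov_genome()
  cnvs <- iv("chr1", 0, 1e5)   # terminal CNV: left flank fully clipped
  reps <- interval_set(data.frame(chrom = "chr1", start = 1e5, end = 1.1e5,
                                  class = "LINE"), g)
  prof <- repeat_fraction_profile(cnvs, reps, flank_offsets = c(1e4, 1e5))
  r1 <- prof[prof$region == "flank@10000", ]
  r2 <- prof[prof$region == "flank@100000", ]
  expect_equal(unique(r1$region_bp), 1e4)          # right side only
  expect_equal(unique(r2$region_bp), 9e4)          # annulus 10-100 kb
  expect_equal(r1$fraction[r1$class == "LINE"], 1.0)
  expect_equal(r2$fraction[r2$class == "LINE"], 0.0)
})

test_that("gene annotation lists names by start and uses the >=1 bp rule", {
  g <- ov_genome()
  cnvs <- iv("chr1", c(0, 5e5), c(1e5, 6e5))
  genes <- interval_set(data.frame(chrom = "chr1",
                                   start = c(5e4, 2e4, 99999),
                                   end = c(6e4, 3e4, 2e5),
                                   name = c("B", "A", "C")), g)
  ann <- annotate_genes(cnvs, genes)
  expect_equal(ann[1], "A,B,C")   # boundary-spanning gene C still listed
  expect_equal(ann[2], "-")
})
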