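#' SNP-array sample quality control on LRR dispersion
#'
#' A sample passes QC if the standard deviation of its autosomal log R
#' ratios is below `sd_threshold` (default 0.24). Sex chromosomes (names
#' containing "X"/"Y") are excluded because hemizygosity shifts their LRR.
#'
#' @param snps a `snp_table`.
#' @param sd_threshold maximum acceptable autosomal LRR SD.
#' @param sample_id label carried into the result.
#' @return list of class `qc_result`: `sample_id`, `lrr_sd`, `pass`,
#'   `reason` (NA when evaluable).
#' @export
qc_lrr <- function(snps, sd_threshold = 0.24, sample_id = "sample") {
  auto <- !grepl("[XY]$", snps$chrom, ignore.case = TRUE)
  if (sum(auto) < 100) {
    return(structure(list(sample_id = sample_id, lrr_sd = NA_real_,
                          pass = FALSE,
                          reason = "fewer than 100 autosomal SNPs"),
                     class = "qc_result"))
  }
  s <- stats::sd(snps$lrr[auto])
  structure(list(sample_id = sample_id, lrr_sd = s, pass = s < sd_threshold,
                 reason = NA_character_),
            class = "qc_result")
}

het_mask <- function(baf, band = c(0.2, 0.8)) {
  baf > band[1] & baf < band[2]
}

#' Detect allelic imbalance from the B-allele frequency track
#'
#' Heterozygous SNPs (BAF within the het band, default (0.2, 0.8)) are
#' segmented on their mirrored BAF `|BAF - 0.5|` with the same rank
#' segmentation engine used for aCGH log2 ratios. A segment spanning at
#' least `min_window` whose het BAFs form two clusters at `0.5 +/- d` with
#' `d >= mode_delta` is reported `imbalanced` — the pattern a 3-copy gain
#' produces, with het clusters at 1/3 and 2/3. Segments with fewer than 10
#' het SNPs are `indeterminate` (too small to read a band pattern);
#' everything else is `balanced`.
#'
#' @param snps a `snp_table` (sample should have passed [qc_lrr()]).
#' @param min_window minimum segment span in bp to report imbalance
#'   (default 360000, a conservative window for 13 kb SNP spacing).
#' @param het_band BAF limits defining heterozygotes.
#' @param mode_delta minimum half-separation of the two het modes.
#' @param params segmentation parameters; default [cnv_params()] with the
#'   aCGH gap rule retained.
#' @param seed passed to the segmentation engine.
#' @return data.frame of class `baf_segments`: `chrom`, `start`, `end`,
#'   `n_het_snps`, `mode_low`, `mode_high`, `mean_lrr`, `state` in
#'   {balanced, imbalanced, indeterminate}.
#' @export
detect_allelic_imbalance <- function(snps, min_window = 360000,
                                     het_band = c(0.2, 0.8), mode_delta = 0.08,
                                     params = cnv_params(), seed = 1L) {
  het <- het_mask(snps$baf, het_band)
  hs <- snps[het, , drop = FALSE]
  out <- list()
  if (nrow(hs)) {
    mir <- data.frame(chrom = hs$chrom, pos = hs$pos,
                      log2_ratio = abs(hs$baf - 0.5),
                      stringsAsFactors = FALSE)
    segs <- rank_segment(mir, params, seed = seed)
    for (i in seq_len(nrow(segs))) {
      sel <- hs$chrom == segs$chrom[i] & hs$pos >= segs$start[i] &
        hs$pos < segs$end[i]
      bafs <- hs$baf[sel]
      n_het <- sum(sel)
      allsel <- snps$chrom == segs$chrom[i] & snps$pos >= segs$start[i] &
        snps$pos < segs$end[i]
      mlrr <- mean(snps$lrr[allsel])
      lowers <- bafs[bafs < 0.5]
      uppers <- bafs[bafs >= 0.5]
      mode_low <- if (length(lowers)) mean(lowers) else NA_real_
      mode_high <- if (length(uppers)) mean(uppers) else NA_real_
      d <- if (is.na(mode_low) || is.na(mode_high)) 0 else (mode_high - mode_low) / 2
      span <- segs$end[i] - segs$start[i]
      state <- if (n_het < 10) "indeterminate"
      else if (span >= min_window && d >= mode_delta) "imbalanced"
      else "balanced"
      out[[length(out) + 1L]] <- data.frame(
        chrom = segs$chrom[i], start = segs$start[i], end = segs$end[i],
        n_het_snps = n_het, mode_low = mode_low, mode_high = mode_high,
        mean_lrr = mlrr, state = state, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_het_snps = integer(), mode_low = numeric(),
               mode_high = numeric(), mean_lrr = numeric(),
               state = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("baf_segments", "data.frame")
  res
}

#' Detect copy-neutral loss of heterozygosity
#'
#' Scans each chromosome for maximal runs of consecutive SNPs with no
#' heterozygous call (BAF outside the het band). A run is reported as
#' copy-neutral LOH when it spans at least `min_window`, the probability of
#' observing zero heterozygotes in that many SNPs at the genome-wide het
#' rate falls below `p_threshold`, and the mean LRR across the run stays
#' within `lrr_neutral` of zero — the copy-neutrality gate that keeps
#' deletions (which also erase heterozygotes but depress LRR) out.
#'
#' @param snps a `snp_table` (QC-passed).
#' @param min_window minimum run span in bp (default 360000).
#' @param expected_het_rate per-SNP heterozygosity rate; default estimated
#'   as the genome-wide fraction of het SNPs.
#' @param lrr_neutral maximum |mean LRR| for copy neutrality (default 0.1).
#' @param het_band BAF limits defining heterozygotes.
#' @param p_threshold maximum run probability `(1 - het_rate)^n` (default
#'   1e-6).
#' @return data.frame of class `loh_calls`: `chrom`, `start`, `end`,
#'   `n_snps`, `p_run`, `mean_lrr`.
#' @export
detect_cn_loh <- function(snps, min_window = 360000,
                          expected_het_rate = NULL, lrr_neutral = 0.1,
                          het_band = c(0.2, 0.8), p_threshold = 1e-6) {
  het <- het_mask(snps$baf, het_band)
  if (is.null(expected_het_rate)) expected_het_rate <- mean(het)
  if (expected_het_rate <= 0)
    stop("genome-wide heterozygosity rate is zero; LOH is undefinable")
  out <- list()
  for (chrom in unique(snps$chrom)) {
    sel <- snps$chrom == chrom
    pos <- snps$pos[sel]; h <- het[sel]; lrr <- snps$lrr[sel]
    r <- rle(!h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      n_run <- i1 - i0 + 1L
      span <- pos[i1] - pos[i0] + 1
      p_run <- (1 - expected_het_rate)^n_run
      mlrr <- mean(lrr[i0:i1])
      if (span >= min_window && p_run < p_threshold && abs(mlrr) <= lrr_neutral) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = pos[i0], end = pos[i1] + 1,
          n_snps = n_run, p_run = p_run, mean_lrr = mlrr,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_snps = integer(), p_run = numeric(), mean_lrr = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("loh_calls", "data.frame")
  res
}
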