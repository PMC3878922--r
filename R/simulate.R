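#' Simulate a two-channel aCGH probe table for a clone vs its donor
#'
#' Places probes at jittered regular spacing along each chromosome and draws
#' per-probe log2(test/reference) ratios around the local segment mean
#' `log2(c_clone / c_donor)`, where the donor sits at the genome baseline and
#' the clone carries the supplied truth events. Copy-neutral LOH events do
#' not move the aCGH signal.
#'
#' A homozygous deletion (clone copy 0) has no finite log ratio; its signal
#' saturates at -3 on the log2 scale, as observed ratios do on real arrays.
#'
#' @param genome a [genome_def()].
#' @param events truth event table ([truth_events()]); may be empty.
#' @param probe_spacing mean probe spacing in bp (default 3300, the spacing
#'   of a ~720K custom canine whole-genome design).
#' @param noise_sd Gaussian probe noise SD in log2 units (default 0.15).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return data.frame of class `probe_table` with columns `probe_id`,
#'   `chrom`, `pos`, `log2_ratio`, positions strictly increasing per
#'   chromosome. The genome and events travel along as attributes.
#' @export
simulate_acgh <- function(genome, events = empty_events(), probe_spacing = 3300,
                          noise_sd = 0.15, seed = 1L) {
  stopifnot(probe_spacing > 0, noise_sd >= 0)
  events <- validate_events(events, genome)
  set.seed(as.integer(seed))
  tabs <- lapply(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    pos <- grid_positions(genome$length[i], probe_spacing)
    data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab$probe_id <- sprintf("P%06d", seq_len(nrow(tab)))
  mu <- expected_log2(genome, events, tab$chrom, tab$pos)
  tab$log2_ratio <- mu + if (noise_sd > 0) stats::rnorm(nrow(tab), 0, noise_sd) else 0
  tab <- tab[, c("probe_id", "chrom", "pos", "log2_ratio")]
  rownames(tab) <- NULL
  structure(tab, class = c("probe_table", "data.frame"),
            genome = genome, events = events, probe_spacing = probe_spacing)
}

# jittered regular grid, strictly increasing, integer bp
grid_positions <- function(chrom_len, spacing) {
  n <- max(1L, floor(chrom_len / spacing))
  centre <- (seq_len(n) - 0.5) * spacing
  jit <- stats::runif(n, -0.25, 0.25) * spacing
  pos <- round(centre + jit)
  pmin(pmax(pos, 0), chrom_len - 1)
}

# expected log2(test/reference) at positions, donor at baseline
expected_log2 <- function(genome, events, chrom, pos) {
  cn <- copy_number_at(genome, events, chrom, pos)
  base <- genome_baseline(genome, chrom)
  mu <- ifelse(cn > 0, log2(cn / base), -3)
  pmax(mu, -3)
}

#' Simulate the dye-swap replicate of a forward hybridisation
#'
#' In a dye-swap the fluorophores of test and reference are exchanged, so a
#' true copy-number signal inverts its sign while noise is drawn afresh: the
#' swap is a new hybridisation, not the arithmetic negation of the forward
#' noise realisation.
#'
#' @param forward a `probe_table` from [simulate_acgh()].
#' @param events truth events; defaults to those stored on `forward`.
#' @param noise_sd log2 noise SD for the new hybridisation.
#' @param seed integer seed (use a different seed than the forward array).
#' @return a `probe_table` over the identical probe set with negated expected
#'   signal plus independent noise.
#' @export
simulate_dye_swap <- function(forward, events = attr(forward, "events"),
                              noise_sd = 0.15, seed = 2L) {
  genome <- attr(forward, "genome")
  if (is.null(genome)) stop("forward table carries no genome attribute")
  events <- validate_events(events, genome)
  stopifnot(noise_sd >= 0)
  set.seed(as.integer(seed))
  mu <- -expected_log2(genome, events, forward$chrom, forward$pos)
  swap <- forward
  swap$log2_ratio <- mu + if (noise_sd > 0) stats::rnorm(nrow(forward), 0, noise_sd) else 0
  structure(swap, class = c("probe_table", "data.frame"),
            genome = genome, events = events,
            probe_spacing = attr(forward, "probe_spacing"))
}

#' Simulate a SNP-array LRR/BAF track for a clone
#'
#' Emulates the two per-SNP summaries of an Illumina-style genotyping array:
#' the log R ratio (LRR, total intensity, centred at `log2(c/2)`) and the B
#' allele frequency (BAF, centred at `b/c` for `b` copies of the B allele out
#' of `c` total). Heterozygous SNPs occur at `het_rate` outside copy-neutral
#' LOH events and never inside them; in a 3-copy gain the heterozygous band
#' splits into clusters at 1/3 and 2/3. LRR inside cn-LOH stays at 0 (copy
#' neutrality). BAF noise is Gaussian, truncated to [0, 1].
#'
#' @param genome a [genome_def()].
#' @param events truth event table.
#' @param snp_spacing mean SNP spacing bp (default 13000, a 170K-class array).
#' @param het_rate per-SNP heterozygosity probability (default 0.30).
#' @param lrr_noise_sd,baf_noise_sd Gaussian noise SDs (defaults 0.15, 0.03).
#' @param seed integer seed.
#' @return data.frame of class `snp_table` with columns `snp_id`, `chrom`,
#'   `pos`, `lrr`, `baf`; genome and events as attributes.
#' @export
simulate_snp_array <- function(genome, events = empty_events(),
                               snp_spacing = 13000, het_rate = 0.30,
                               lrr_noise_sd = 0.15, baf_noise_sd = 0.03,
                               seed = 1L) {
  stopifnot(het_rate >= 0, het_rate <= 1, snp_spacing > 0,
            lrr_noise_sd >= 0, baf_noise_sd >= 0)
  events <- validate_events(events, genome)
  set.seed(as.integer(seed))
  tabs <- lapply(seq_len(nrow(genome)), function(i) {
    data.frame(chrom = genome$chrom[i],
               pos = grid_positions(genome$length[i], snp_spacing),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  n <- nrow(tab)
  tab$snp_id <- sprintf("S%06d", seq_len(n))
  cn <- copy_number_at(genome, events, tab$chrom, tab$pos)
  base <- genome_baseline(genome, tab$chrom)
  inloh <- in_loh_at(events, tab$chrom, tab$pos)

  het <- stats::runif(n) < het_rate
  het[inloh] <- FALSE
  het[cn <= 1] <- FALSE        # a single copy cannot be heterozygous

  # B-allele dosage: het -> b uniform in 1..c-1; hom -> 0 or c with equal prob
  b <- integer(n)
  hom_b_is_c <- stats::runif(n) < 0.5
  b[!het & hom_b_is_c] <- cn[!het & hom_b_is_c]
  if (any(het)) {
    b[het] <- vapply(cn[het], function(c) sample.int(c - 1L, 1L), integer(1))
  }
  baf0 <- ifelse(cn > 0, b / cn, 0.5)

  lrr0 <- ifelse(inloh, 0, ifelse(cn > 0, log2(cn / base), -3))
  tab$lrr <- lrr0 + if (lrr_noise_sd > 0) stats::rnorm(n, 0, lrr_noise_sd) else 0
  baf <- baf0 + if (baf_noise_sd > 0) stats::rnorm(n, 0, baf_noise_sd) else 0
  tab$baf <- pmin(pmax(baf, 0), 1)
  tab <- tab[, c("snp_id", "chrom", "pos", "lrr", "baf")]
  rownames(tab) <- NULL
  structure(tab, class = c("snp_table", "data.frame"),
            genome = genome, events = events, het_rate = het_rate)
}

#' Simulate triplicate qPCR threshold cycles for a target locus
#'
#' Generates replicate Ct values for the four well groups of a relative
#' copy-number assay: sample/calibrator x target/control locus. With ideal
#' amplification efficiency (2 by default) the sample target comes up
#' `log2(copy_number / baseline_copy)` cycles earlier than the calibrator
#' target; the control locus is diploid in both DNAs.
#'
#' @param copy_number clone copy number at the target (need not be integer).
#' @param baseline_copy calibrator (donor) copy number at the target,
#'   default 2.
#' @param ct_reference nominal threshold cycle of the assays (default 25).
#' @param replicates wells per group (default 3, i.e. triplicate).
#' @param ct_noise_sd per-well Ct noise SD in cycles (default 0.1).
#' @param efficiency amplification efficiency per cycle (default 2).
#' @param seed integer seed.
#' @return data.frame of class `qpcr_assay` with columns `group` (one of
#'   `sample_target`, `sample_control`, `calibrator_target`,
#'   `calibrator_control`), `replicate`, `ct`.
#' @export
simulate_qpcr <- function(copy_number, baseline_copy = 2L, ct_reference = 25,
                          replicates = 3L, ct_noise_sd = 0.1,
                          efficiency = 2, seed = 1L) {
  stopifnot(copy_number > 0, baseline_copy >= 1, replicates >= 1,
            ct_noise_sd >= 0, efficiency > 1)
  set.seed(as.integer(seed))
  shift <- log(copy_number / baseline_copy, base = efficiency)
  mu <- c(sample_target = ct_reference - shift,
          sample_control = ct_reference,
          calibrator_target = ct_reference,
          calibrator_control = ct_reference)
  tab <- data.frame(
    group = rep(names(mu), each = replicates),
    replicate = rep(seq_len(replicates), times = 4),
    ct = rep(unname(mu), each = replicates) +
      if (ct_noise_sd > 0) stats::rnorm(4 * replicates, 0, ct_noise_sd) else 0,
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("qpcr_assay", "data.frame"))
}

#' Simulate annotation tracks: known-CNV database, SDs, repeats, genes
#'
#' Draws interval tracks with realistic size ranges on the given genome:
#' a known-CNV database (the published CNV regions a new call set is compared
#' against), segmental duplications, class-labelled retroelements (LINE /
#' SINE / LTR) and named genes. Interval starts are uniform within each
#' chromosome (chromosome chosen proportional to its length); intervals may
#' overlap each other, as real track entries do.
#'
#' @param genome a [genome_def()].
#' @param n_intervals named list of track sizes; defaults
#'   `list(cnv_db = 100, sd = 60, repeats = 600, genes = 150)`.
#' @param size_dist named list of `c(min, max)` bp size ranges per track
#'   (log-uniform draw); defaults span 10-500 kb CNVs, 10-200 kb SDs,
#'   0.2-6 kb repeats, 5-100 kb genes.
#' @param density_cap reject if a track's requested total length would
#'   exceed this fraction of the genome (default 0.5).
#' @param seed integer seed; fixed seed gives identical tracks.
#' @return named list of `interval_set` data.frames (`cnv_db`, `sd`,
#'   `repeats`, `genes`); `repeats` carries a `class` column, `genes` a
#'   `name` column.
#' @export
simulate_annotation_tracks <- function(genome,
                                       n_intervals = list(cnv_db = 100, sd = 60,
                                                          repeats = 600, genes = 150),
                                       size_dist = list(cnv_db = c(1e4, 5e5),
                                                        sd = c(1e4, 2e5),
                                                        repeats = c(200, 6e3),
                                                        genes = c(5e3, 1e5)),
                                       density_cap = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  draw <- function(n, range, classes = NULL, prefix = "iv") {
    n <- as.integer(n)
    if (n == 0) {
      out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                        name = character(), stringsAsFactors = FALSE)
      if (!is.null(classes)) out$class <- character()
      return(interval_set(out, genome))
    }
    stopifnot(range[1] > 0, range[2] <= max(genome$length))
    sizes <- round(exp(stats::runif(n, log(range[1]), log(range[2]))))
    if (sum(sizes) > density_cap * sum(genome$length))
      stop("requested track density exceeds the configured cap")
    # chromosome proportional to length, among chromosomes that can hold the interval
    chrom <- character(n); start <- numeric(n)
    for (i in seq_len(n)) {
      ok <- genome$length >= sizes[i]
      if (!any(ok)) stop("interval larger than every chromosome")
      ci <- sample.int(sum(ok), 1L, prob = genome$length[ok])
      ci <- which(ok)[ci]
      chrom[i] <- genome$chrom[ci]
      start[i] <- floor(stats::runif(1, 0, genome$length[ci] - sizes[i] + 1))
    }
    out <- data.frame(chrom = chrom, start = start, end = start + sizes,
                      name = sprintf("%s%04d", prefix, seq_len(n)),
                      stringsAsFactors = FALSE)
    if (!is.null(classes))
      out$class <- sample(classes, n, replace = TRUE)
    out <- out[order(match(out$chrom, genome$chrom), out$start), , drop = FALSE]
    rownames(out) <- NULL
    interval_set(out, genome)
  }
  list(
    cnv_db  = draw(n_intervals$cnv_db, size_dist$cnv_db, prefix = "kcnv"),
    sd      = draw(n_intervals$sd, size_dist$sd, prefix = "sd"),
    repeats = draw(n_intervals$repeats, size_dist$repeats,
                   classes = c("LINE", "SINE", "LTR"), prefix = "rep"),
    genes   = draw(n_intervals$genes, size_dist$genes, prefix = "gene")
  )
}

#' Simulate a microsatellite genotype panel under Hardy-Weinberg equilibrium
#'
#' Draws unordered diploid genotypes independently per locus and individual,
#' with both alleles sampled from the locus allele-frequency vector (HWE).
#'
#' @param allele_freqs named list; each element a numeric allele-frequency
#'   vector summing to 1 (named or unnamed alleles).
#' @param n_individuals number of individuals.
#' @param seed integer seed.
#' @return data.frame with columns `individual`, `locus`, `allele1`,
#'   `allele2` (allele labels as character).
#' @export
simulate_microsat_panel <- function(allele_freqs, n_individuals, seed = 1L) {
  stopifnot(length(allele_freqs) >= 1, n_individuals >= 1)
  for (nm in names(allele_freqs)) check_freqs(allele_freqs[[nm]], nm)
  set.seed(as.integer(seed))
  rows <- lapply(names(allele_freqs), function(nm) {
    p <- allele_freqs[[nm]]
    alleles <- if (is.null(names(p))) as.character(seq_along(p)) else names(p)
    a1 <- sample(alleles, n_individuals, replace = TRUE, prob = p)
    a2 <- sample(alleles, n_individuals, replace = TRUE, prob = p)
    data.frame(individual = sprintf("ind%04d", seq_len(n_individuals)),
               locus = nm, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_freqs <- function(p, name = "locus") {
  if (any(p < 0)) stop("negative allele frequency at ", name)
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies at ", name, " do not sum to 1")
  invisible(p)
}
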