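#' Construct an interval set bound to a genome
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `class`.
#' @param genome the [genome_def()] the intervals live on.
#' @return the data.frame with class `interval_set` and the genome attached.
#' @export
interval_set <- function(df, genome) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df)) {
    unknown <- setdiff(df$chrom, genome$chrom)
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(df$start >= df$end)) stop("interval start must be < end")
    lens <- genome_length(genome, df$chrom)
    if (any(df$start < 0) || any(df$end > lens))
      stop("interval outside chromosome bounds")
  }
  structure(as.data.frame(df), class = c("interval_set", "data.frame"),
            genome = genome)
}

iv_genome <- function(x) attr(x, "genome")

check_same_genome <- function(a, b) {
  if (!same_genome(iv_genome(a), iv_genome(b)))
    stop("interval sets are defined on different genomes")
}

as_granges <- function(iv) {
  g <- iv_genome(iv)
  sl <- stats::setNames(g$length, g$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(iv$chrom, levels = g$chrom),
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end),
    seqlengths = sl
  )
}

#' Count query intervals overlapping a database
#'
#' Counts how many query intervals share at least `min_bp` bases with any
#' database interval; a query interval counts once no matter how many
#' database entries it hits. Coordinates are half-open, so abutting
#' intervals do not overlap.
#'
#' @param query,db `interval_set`s on the same genome.
#' @param min_bp minimum shared bases (default 1: any positive overlap).
#' @return list: `count`, and `hits` — `query` with a logical `overlaps_db`
#'   column.
#' @export
count_overlaps <- function(query, db, min_bp = 1L) {
  check_same_genome(query, db)
  if (nrow(query) == 0) return(list(count = 0L, hits = query))
  hit <- if (nrow(db) == 0) rep(FALSE, nrow(query)) else
    IRanges::overlapsAny(as_granges(query), as_granges(db),
                         minoverlap = as.integer(min_bp))
  ann <- query
  ann$overlaps_db <- hit
  list(count = sum(hit), hits = ann)
}

#' Reshuffle intervals uniformly within their own chromosomes
#'
#' Each interval is independently relocated to a uniform random start on the
#' same chromosome, preserving its length; per-chromosome interval counts
#' and sizes are therefore invariant. Permuted intervals may overlap each
#' other and the original positions — the exact uniform null.
#'
#' @param query an `interval_set`.
#' @param seed integer seed.
#' @return a permuted `interval_set` on the same genome.
#' @export
permute_intervals <- function(query, seed = 1L) {
  set.seed(as.integer(seed))
  permute_intervals_norng(query)
}

# uses the current RNG stream (callers that loop seed once, outside)
permute_intervals_norng <- function(query) {
  g <- iv_genome(query)
  len <- query$end - query$start
  chrom_len <- genome_length(g, query$chrom)
  if (any(len > chrom_len)) stop("interval longer than its chromosome")
  # uniform integer start in [0, chrom_len - len]
  new_start <- floor(stats::runif(nrow(query)) * (chrom_len - len + 1))
  new_start <- pmin(new_start, chrom_len - len)   # guard the runif(1.0) edge
  out <- query
  out$start <- new_start
  out$end <- new_start + len
  out
}

#' Permutation test for interval overlap enrichment
#'
#' Tests whether a call set overlaps a database more than expected by
#' chance: the observed count of overlapping query intervals (>=1 bp rule)
#' is compared with `n_iter` random reshuffles that keep each interval on
#' its own chromosome with its length intact. The p-value is the fraction
#' of permutations whose overlap count is strictly greater than the
#' observed one; when no permutation exceeds it the result is reported as
#' "< 1/n_iter".
#'
#' @param query,db `interval_set`s on the same genome.
#' @param n_iter number of permutations (default 1000).
#' @param seed integer seed.
#' @param min_bp minimum shared bases for an overlap (default 1).
#' @return list of class `permutation_result`: `observed`, `n_iter`,
#'   `n_greater`, `p_value`, `reported` (formatted string), `null_counts`.
#' @export
permutation_overlap_test <- function(query, db, n_iter = 1000L, seed = 1L,
                                     min_bp = 1L) {
  check_same_genome(query, db)
  if (nrow(query) == 0) stop("empty query set: p-value undefined")
  stopifnot(n_iter >= 1)
  observed <- count_overlaps(query, db, min_bp)$count
  g <- iv_genome(query)
  use_fast <- min_bp == 1L && nrow(db) > 0
  if (use_fast) {
    merged <- merged_db_index(db, g)
    counter <- function(iv) fast_overlap_count(iv, merged)
  } else {
    counter <- function(iv) count_overlaps(iv, db, min_bp)$count
  }
  set.seed(as.integer(seed))
  null_counts <- integer(n_iter)
  for (b in seq_len(n_iter)) {
    null_counts[b] <- counter(permute_intervals_norng(query))
  }
  n_greater <- sum(null_counts > observed)
  p <- n_greater / n_iter
  reported <- if (n_greater == 0) sprintf("< %g", 1 / n_iter) else
    sprintf("%g", p)
  structure(list(observed = observed, n_iter = as.integer(n_iter),
                 n_greater = n_greater, p_value = p, reported = reported,
                 null_counts = null_counts),
            class = "permutation_result")
}

# merged (disjoint, sorted) db intervals per chromosome, for O(log n) lookup
merged_db_index <- function(db, genome) {
  idx <- list()
  for (chrom in unique(db$chrom)) {
    d <- db[db$chrom == chrom, , drop = FALSE]
    o <- order(d$start)
    s <- d$start[o]; e <- d$end[o]
    ms <- numeric(0); me <- numeric(0)
    cs <- s[1]; ce <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] <= ce) ce <- max(ce, e[i])
      else { ms <- c(ms, cs); me <- c(me, ce); cs <- s[i]; ce <- e[i] }
    }
    idx[[chrom]] <- list(start = c(ms, cs), end = c(me, ce))
  }
  idx
}

fast_overlap_count <- function(iv, merged) {
  n <- 0L
  for (chrom in unique(iv$chrom)) {
    m <- merged[[chrom]]
    sel <- iv$chrom == chrom
    if (is.null(m)) next
    s <- iv$start[sel]; e <- iv$end[sel]
    k <- findInterval(s, m$start)
    hit <- (k >= 1 & m$end[pmax(k, 1)] > s) |
      (k < length(m$start) & m$start[pmin(k + 1, length(m$start))] < e)
    n <- n + sum(hit)
  }
  n
}

#' Summarise CNV overlap with segmental duplications
#'
#' @param cnvs,sds `interval_set`s on the same genome.
#' @return list: `n_overlapping` (CNVs sharing >=1 bp with an SD),
#'   `total_overlapped_length` (summed full lengths of those CNVs),
#'   `fraction_of_total_cnv_length`.
#' @export
sd_overlap_summary <- function(cnvs, sds) {
  co <- count_overlaps(cnvs, sds)
  lens <- cnvs$end - cnvs$start
  hit_len <- sum(lens[co$hits$overlaps_db])
  list(n_overlapping = co$count,
       total_overlapped_length = hit_len,
       fraction_of_total_cnv_length =
         if (sum(lens) > 0) hit_len / sum(lens) else 0)
}

#' Repeat-class genomic fraction within and around CNVs
#'
#' Computes, for the union of the CNV intervals (`intraCNV`) and for
#' flanking annuli at increasing offsets, the fraction of region bases
#' covered by each repeat class. Flanks are clipped at chromosome ends and
#' exclude the CNV union itself (and hence neighbouring CNVs); successive
#' flank windows are disjoint annuli, e.g. the 100 kb flank covers bases
#' 10-100 kb away from a CNV edge when preceded by a 10 kb window.
#'
#' @param cnvs an `interval_set`.
#' @param repeats an `interval_set` with a `class` column (e.g. LINE, SINE,
#'   LTR).
#' @param flank_offsets increasing bp offsets (default 10 kb, 100 kb, 1 Mb,
#'   10 Mb).
#' @return data.frame: `region`, `class`, `region_bp`, `class_bp`,
#'   `fraction` (also the per-kb retroelement fraction, the two being the
#'   same ratio). Zero-length regions are omitted.
#' @export
repeat_fraction_profile <- function(cnvs, repeats,
                                    flank_offsets = c(1e4, 1e5, 1e6, 1e7)) {
  check_same_genome(cnvs, repeats)
  stopifnot(!is.unsorted(flank_offsets, strictly = TRUE))
  cnv_gr <- GenomicRanges::reduce(as_granges(cnvs))
  classes <- sort(unique(repeats$class))
  rep_grs <- lapply(classes, function(cl)
    GenomicRanges::reduce(as_granges(repeats[repeats$class == cl, , drop = FALSE])))
  names(rep_grs) <- classes

  regions <- list(intraCNV = cnv_gr)
  prev <- 0
  for (w in flank_offsets) {
    outer <- GenomicRanges::trim(suppressWarnings(cnv_gr + w))
    inner <- GenomicRanges::trim(suppressWarnings(cnv_gr + prev))
    annulus <- GenomicRanges::setdiff(outer, inner)
    annulus <- GenomicRanges::setdiff(annulus, cnv_gr)
    lab <- paste0("flank@", format(w, scientific = FALSE, trim = TRUE))
    regions[[lab]] <- GenomicRanges::reduce(annulus)
    prev <- w
  }

  rows <- list()
  for (rn in names(regions)) {
    rg <- regions[[rn]]
    rbp <- sum(IRanges::width(rg))
    if (rbp == 0) next
    for (cl in classes) {
      cbp <- sum(IRanges::width(GenomicRanges::intersect(rg, rep_grs[[cl]])))
      rows[[length(rows) + 1L]] <- data.frame(
        region = rn, class = cl, region_bp = rbp, class_bp = cbp,
        fraction = cbp / rbp, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), class = character(),
               region_bp = numeric(), class_bp = numeric(),
               fraction = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate CNVs with overlapping gene names
#'
#' @param cnvs an `interval_set`.
#' @param genes an `interval_set` with a `name` column.
#' @return character vector, one element per CNV: comma-separated gene
#'   names sorted by gene start ("-" when none overlaps, >=1 bp rule).
#' @export
annotate_genes <- function(cnvs, genes) {
  check_same_genome(cnvs, genes)
  if (nrow(cnvs) == 0) return(character(0))
  if (nrow(genes) == 0) return(rep("-", nrow(cnvs)))
  hits <- GenomicRanges::findOverlaps(as_granges(cnvs), as_granges(genes))
  vapply(seq_len(nrow(cnvs)), function(i) {
    gi <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (!length(gi)) return("-")
    gi <- gi[order(genes$start[gi])]
    paste(genes$name[gi], collapse = ",")
  }, character(1))
}
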