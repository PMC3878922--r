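#' Define a genome for simulation and interval arithmetic
#'
#' A minimal genome description: ordered chromosomes with lengths and a
#' per-chromosome baseline copy number. The baseline is the copy number of
#' the nuclear donor, against which clone events are expressed; it defaults
#' to 2 everywhere but is configurable per chromosome (e.g. 1 for the X of a
#' male donor hybridised against a male reference).
#'
#' All internal coordinates in this package are 0-based half-open `[start,
#' end)`. See [to_report_coords()] for the 1-based reporting convention.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp, or a
#'   data.frame with columns `chrom` and `length`.
#' @param ploidy_baseline integer baseline copy number, length 1 (recycled)
#'   or one per chromosome; default 2.
#' @return An object of class `genome_def`: a data.frame with columns
#'   `chrom`, `length`, `baseline`.
#' @examples
#' genome_def(c(chr1 = 50e6, chrX = 120e6), ploidy_baseline = c(2, 1))
#' @export
genome_def <- function(chromosomes, ploidy_baseline = 2L) {
  if (is.data.frame(chromosomes)) {
    chrom <- as.character(chromosomes$chrom)
    len <- as.numeric(chromosomes$length)
  } else {
    if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
      stop("chromosomes must be named (name = chromosome, value = length)")
    chrom <- names(chromosomes)
    len <- as.numeric(chromosomes)
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(len)) || any(len <= 0)) stop("chromosome lengths must be positive")
  baseline <- as.integer(rep_len(ploidy_baseline, length(chrom)))
  if (any(baseline < 1)) stop("ploidy_baseline must be >= 1")
  structure(
    data.frame(chrom = chrom, length = len, baseline = baseline,
               stringsAsFactors = FALSE),
    class = c("genome_def", "data.frame")
  )
}

genome_baseline <- function(genome, chrom) {
  genome$baseline[match(chrom, genome$chrom)]
}

#' Chromosome lengths of a genome definition
#'
#' @param genome a [genome_def()].
#' @param chrom character vector of chromosome names.
#' @return numeric lengths in bp (NA for unknown chromosomes).
#' @export
genome_length <- function(genome, chrom) {
  genome$length[match(chrom, genome$chrom)]
}

same_genome <- function(g1, g2) {
  identical(g1$chrom, g2$chrom) && identical(g1$length, g2$length)
}

#' Construct a ground-truth event list
#'
#' Truth events describe the clone genome relative to the donor baseline:
#' copy-number gains and losses, and copy-neutral loss of heterozygosity
#' (`cn_loh`, total copy number unchanged but one haplotype replaced by the
#' other, as in mitotic uniparental disomy).
#'
#' @param chrom,start,end event coordinates, 0-based half-open.
#' @param kind one of `"gain"`, `"loss"`, `"cn_loh"` per event.
#' @param copy_number integer clone copy number. For `cn_loh` it may be `NA`
#'   (resolved to the baseline).
#' @param genome a [genome_def()] used to validate bounds and baselines.
#' @return data.frame of class `truth_events` with columns `chrom`, `start`,
#'   `end`, `kind`, `copy_number`.
#' @export
truth_events <- function(chrom, start, end, kind, copy_number, genome) {
  ev <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), kind = as.character(kind),
                   copy_number = as.integer(copy_number),
                   stringsAsFactors = FALSE)
  validate_events(ev, genome)
}

#' An empty truth event table (an event-free clone)
#'
#' @return zero-row `truth_events` data.frame.
#' @export
empty_events <- function() {
  structure(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               kind = character(), copy_number = integer(),
               stringsAsFactors = FALSE),
    class = c("truth_events", "data.frame")
  )
}

validate_events <- function(events, genome) {
  if (nrow(events) == 0) return(empty_events())
  if (!all(events$kind %in% c("gain", "loss", "cn_loh")))
    stop("event kind must be gain, loss or cn_loh")
  unknown <- setdiff(events$chrom, genome$chrom)
  if (length(unknown))
    stop("unknown chromosome in events: ", paste(unknown, collapse = ", "))
  if (any(events$start >= events$end)) stop("event start must be < end")
  lens <- genome_length(genome, events$chrom)
  if (any(events$start < 0) || any(events$end > lens))
    stop("event outside chromosome bounds")
  base <- genome_baseline(genome, events$chrom)
  loh <- events$kind == "cn_loh"
  events$copy_number[loh] <- base[loh]
  if (any(events$kind == "gain" & events$copy_number <= base))
    stop("gain copy_number must exceed the baseline")
  if (any(events$kind == "loss" & (events$copy_number >= base | events$copy_number < 0)))
    stop("loss copy_number must be below the baseline and >= 0")
  # overlapping events of conflicting kind/copy number are ambiguous
  ord <- order(events$chrom, events$start)
  ev <- events[ord, , drop = FALSE]
  for (i in seq_len(nrow(ev) - 1)) {
    j <- i + 1
    while (j <= nrow(ev) && ev$chrom[j] == ev$chrom[i] && ev$start[j] < ev$end[i]) {
      if (ev$kind[j] != ev$kind[i] || ev$copy_number[j] != ev$copy_number[i])
        stop("overlapping events of conflicting kind")
      j <- j + 1
    }
  }
  rownames(ev) <- NULL
  class(ev) <- c("truth_events", "data.frame")
  ev
}

#' Local clone copy number at given positions
#'
#' @param genome a [genome_def()].
#' @param events a truth event table (see [truth_events()]).
#' @param chrom,pos vectors of positions (0-based).
#' @return integer copy numbers (baseline outside events).
#' @keywords internal
copy_number_at <- function(genome, events, chrom, pos) {
  cn <- genome_baseline(genome, chrom)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      if (events$kind[i] == "cn_loh") next
      hit <- chrom == events$chrom[i] & pos >= events$start[i] & pos < events$end[i]
      cn[hit] <- events$copy_number[i]
    }
  }
  cn
}

in_loh_at <- function(events, chrom, pos) {
  inloh <- rep(FALSE, length(pos))
  if (nrow(events)) {
    for (i in which(events$kind == "cn_loh")) {
      hit <- chrom == events$chrom[i] & pos >= events$start[i] & pos < events$end[i]
      inloh[hit] <- TRUE
    }
  }
  inloh
}

#' Convert internal to report coordinates
#'
#' Internally all intervals are 0-based half-open. Reports and output tables
#' print a 1-based start with `end = start + length`, so that the printed
#' `end - start` equals the interval length in bp.
#'
#' @param start,end internal 0-based half-open coordinates.
#' @return data.frame with `start`, `end`, `length` on the report scale.
#' @examples
#' to_report_coords(0, 100)    # start 1, end 101, length 100
#' @export
to_report_coords <- function(start, end) {
  data.frame(start = start + 1, end = end + 1, length = end - start)
}

#' Length of an interval from report coordinates
#'
#' The reporting convention makes interval length the plain difference of the
#' printed coordinates.
#'
#' @param start,end report-scale coordinates.
#' @return numeric lengths `end - start`.
#' @export
report_length <- function(start, end) {
  if (any(end <= start)) stop("end must exceed start")
  end - start
}
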