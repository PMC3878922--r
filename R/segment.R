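#' CNV calling parameters
#'
#' Defaults follow the calling criteria of the discovery analysis this
#' package implements: boundary-test significance threshold 1e-6, a forced
#' segment break wherever adjacent probes are more than 1 Mb apart, at least
#' 5 probes per CNV segment, and log2-ratio thresholds of +0.2 / -0.2 for
#' gains and losses.
#'
#' @param alpha significance threshold for accepting a segment split.
#' @param max_gap maximum contiguous probe spacing in bp; larger gaps force
#'   a segment break.
#' @param min_probes minimum probes per CNV segment (and per split child).
#' @param gain_thr,loss_thr mean log2-ratio thresholds for calling.
#' @param perm_cutoff below this run length the boundary p-value is computed
#'   by permutation rather than normal approximation.
#' @param n_perm permutations for the small-run fallback.
#' @return list of class `cnv_params`.
#' @export
cnv_params <- function(alpha = 1e-6, max_gap = 1e6, min_probes = 5L,
                       gain_thr = 0.2, loss_thr = -0.2,
                       perm_cutoff = 50L, n_perm = 999L) {
  stopifnot(alpha > 0, alpha < 1, max_gap > 0, min_probes >= 2,
            loss_thr < 0, gain_thr > 0)
  structure(list(alpha = alpha, max_gap = max_gap,
                 min_probes = as.integer(min_probes),
                 gain_thr = gain_thr, loss_thr = loss_thr,
                 perm_cutoff = as.integer(perm_cutoff),
                 n_perm = as.integer(n_perm)),
            class = "cnv_params")
}

# Geometric grid of candidate segment widths for the windowed rank scan.
scan_widths <- function(min_w, max_w, ratio = 1.2) {
  if (max_w < min_w) return(integer(0))
  w <- min_w
  out <- integer(0)
  while (w < max_w) {
    out <- c(out, w)
    w <- max(w + 1L, as.integer(ceiling(w * ratio)))
  }
  c(out, max_w)
}

# Best split of a run by the segment-vs-rest rank statistic.
# Candidate contiguous segments [i+1, i+w] over a geometric width grid are
# compared against the remainder of the run via the Wilcoxon-Mann-Whitney
# rank-sum z score (normal form with tie correction); a prefix/suffix
# candidate reduces to the classical single-breakpoint two-sample split.
# A segment-vs-rest contrast is used because a single prefix-vs-suffix
# contrast has essentially no power against short events embedded in long
# runs. Admissible candidates leave each flank either empty or with at
# least min_probes probes. Returns the maximising candidate (leftmost,
# then narrowest, on ties) or NULL.
best_rank_split <- function(x, min_probes) {
  n <- length(x)
  if (n < 2L * min_probes) return(NULL)
  r <- rank(x)
  C <- c(0, cumsum(r))
  tie_sizes <- tabulate(match(x, unique(x)))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  vfac <- (n + 1) - tie_term / (n * (n - 1))
  if (vfac <= 0) return(NULL)                   # constant run
  zfun <- function(a, b) {                      # segment is (a, b] as 0-based cuts
    w <- b - a
    S <- C[b + 1] - C[a + 1]
    (S - w * (n + 1) / 2) / sqrt(w * (n - w) / 12 * vfac)
  }
  best <- NULL
  for (w in scan_widths(min_probes, n - min_probes)) {
    i <- 0:(n - w)                              # segment is [i+1, i+w]
    left_ok <- i == 0L | i >= min_probes
    right <- n - i - w
    right_ok <- right == 0L | right >= min_probes
    i <- i[left_ok & right_ok]
    if (!length(i)) next
    z <- zfun(i, i + w)
    k <- which.max(abs(z))                      # leftmost on ties
    if (is.null(best) || abs(z[k]) > best$z) {
      best <- list(i = i[k], w = w, z = abs(z[k]))
    }
  }
  if (is.null(best)) return(NULL)
  refine_split_edges(best, zfun, n, min_probes)
}

# Coordinate-wise local refinement of the grid-scan winner: each segment
# edge in turn is moved to the position maximising |z| within a halo around
# the grid candidate, under the same flank constraints. The grid quantises
# widths, so without this step boundaries land near, not on, the true
# change points.
refine_split_edges <- function(best, zfun, n, min_probes) {
  a <- best$i; b <- best$i + best$w
  for (iter in 1:3) {
    h <- max(3L, ceiling(0.25 * (b - a)))
    ca <- seq.int(max(0L, a - h), min(a + h, b - min_probes))
    ca <- ca[(ca == 0L | ca >= min_probes) & (b - ca) < n]
    if (length(ca)) {
      za <- abs(zfun(ca, b))
      a <- ca[which.max(za)]
    }
    cb <- seq.int(max(b - h, a + min_probes), min(n, b + h))
    cb <- cb[(n - cb == 0L | n - cb >= min_probes) & (cb - a) < n]
    if (length(cb)) {
      zb <- abs(zfun(a, cb))
      b <- cb[which.max(zb)]
    }
  }
  list(i = a, w = b - a, z = abs(zfun(a, b)))
}

split_pvalue <- function(x, obs_z, params) {
  n <- length(x)
  if (n >= params$perm_cutoff) {
    return(2 * stats::pnorm(-obs_z))
  }
  worse <- 0L
  for (b in seq_len(params$n_perm)) {
    sp <- best_rank_split(sample(x), params$min_probes)
    if (!is.null(sp) && sp$z >= obs_z) worse <- worse + 1L
  }
  (1 + worse) / (params$n_perm + 1)
}

# Recursive segmentation of one gap-free run; an accepted candidate segment
# splits the run three ways (left flank, segment, right flank; empty flanks
# allowed). Returns sorted interior boundaries (index of the first probe of
# the segment that starts there) with the p-value of the split that created
# each.
segment_one_run <- function(x, params) {
  boundaries <- numeric(0)
  split_p <- numeric(0)
  stack <- list(c(1L, length(x)))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- iv[1]; hi <- iv[2]
    sp <- best_rank_split(x[lo:hi], params$min_probes)
    if (is.null(sp)) next
    p <- split_pvalue(x[lo:hi], sp$z, params)
    if (p <= params$alpha) {
      seg_lo <- lo + sp$i                 # first probe of the segment
      seg_hi <- seg_lo + sp$w - 1L        # last probe of the segment
      if (seg_lo > lo) {
        boundaries <- c(boundaries, seg_lo)
        split_p <- c(split_p, p)
        stack <- c(stack, list(c(lo, seg_lo - 1L)))
      }
      if (seg_hi < hi) {
        boundaries <- c(boundaries, seg_hi + 1L)
        split_p <- c(split_p, p)
        stack <- c(stack, list(c(seg_hi + 1L, hi)))
      }
      stack <- c(stack, list(c(seg_lo, seg_hi)))
    }
  }
  ord <- order(boundaries)
  list(boundaries = boundaries[ord], split_p = split_p[ord])
}

#' Rank-based recursive segmentation of probe-level log2 ratios
#'
#' Each chromosome is first split into runs wherever adjacent probe spacing
#' exceeds `max_gap` (array coverage gaps are never bridged). Within a run,
#' recursive binary segmentation is applied to the ranks of the log2 ratios:
#' at each step the breakpoint maximising the two-sample Wilcoxon rank
#' statistic (normal approximation with tie correction; permutation below
#' `perm_cutoff` probes) is accepted if its p-value is at most `alpha` and
#' both children retain at least `min_probes` probes. Every probe belongs to
#' exactly one output segment.
#'
#' @param probes a `probe_table` (columns `chrom`, `pos`, `log2_ratio`,
#'   sorted by position within chromosome).
#' @param params a [cnv_params()] list.
#' @param seed integer seed (used only by the small-run permutation
#'   fallback).
#' @return data.frame of class `segment_table`: `chrom`, `start`, `end`
#'   (bp span of member probes, half-open), `n_probes`, `mean_log2`,
#'   `split_p` (p-value of the boundary test that created the segment, NA
#'   for never-split runs), `run_id`, `unsegmentable` (TRUE for chromosomes
#'   with fewer than `min_probes` probes).
#' @export
rank_segment <- function(probes, params = cnv_params(), seed = 1L) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "pos", "log2_ratio") %in% names(probes)))
  if (any(!is.finite(probes$log2_ratio))) stop("log2 ratios must be finite")
  set.seed(as.integer(seed))
  out <- list()
  run_id <- 0L
  for (chrom in unique(probes$chrom)) {
    pc <- probes[probes$chrom == chrom, , drop = FALSE]
    if (is.unsorted(pc$pos, strictly = TRUE))
      stop("probe positions must be strictly increasing within ", chrom)
    n <- nrow(pc)
    unseg <- n < params$min_probes
    gaps <- which(diff(pc$pos) > params$max_gap)
    run_starts <- c(1L, gaps + 1L)
    run_ends <- c(gaps, n)
    for (r in seq_along(run_starts)) {
      run_id <- run_id + 1L
      lo <- run_starts[r]; hi <- run_ends[r]
      x <- pc$log2_ratio[lo:hi]
      if (unseg || length(x) < 2L * params$min_probes) {
        seg_starts <- 1L; seg_p <- NA_real_
      } else {
        sr <- segment_one_run(x, params)
        seg_starts <- c(1L, sr$boundaries)
        # a boundary's p annotates the segment it starts; the run's first
        # segment inherits the p of the run's first accepted split (NA if none)
        seg_p <- c(if (length(sr$boundaries)) sr$split_p[1] else NA_real_,
                   sr$split_p)
      }
      seg_ends <- c(seg_starts[-1] - 1L, length(x))
      for (s in seq_along(seg_starts)) {
        i0 <- lo + seg_starts[s] - 1L
        i1 <- lo + seg_ends[s] - 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom,
          start = pc$pos[i0],
          end = pc$pos[i1] + 1,
          n_probes = i1 - i0 + 1L,
          mean_log2 = mean(pc$log2_ratio[i0:i1]),
          split_p = seg_p[s],
          run_id = run_id,
          unsegmentable = unseg,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  class(segs) <- c("segment_table", "data.frame")
  segs
}

#' Call CNVs from a segment table
#'
#' Segments whose mean log2 ratio exceeds `gain_thr` (or falls below
#' `loss_thr`) with at least `min_probes` probes become gain (loss) calls.
#' Adjacent same-direction calls separated only by a coverage-gap break are
#' merged into one call (gaps are array artifacts, not event boundaries);
#' same-direction neighbours within a run, i.e. separated by a significant
#' boundary, are kept apart since they represent distinct copy levels.
#'
#' @param segments a `segment_table` from [rank_segment()].
#' @param params a [cnv_params()].
#' @return data.frame of class `cnv_calls`: `chrom`, `start`, `end`,
#'   `length`, `event` ("gain"/"loss"), `n_probes`, `mean_log2`, plus
#'   validation flag columns `dye_swap`, `qpcr`, `baf` initialised to NA.
#' @export
call_cnvs <- function(segments, params = cnv_params()) {
  ev <- ifelse(segments$mean_log2 > params$gain_thr, "gain",
               ifelse(segments$mean_log2 < params$loss_thr, "loss", NA))
  keep <- !is.na(ev) & segments$n_probes >= params$min_probes
  if (!any(keep)) return(empty_calls())
  calls <- segments[keep, , drop = FALSE]
  calls$event <- ev[keep]
  if (nrow(calls) > 1) {
    merged <- list(calls[1, , drop = FALSE])
    for (i in 2:nrow(calls)) {
      last <- merged[[length(merged)]]
      cur <- calls[i, , drop = FALSE]
      adjacent_rows <- which(keep)[i] - which(keep)[i - 1] == 1L
      gap_break <- cur$run_id != last$run_id[nrow(last)]
      if (cur$chrom == last$chrom[1] && cur$event == last$event[1] &&
          adjacent_rows && gap_break) {
        merged[[length(merged)]] <- rbind(last, cur)
      } else {
        merged[[length(merged) + 1L]] <- cur
      }
    }
    calls <- do.call(rbind, lapply(merged, function(g) {
      data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
                 event = g$event[1], n_probes = sum(g$n_probes),
                 mean_log2 = sum(g$mean_log2 * g$n_probes) / sum(g$n_probes),
                 stringsAsFactors = FALSE)
    }))
  } else {
    calls <- calls[, c("chrom", "start", "end", "event", "n_probes", "mean_log2")]
  }
  calls$length <- calls$end - calls$start
  calls$dye_swap <- NA
  calls$qpcr <- NA
  calls$baf <- NA
  calls <- calls[, c("chrom", "start", "end", "length", "event",
                     "n_probes", "mean_log2", "dye_swap", "qpcr", "baf")]
  rownames(calls) <- NULL
  class(calls) <- c("cnv_calls", "data.frame")
  calls
}

empty_calls <- function() {
  structure(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               length = numeric(), event = character(), n_probes = integer(),
               mean_log2 = numeric(), dye_swap = logical(), qpcr = logical(),
               baf = logical(), stringsAsFactors = FALSE),
    class = c("cnv_calls", "data.frame")
  )
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Validate CNV calls by dye-swap concordance
#'
#' A true copy-number change must invert its sign when the fluorophores are
#' swapped: a forward call passes if some swap call of the opposite
#' direction overlaps it reciprocally by at least `min_reciprocal`. With an
#' empty swap call set every forward call fails (the swap experiment was
#' run and showed nothing).
#'
#' @param calls_forward,calls_swap `cnv_calls` from the forward and
#'   dye-swapped hybridisations, called with identical settings.
#' @param min_reciprocal minimum reciprocal overlap fraction (default 0.5).
#' @return `calls_forward` with its `dye_swap` flag set TRUE/FALSE.
#' @export
dye_swap_concordance <- function(calls_forward, calls_swap, min_reciprocal = 0.5) {
  if (nrow(calls_forward) == 0) return(calls_forward)
  flip <- c(gain = "loss", loss = "gain")
  calls_forward$dye_swap <- vapply(seq_len(nrow(calls_forward)), function(i) {
    want <- flip[[calls_forward$event[i]]]
    cand <- calls_swap[calls_swap$event == want &
                         calls_swap$chrom == calls_forward$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) return(FALSE)
    any(reciprocal_overlap(calls_forward$start[i], calls_forward$end[i],
                           cand$start, cand$end) >= min_reciprocal)
  }, logical(1))
  calls_forward
}

#' Compare CNV calls with ground-truth events
#'
#' Scores a call set against the truth events of a simulated genome: an
#' event is recalled if a call of the same direction overlaps it; boundary
#' error is measured in probes between the call and truth boundaries.
#'
#' @param calls a `cnv_calls` table.
#' @param truth a truth event table (gains/losses scored; cn_loh ignored).
#' @param probes the `probe_table` the calls came from.
#' @return list with `events` (per-event data.frame: `recalled`,
#'   `start_err_probes`, `end_err_probes`), `recall`, `n_false_calls`
#'   (calls overlapping no truth event).
#' @export
evaluate_calls <- function(calls, truth, probes) {
  truth <- truth[truth$kind %in% c("gain", "loss"), , drop = FALSE]
  n_probes_between <- function(chrom, a, b) {
    p <- probes$pos[probes$chrom == chrom]
    sum(p >= min(a, b) & p < max(a, b))
  }
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    cand <- calls[calls$chrom == truth$chrom[i] & calls$event == truth$kind[i] &
                    calls$end > truth$start[i] & calls$start < truth$end[i], ,
                  drop = FALSE]
    if (nrow(cand) == 0)
      return(data.frame(recalled = FALSE, start_err_probes = NA_real_,
                        end_err_probes = NA_real_))
    ov <- pmin(cand$end, truth$end[i]) - pmax(cand$start, truth$start[i])
    best <- cand[which.max(ov), , drop = FALSE]
    data.frame(
      recalled = TRUE,
      start_err_probes = n_probes_between(truth$chrom[i], best$start, truth$start[i]),
      end_err_probes = n_probes_between(truth$chrom[i], best$end, truth$end[i])
    )
  })
  evdf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recalled = logical(), start_err_probes = numeric(),
               end_err_probes = numeric())
  false_calls <- 0L
  if (nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      hit <- any(truth$chrom == calls$chrom[i] &
                   truth$end > calls$start[i] & truth$start < calls$end[i])
      if (!hit) false_calls <- false_calls + 1L
    }
  }
  list(events = evdf,
       recall = if (nrow(evdf)) mean(evdf$recalled) else NA_real_,
       n_false_calls = false_calls)
}
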