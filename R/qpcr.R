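#' Relative copy number from qPCR threshold cycles (2^-ddCt)
#'
#' Classical relative quantification: replicate Cts are averaged per well
#' group, the target is normalised against the diploid control locus within
#' each DNA (`dCt = Ct_target - Ct_control`), and the sample is expressed
#' relative to the calibrator (the nuclear donor): `fold = 2^-(dCt_sample -
#' dCt_calibrator)`. A fold of 1.5 on a diploid baseline indicates three
#' copies; 0.5 indicates one.
#'
#' @param assay a `qpcr_assay` data.frame with columns `group`, `ct`; the
#'   four groups `sample_target`, `sample_control`, `calibrator_target`,
#'   `calibrator_control` must all be present.
#' @return list of class `fold_change`: `value`, per-group mean and SD of
#'   the replicate Cts.
#' @export
ddct_fold_change <- function(assay) {
  groups <- c("sample_target", "sample_control",
              "calibrator_target", "calibrator_control")
  missing <- setdiff(groups, unique(assay$group))
  if (length(missing))
    stop("missing well group(s): ", paste(missing, collapse = ", "))
  if (any(assay$ct <= 0)) stop("Ct values must be positive")
  m <- vapply(groups, function(g) mean(assay$ct[assay$group == g]), numeric(1))
  s <- vapply(groups, function(g) stats::sd(assay$ct[assay$group == g]), numeric(1))
  ddct <- (m["sample_target"] - m["sample_control"]) -
    (m["calibrator_target"] - m["calibrator_control"])
  structure(list(value = unname(2^(-ddct)), mean_ct = m, sd_ct = s),
            class = "fold_change")
}

#' Classify a qPCR fold change as gain, loss or neutral
#'
#' @param value positive fold change (1 = diploid relative to calibrator).
#' @param gain_thr minimum fold for a gain call (default 1.4, below the 1.5
#'   expected for a single-copy gain on a diploid baseline).
#' @param loss_thr maximum fold for a loss call (default 0.7, above the 0.5
#'   expected for a single-copy loss).
#' @return "gain", "loss" or "neutral" (vectorised).
#' @export
classify_fold <- function(value, gain_thr = 1.4, loss_thr = 0.7) {
  if (!(loss_thr < 1 && 1 < gain_thr))
    stop("thresholds must satisfy loss_thr < 1 < gain_thr")
  if (any(value <= 0)) stop("fold change must be positive")
  ifelse(value >= gain_thr, "gain", ifelse(value <= loss_thr, "loss", "neutral"))
}

#' Validate a CNV call by multi-point qPCR
#'
#' Multiple assay points are placed inside and outside the expected CNV
#' breakpoints. The call is `validated` when every inside point classifies
#' concordant with the call direction and every outside point classifies
#' neutral; `not_validated` when no inside point is concordant; otherwise
#' `indeterminate`. The refined boundary brackets each breakpoint between
#' the outermost concordant inside point and the innermost neutral outside
#' point.
#'
#' @param cnv one row of a `cnv_calls` table (needs `chrom`, `start`, `end`,
#'   `event`).
#' @param assays data.frame with one row per assay point: `position` (bp),
#'   `inside` (logical: within the expected CNV), `fold` (from
#'   [ddct_fold_change()]); at least one inside point required.
#' @param gain_thr,loss_thr classification thresholds for [classify_fold()].
#' @return list of class `qpcr_verdict`: `verdict`, `assays` (with a
#'   `class` column), `refined` (data.frame `inner_start`, `inner_end`,
#'   `outer_start`, `outer_end`; NA where no bracketing point exists).
#' @export
validate_boundaries <- function(cnv, assays, gain_thr = 1.4, loss_thr = 0.7) {
  if (nrow(assays) == 0) {
    return(structure(list(verdict = "indeterminate",
                          reason = "no assay points supplied",
                          assays = assays, refined = NULL),
                     class = "qpcr_verdict"))
  }
  if (!any(assays$inside))
    stop("at least one assay point inside the expected CNV is required")
  assays$class <- classify_fold(assays$fold, gain_thr, loss_thr)
  inside <- assays[assays$inside, , drop = FALSE]
  outside <- assays[!assays$inside, , drop = FALSE]
  concordant <- inside$class == cnv$event
  outside_neutral <- outside$class == "neutral"
  verdict <- if (all(concordant) && all(outside_neutral)) "validated"
  else if (!any(concordant)) "not_validated"
  else "indeterminate"
  conc_pos <- inside$position[concordant]
  left_out <- outside$position[outside_neutral & outside$position < cnv$start]
  right_out <- outside$position[outside_neutral & outside$position >= cnv$end]
  refined <- data.frame(
    inner_start = if (length(conc_pos)) min(conc_pos) else NA_real_,
    inner_end = if (length(conc_pos)) max(conc_pos) else NA_real_,
    outer_start = if (length(left_out)) max(left_out) else NA_real_,
    outer_end = if (length(right_out)) min(right_out) else NA_real_
  )
  structure(list(verdict = verdict, reason = NA_character_,
                 assays = assays, refined = refined),
            class = "qpcr_verdict")
}
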