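#' Read and write the package's tabular formats
#'
#' Typed TSV readers/writers for probe tables, SNP tables, Ct tables and
#' allele-frequency tables, plus a minimal BED3+ reader/writer (name and
#' optional class columns). BED files are 0-based half-open per the BED
#' standard — the same convention used internally, so no shift is applied;
#' report tables print 1-based coordinates via [to_report_coords()].
#' Writers emit rows ordered by (chromosome, position), so a fixed input
#' always produces byte-identical files.
#'
#' @param path file path.
#' @param x table to write.
#' @name clonecnv-io
NULL

read_tsv_checked <- function(path, required, numeric_cols) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  for (col in intersect(numeric_cols, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop(path, ": malformed value in column '", col, "' at line ",
           bad[1] + 1L)  # +1 for the header line
    tab[[col]] <- v
  }
  tab
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname clonecnv-io
#' @export
write_probe_table <- function(x, path) {
  x <- x[order(x$chrom, x$pos), c("probe_id", "chrom", "pos", "log2_ratio")]
  write_tsv_plain(x, path)
}

#' @rdname clonecnv-io
#' @export
read_probe_table <- function(path) {
  tab <- read_tsv_checked(path, c("probe_id", "chrom", "pos", "log2_ratio"),
                          c("pos", "log2_ratio"))
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("probe_table", "data.frame")
  tab
}

#' @rdname clonecnv-io
#' @export
write_snp_table <- function(x, path) {
  x <- x[order(x$chrom, x$pos), c("snp_id", "chrom", "pos", "lrr", "baf")]
  write_tsv_plain(x, path)
}

#' @rdname clonecnv-io
#' @export
read_snp_table <- function(path) {
  tab <- read_tsv_checked(path, c("snp_id", "chrom", "pos", "lrr", "baf"),
                          c("pos", "lrr", "baf"))
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("snp_table", "data.frame")
  tab
}

#' @rdname clonecnv-io
#' @param genome optional [genome_def()]; when given the result is an
#'   [interval_set()] validated against it.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3))
      stop(path, ": malformed BED row at line ", which(nf < 3)[1])
    out <- data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = as.numeric(vapply(parts, `[`, "", 2)),
      end = as.numeric(vapply(parts, `[`, "", 3)),
      stringsAsFactors = FALSE
    )
    if (any(is.na(out$start) | is.na(out$end)))
      stop(path, ": non-numeric BED coordinate at line ",
           which(is.na(out$start) | is.na(out$end))[1])
    if (all(nf >= 4)) out$name <- vapply(parts, `[`, "", 4)
    if (all(nf >= 5)) out$class <- vapply(parts, `[`, "", 5)
  }
  if (!is.null(genome)) out <- interval_set(out, genome) else out
}

#' @rdname clonecnv-io
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "class"), names(x))
  x <- x[order(x$chrom, x$start), cols, drop = FALSE]
  x$start <- format(x$start, scientific = FALSE, trim = TRUE)
  x$end <- format(x$end, scientific = FALSE, trim = TRUE)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname clonecnv-io
#' @export
read_ct_table <- function(path) {
  tab <- read_tsv_checked(path, c("assay", "group", "replicate", "ct"),
                          c("replicate", "ct"))
  bad <- setdiff(unique(tab$group),
                 c("sample_target", "sample_control",
                   "calibrator_target", "calibrator_control"))
  if (length(bad)) stop(path, ": unknown well group ", bad[1])
  tab
}

#' @rdname clonecnv-io
#' @export
read_allele_freqs <- function(path) {
  tab <- read_tsv_checked(path, c("locus", "allele", "freq"), "freq")
  split_tab <- split(tab, tab$locus)
  lapply(split_tab, function(d) stats::setNames(d$freq, d$allele))
}

#' @rdname clonecnv-io
#' @export
write_allele_freqs <- function(x, path) {
  rows <- lapply(names(x), function(l)
    data.frame(locus = l,
               allele = if (is.null(names(x[[l]]))) as.character(seq_along(x[[l]]))
                        else names(x[[l]]),
               freq = unname(x[[l]]), stringsAsFactors = FALSE))
  write_tsv_plain(do.call(rbind, rows), path)
}

#' Format CNV or LOH calls as a report table
#'
#' Converts internal half-open coordinates to the reporting convention
#' (1-based start, end = start + length) and attaches the validation flag
#' columns as "pass"/"fail"/"NA" strings.
#'
#' @param calls a `cnv_calls` or `loh_calls` table.
#' @return data.frame ready for writing with [write_tsv_plain()] semantics.
#' @export
format_report_calls <- function(calls) {
  if (nrow(calls) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length = numeric(), stringsAsFactors = FALSE))
  }
  rc <- to_report_coords(calls$start, calls$end)
  out <- data.frame(chrom = calls$chrom, start = rc$start, end = rc$end,
                    length = rc$length, stringsAsFactors = FALSE)
  for (col in intersect(c("event", "n_probes", "mean_log2", "n_snps", "p_run"),
                        names(calls)))
    out[[col]] <- calls[[col]]
  for (flag in intersect(c("dye_swap", "qpcr", "baf"), names(calls)))
    out[[flag]] <- ifelse(is.na(calls[[flag]]), "NA",
                          ifelse(calls[[flag]], "pass", "fail"))
  out
}
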